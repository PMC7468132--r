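test_that("credible intervals follow the Beta posterior quantiles", {
  ci <- vaf_credible_interval(50, 100)
  expect_equal(ci$lo, qbeta(0.025, 51, 51))
  expect_equal(ci$hi, qbeta(0.975, 51, 51))
  expect_lt(abs((ci$lo + ci$hi) / 2 - 0.5), 0.01)

  ci0 <- vaf_credible_interval(0, 100)
  expect_equal(ci0$lo, 0)
  expect_lt(ci0$hi, 0.05)

  # width shrinks with coverage at fixed VAF
  w <- vapply(c(20, 80, 320, 1280), function(t) {
    ci <- vaf_credible_interval(round(t * 0.3), t)
    ci$hi - ci$lo
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(vaf_credible_interval(1, 0), "positive")
})

test_that("predicted VAFs enumerate mutated-copy assignments", {
  # one tumor clone, state (1,1), u = (0.4, 0.6), ctilde = 1 -> 0.3
  v <- predicted_vafs(c(1, 1), c(1, 1), c(0.4, 0.6))
  expect_true(any(abs(v - 0.3) < 1e-12))
  # the all-zero assignment is excluded
  expect_false(any(v == 0))

  # post-WGD (2,2), purity 1 -> {0.25, 0.5}
  v2 <- predicted_vafs(c(1, 2), c(1, 2), c(0, 1))
  expect_true(all(c(0.25, 0.5) %in% v2))

  # an absent clone contributes nothing
  v3 <- predicted_vafs(c(1, 1, 5), c(1, 1, 5), c(0.4, 0.6, 0))
  expect_equal(v3, predicted_vafs(c(1, 1, 0), c(1, 1, 0), c(0.4, 0.6, 0)))

  # total deletion errors
  expect_error(predicted_vafs(c(0, 0), c(0, 0), c(0.5, 0.5)), "deletion")
})

test_that("CCF follows the purity- and ploidy-corrected formula", {
  # clonal single-copy mutation, diploid locus, mu = 0.6, VAF = 0.3 -> 1
  r <- mutation_ccf(0.3, 0.6, cbar = 2, max_mult = 1)
  expect_equal(r$ccf, 1.0)
  expect_equal(r$multiplicity, 1L)
  # half the VAF -> CCF 0.5
  expect_equal(mutation_ccf(0.15, 0.6, 2, 1)$ccf, 0.5)
  # pure tumor, (1,1) locus, VAF 0.5 -> 1
  expect_equal(mutation_ccf(0.5, 1, 2, 1)$ccf, 1.0)
  # multiplicity selection: VAF 0.5 at a (2,2) locus, purity 1: m = 2
  r2 <- mutation_ccf(0.5, 1, 4, 2)
  expect_equal(r2$multiplicity, 2L)
  expect_equal(r2$ccf, 1.0)
  # undefined without tumor content
  expect_true(is.na(mutation_ccf(0.3, 0, 2, 1)$ccf))
})

test_that("true solutions explain simulated mutations", {
  pat <- quick_patient(seed = 43, n_clones = 3, n_samples = 2,
                       genome_size = 3e7)
  sim <- simulate_mutations(pat, n_mutations = 50, coverage = 100,
                            seed = 44)
  truth <- pat$truth
  # build the true cluster solution at bin resolution
  st <- truth$bin_states
  bins <- pat$bins
  A <- cbind(1L, st[[2]]$a, st[[3]]$a)
  B <- cbind(1L, st[[2]]$b, st[[3]]$b)
  rownames(A) <- rownames(B) <- as.character(bins$bin)
  colnames(A) <- colnames(B) <- c("normal", "clone2", "clone3")
  U <- truth$U
  lens <- setNames(bins$end - bins$start, bins$bin)
  sol <- clonecna:::new_cna_solution(A, B, U, lens, 0, list(wgd = FALSE))
  cluster_of <- function(chrom, pos) {
    as.character(clonecna:::assign_to_bins(bins, chrom, pos))
  }
  res <- assess_mutations(sim$mutations, sol, cluster_of = cluster_of,
                          min_vaf = 0)
  high <- res$assessment[res$assessment$total_reads >= 60, ]
  expect_gte(mean(high$explained), 0.95)
})

test_that("wrong proportions leave high-coverage mutations unexplained", {
  # deep coverage, single clonal mutation; solution purity off by 0.3
  A <- cbind(1L, 1L); B <- cbind(1L, 1L)
  rownames(A) <- rownames(B) <- "1"
  colnames(A) <- colnames(B) <- c("normal", "clone2")
  U_wrong <- matrix(c(0.7, 0.3), 2, 1,
                    dimnames = list(c("normal", "clone2"), "s1"))
  sol <- clonecna:::new_cna_solution(A, B, U_wrong, c(`1` = 1e5), 0,
                                     list(wgd = FALSE))
  muts <- tibble::tibble(chrom = "chr1", pos = 10, sample = "s1",
                         var_reads = 3000, total_reads = 10000)
  res <- assess_mutations(muts, sol, cluster_of = function(...) "1",
                          min_vaf = 0)
  expect_false(res$assessment$explained[1])
})

test_that("low-frequency mutations are excluded from the summary", {
  A <- cbind(1L, 1L); B <- cbind(1L, 1L)
  rownames(A) <- rownames(B) <- "1"
  colnames(A) <- colnames(B) <- c("normal", "clone2")
  U <- matrix(c(0.4, 0.6), 2, 1,
              dimnames = list(c("normal", "clone2"), "s1"))
  sol <- clonecna:::new_cna_solution(A, B, U, c(`1` = 1e5), 0,
                                     list(wgd = FALSE))
  muts <- tibble::tibble(chrom = "chr1", pos = c(10, 20), sample = "s1",
                         var_reads = c(10, 30), total_reads = 100)
  res <- assess_mutations(muts, sol, cluster_of = function(...) "1")
  expect_equal(res$summary$n, 1) # the VAF = 0.1 mutation is filtered out
  expect_equal(nrow(res$assessment), 2)
})

test_that("mutations outside the covered genome are skipped with a warning", {
  A <- cbind(1L, 1L); B <- cbind(1L, 1L)
  rownames(A) <- rownames(B) <- "1"
  colnames(A) <- colnames(B) <- c("normal", "clone2")
  U <- matrix(c(0.4, 0.6), 2, 1,
              dimnames = list(c("normal", "clone2"), "s1"))
  sol <- clonecna:::new_cna_solution(A, B, U, c(`1` = 1e5), 0,
                                     list(wgd = FALSE))
  muts <- tibble::tibble(chrom = "chr1", pos = c(10, 20), sample = "s1",
                         var_reads = c(30, 30), total_reads = 100)
  co <- function(chrom, pos) ifelse(pos == 10, "1", NA_character_)
  expect_warning(res <- assess_mutations(muts, sol, cluster_of = co),
                 "skipped")
  expect_equal(nrow(res$assessment), 1)
})
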