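fake_grid <- function(hyp, n, D, phi) {
  sols <- lapply(seq_along(n), function(i) {
    A <- matrix(1L, 2, n[i]); B <- matrix(1L, 2, n[i])
    U <- matrix(0, n[i], 1); U[1, 1] <- 1
    dimnames(A) <- dimnames(B) <- list(1:2, paste0("c", seq_len(n[i])))
    dimnames(U) <- list(paste0("c", seq_len(n[i])), "s1")
    s <- clonecna:::new_cna_solution(A, B, U, c(`1` = 1, `2` = 1), D[i],
                                     hypothesis = list(wgd = hyp[i] == "wgd"))
    s$phi <- phi[i]
    s
  })
  structure(tibble::tibble(hypothesis = hyp, n = n, objective = D,
                           phi = phi, solution = sols),
            class = c("model_grid", "tbl_df", "tbl", "data.frame"))
}

test_that("the elbow rule stops at the first negligible improvement", {
  g <- fake_grid(rep("no_wgd", 3), 2:4, c(100, 99, 98.5), rep(1000, 3))
  sol <- select_solution(g, tau = 0.05)
  expect_equal(ncol(sol$A), 2)

  # a large relative drop keeps growing n
  g2 <- fake_grid(rep("no_wgd", 3), 2:4, c(100, 40, 39), rep(1000, 3))
  expect_equal(ncol(select_solution(g2, tau = 0.05)$A), 3)
})

test_that("an infeasible WGD hypothesis leaves no-WGD selected", {
  g <- fake_grid(rep("no_wgd", 2), 2:3, c(50, 49), rep(1000, 2))
  sol <- select_solution(g)
  expect_false(sol$hypothesis$wgd)
})

test_that("hypothesis comparison is scale-aware with a WGD margin", {
  # same clone count; WGD distance must beat no-WGD by sqrt(phi ratio)
  g <- fake_grid(c("no_wgd", "wgd"), c(2, 2), c(10, 10), c(1000, 2000))
  # normalized: 0.01 vs 0.005; margin sqrt(2) -> 0.005*1.41 = 0.0071 < 0.01
  expect_true(select_solution(g)$hypothesis$wgd)
  g2 <- fake_grid(c("no_wgd", "wgd"), c(2, 2), c(10, 16), c(1000, 2000))
  # normalized: 0.01 vs 0.008; with margin 0.0113 > 0.01 -> no-WGD
  expect_false(select_solution(g2)$hypothesis$wgd)
  # fewer clones wins outright
  g3 <- fake_grid(c("no_wgd", "no_wgd", "wgd"), c(2, 3, 2),
                  c(100, 20, 30), c(1000, 1000, 2000))
  expect_true(select_solution(g3)$hypothesis$wgd)
})

test_that("warm-started grids are non-increasing in n", {
  set.seed(31)
  inst <- random_instance(m = 12, n = 3, k = 2, sigma = 0.06)
  fr <- structure(list(FA = inst$FA, FB = inst$FB, lengths = inst$lengths,
                       hypothesis = list(wgd = FALSE)),
                  class = "fractional_cn")
  g <- fit_model_grid(list(no_wgd = fr), n_max = 5, restarts = 4, seed = 2,
                      tau = 0) # tau 0 disables early stopping
  D <- g$objective[order(g$n)]
  expect_true(all(diff(D) <= 1e-9))
})

test_that("selected clone count stays near truth on noiseless input", {
  set.seed(32)
  for (rep in 1:3) {
    n_true <- sample(2:4, 1)
    inst <- random_instance(m = 15, n = n_true, k = 3)
    fr <- structure(list(FA = inst$FA, FB = inst$FB, lengths = inst$lengths,
                         hypothesis = list(wgd = FALSE)),
                    class = "fractional_cn")
    g <- fit_model_grid(list(no_wgd = fr), n_max = 6, restarts = 8,
                        seed = rep)
    sol <- select_solution(g)
    expect_lte(ncol(sol$A), n_true + 1)
  }
})

test_that("clusters are classified by state agreement among present clones", {
  A <- rbind(c(1L, 2L, 2L), c(1L, 2L, 3L), c(1L, 1L, 2L))
  B <- rbind(c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 0L))
  U <- rbind(c(0.3, 0.4), c(0.5, 0.6), c(0.2, 0.0))
  dimnames(A) <- dimnames(B) <- list(1:3, c("normal", "clone2", "clone3"))
  dimnames(U) <- list(c("normal", "clone2", "clone3"), c("s1", "s2"))
  sol <- clonecna:::new_cna_solution(A, B, U, c(`1` = 10, `2` = 20, `3` = 30),
                                     0, list(wgd = FALSE))
  cls <- classify_clusters(sol)
  ps <- cls$per_sample
  # cluster 1: both tumor clones share (2,1)-style state -> sample-clonal
  expect_true(ps$sample_clonal[ps$cluster == "1" & ps$sample == "s1"])
  # cluster 2: tumor clones differ and are both present in s1
  expect_false(ps$sample_clonal[ps$cluster == "2" & ps$sample == "s1"])
  # cluster 3: clone3 deviates but is absent in s2 -> clonal there
  expect_false(ps$sample_clonal[ps$cluster == "3" & ps$sample == "s1"])
  expect_true(ps$sample_clonal[ps$cluster == "3" & ps$sample == "s2"])
  expect_false(cls$per_cluster$tumor_clonal[2])
  expect_false(cls$per_cluster$tumor_clonal[3])
  expect_true(cls$per_cluster$tumor_clonal[1])
})

test_that("an n = 2 solution is clonal everywhere", {
  A <- cbind(1L, c(2L, 3L)); B <- cbind(1L, c(1L, 0L))
  U <- matrix(c(0.4, 0.6), 2, 1)
  dimnames(A) <- dimnames(B) <- list(1:2, c("normal", "clone2"))
  dimnames(U) <- list(c("normal", "clone2"), "s1")
  sol <- clonecna:::new_cna_solution(A, B, U, c(`1` = 1, `2` = 1), 0,
                                     list(wgd = FALSE))
  cls <- classify_clusters(sol)
  # normal and tumor differ, so bins are sample-subclonal when both present,
  # but tumor-clonal since there is a single tumor clone
  expect_true(all(cls$per_cluster$tumor_clonal))
})

test_that("per-sample summaries satisfy the purity-ploidy identity", {
  A <- rbind(c(1L, 2L, 2L), c(1L, 1L, 2L))
  B <- rbind(c(1L, 2L, 2L), c(1L, 1L, 1L))
  U <- rbind(c(0.3, 1.0), c(0.4, 0.0), c(0.3, 0.0))
  dimnames(A) <- dimnames(B) <- list(1:2, c("normal", "clone2", "clone3"))
  dimnames(U) <- list(c("normal", "clone2", "clone3"), c("s1", "s2"))
  lens <- c(`1` = 3e7, `2` = 7e7)
  sol <- clonecna:::new_cna_solution(A, B, U, lens, 0, list(wgd = TRUE))
  sm <- summarize_solution(sol)
  L <- sum(lens)
  C <- A + B
  Li <- as.numeric(t(C) %*% lens)
  for (p in 1:2) {
    mu <- sm$purity[p]
    if (mu > 0) {
      expect_equal(sm$ploidy[p] * mu * L, sum(U[-1, p] * Li[-1]))
    }
  }
  # pure-normal sample
  expect_equal(sm$purity[2], 0)
  expect_equal(sm$subclonal_fraction[2], 0)
  # cluster 2 (70% of genome) is subclonal in s1 (clone2/3 states differ)
  expect_equal(sm$subclonal_fraction[1], 0.7)
})

test_that("a single present tumor clone gives purity without subclonality", {
  A <- cbind(1L, c(2L, 3L)); B <- cbind(1L, c(1L, 1L))
  U <- matrix(c(0.3, 0.7), 2, 1)
  dimnames(A) <- dimnames(B) <- list(1:2, c("normal", "clone2"))
  dimnames(U) <- list(c("normal", "clone2"), "s1")
  sol <- clonecna:::new_cna_solution(A, B, U, c(`1` = 1, `2` = 1), 0,
                                     list(wgd = FALSE))
  sm <- summarize_solution(sol)
  expect_equal(sm$purity, 0.7)
  expect_equal(sm$subclonal_fraction, 0)
})
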