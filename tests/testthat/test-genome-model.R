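test_that("make_bins tiles chromosomes with truncation at the end", {
  b <- make_bins(c(chr1 = 150000), width = 50000)
  expect_equal(b$start, c(0, 50000, 100000))
  expect_equal(b$end, c(50000, 100000, 150000))

  b2 <- make_bins(c(chr1 = 120000), width = 50000)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$end[3], 120000)
  expect_equal(b2$start[3], 100000)

  b3 <- make_bins(c(chr1 = 49999), width = 50000)
  expect_equal(nrow(b3), 1)
  expect_equal(c(b3$start, b3$end), c(0, 49999))

  # lengths add up per chromosome
  b4 <- make_bins(c(chr1 = 123456, chr2 = 99999), width = 10000)
  lens <- tapply(b4$end - b4$start, b4$chrom, sum)
  expect_equal(as.numeric(lens), c(123456, 99999))

  expect_error(make_bins(setNames(numeric(0), character(0))), "chromosome")
})

test_that("sex and mitochondrial chromosomes are flagged excluded", {
  b <- make_bins(c(chr1 = 1e5, chrX = 1e5, Y = 1e5, chrM = 2e4))
  expect_equal(unique(b$excluded[b$chrom == "chr1"]), FALSE)
  expect_true(all(b$excluded[b$chrom != "chr1"]))
})

test_that("count tables round-trip through TSV and reject bad input", {
  bc <- toy_bin_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_counts(bc, path)
  back <- read_bin_counts(path)
  # the reader returns rows sorted by (chrom, start, sample)
  bc_sorted <- dplyr::arrange(bc, chrom, start, sample)
  expect_equal(back$tumor_reads, bc_sorted$tumor_reads)
  expect_equal(back$normal_reads, bc_sorted$normal_reads)
  expect_equal(back$sample, bc_sorted$sample)

  # negative count names the offending line
  txt <- readLines(path)
  txt[3] <- sub("700", "-700", txt[3])
  writeLines(txt, path)
  expect_error(read_bin_counts(path), "line 3")

  # malformed header
  writeLines(c("CHROM\tSTART", "chr1\t0"), path)
  expect_error(read_bin_counts(path), "header")
})

test_that("bin-count validation enforces completeness and consistency", {
  bc <- toy_bin_counts()
  expect_error(clonecna:::validate_bin_counts(as.data.frame(bc[-1, ])), "exactly once")
  bad <- as.data.frame(toy_bin_counts())
  bad$normal_reads[1] <- 999
  expect_error(clonecna:::validate_bin_counts(bad), "NORMAL_READS")
})

test_that("SNP and mutation tables validate their invariants", {
  snp <- tibble::tibble(chrom = "chr1", pos = c(100, 100), sample = "s1",
                        ref_reads = c(10, 10), alt_reads = c(5, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snp_counts(snp, path)
  expect_error(read_snp_counts(path), "Duplicated")

  mut <- tibble::tibble(chrom = "chr1", pos = 5, sample = "s1",
                        var_reads = 20, total_reads = 10)
  write_mutation_counts(mut, path)
  expect_error(read_mutation_counts(path), "exceeds")
})

test_that("simulator tables survive a write/read cycle unchanged", {
  pat <- quick_patient(seed = 5, genome_size = 2e7)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_bin_counts(pat$bin_counts, p1)
  back <- read_bin_counts(p1)
  expect_equal(back$tumor_reads,
               pat$bin_counts$tumor_reads[order(pat$bin_counts$chrom,
                                                pat$bin_counts$start,
                                                pat$bin_counts$sample)])
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_snp_counts(pat$snp_counts, p2)
  snp <- read_snp_counts(p2)
  expect_equal(nrow(snp), nrow(pat$snp_counts))
  expect_equal(sum(snp$alt_reads), sum(pat$snp_counts$alt_reads))
})

test_that("clone profiles round-trip A, B and U exactly", {
  set.seed(71)
  for (rep in 1:5) {
    inst <- random_instance(m = 6, n = 3, k = 2)
    sol <- clonecna:::new_cna_solution(
      A = inst$A, B = inst$B,
      U = matrix(inst$U, nrow = 3,
                 dimnames = list(c("normal", "clone2", "clone3"),
                                 c("s1", "s2"))),
      lengths = setNames(inst$lengths, seq_len(6)),
      objective = 0, hypothesis = list(wgd = FALSE))
    dimnames(sol$A) <- dimnames(sol$B) <-
      list(seq_len(6), c("normal", "clone2", "clone3"))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_clone_profile(sol, path)
    back <- read_clone_profile(path)
    expect_identical(unname(back$A), unname(inst$A))
    expect_identical(unname(back$B), unname(inst$B))
    expect_equal(unname(back$U), unname(inst$U), tolerance = 0)
    expect_equal(unname(as.numeric(back$lengths)), unname(inst$lengths))
  }
})

test_that("a normal-only profile writes 1|1 states for the normal clone", {
  A <- matrix(1L, 1, 2, dimnames = list("1", c("normal", "clone2")))
  U <- matrix(c(1, 0), 2, 1, dimnames = list(c("normal", "clone2"), "s1"))
  sol <- clonecna:::new_cna_solution(A = A, B = A, U = U,
                                     lengths = c("1" = 100), objective = 0,
                                     hypothesis = list(wgd = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clone_profile(sol, path)
  row <- read.delim(path, check.names = FALSE)
  expect_equal(row$normal, "1|1")
  back <- read_clone_profile(path)
  expect_equal(unname(back$U[, 1]), c(1, 0))
})
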