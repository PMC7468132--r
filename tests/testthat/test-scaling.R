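test_that("the balanced anchor is the largest cluster near BAF 0.5", {
  cents <- tidyr::expand_grid(cluster = 1:3, sample = c("s1", "s2"))
  cents$rdr <- 1
  cents$baf <- c(0.49, 0.49, 0.50, 0.50, 0.31, 0.31)[order(rep(1:3, each = 2))]
  cents <- tibble::tibble(cluster = rep(1:3, each = 2),
                          sample = rep(c("s1", "s2"), 3),
                          rdr = 1, baf = c(0.49, 0.49, 0.50, 0.50, 0.31, 0.31))
  cl <- fake_clustering(cents, lengths = c(30e6, 80e6, 10e6))
  expect_equal(find_diploid_anchor(cl), "2")

  single <- fake_clustering(tibble::tibble(cluster = 1, sample = "s1",
                                           rdr = 1, baf = 0.5), 1e6)
  expect_equal(find_diploid_anchor(single), "1")

  skewed <- fake_clustering(tibble::tibble(cluster = 1:2, sample = "s1",
                                           rdr = 1, baf = c(0.4, 0.35)),
                            c(1e6, 1e6))
  expect_error(find_diploid_anchor(skewed), "no balanced clonal cluster")
})

test_that("no-WGD scaling matches the closed form", {
  # r_anchor = 1.0, r_s = 1.5, beta = 1/3 -> f = 3, (fA, fB) = (2, 1)
  cents <- tibble::tibble(cluster = rep(1:2, each = 1), sample = "s1",
                          rdr = c(1.0, 1.5), baf = c(0.5, 1 / 3))
  cl <- fake_clustering(cents, c(50e6, 10e6))
  hyp <- list(wgd = FALSE, anchor1 = "1", omega1 = 2)
  fr <- scale_to_fractional(cl, hyp)
  expect_equal(unname(fr$FA["2", ] + fr$FB["2", ]), 3)
  expect_equal(unname(fr$FA["2", ]), 2)
  expect_equal(unname(fr$FB["2", ]), 1)
  # f^A + f^B = gamma * r for every cluster
  expect_equal(unname(fr$FA["1", ] + fr$FB["1", ]), 2)
})

test_that("WGD scaling solves the two-anchor linear system", {
  # worked example: omega = (4, 2), r = (1.0, 0.6) -> gamma = 10/3, u1 = 1/3
  cents <- tibble::tibble(cluster = rep(1:2, each = 1), sample = "s1",
                          rdr = c(1.0, 0.6), baf = c(0.5, 0.0))
  cl <- fake_clustering(cents, c(50e6, 20e6))
  hyp <- list(wgd = TRUE, anchor1 = "1", omega1 = 4, anchor2 = "2",
              omega2 = 2)
  fr <- scale_to_fractional(cl, hyp)
  expect_equal(unname(fr$gamma), 10 / 3, tolerance = 1e-12)
  expect_equal(unname(fr$u1), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(fr$FA["1", ] + fr$FB["1", ]), 10 / 3)
  expect_equal(unname(fr$FA["2", ] + fr$FB["2", ]), 2)
})

test_that("a pure-normal sample scales to f = 2 with equal alleles", {
  cents <- tibble::tibble(cluster = rep(1:2, each = 1), sample = "s1",
                          rdr = c(1, 1), baf = c(0.5, 0.5))
  cl <- fake_clustering(cents, c(5e7, 5e7))
  fr <- scale_to_fractional(cl, list(wgd = FALSE, anchor1 = "1", omega1 = 2))
  expect_equal(unname(fr$FA[, 1]), c(1, 1))
  expect_equal(unname(fr$FB[, 1]), c(1, 1))
})

test_that("scaling is invariant to rescaling a sample's RDRs", {
  cents <- tibble::tibble(cluster = rep(1:3, each = 1), sample = "s1",
                          rdr = c(1.0, 1.4, 0.7), baf = c(0.5, 0.37, 0.2))
  cl1 <- fake_clustering(cents, c(5e7, 1e7, 1e7))
  cents2 <- cents; cents2$rdr <- cents2$rdr * 3.7
  cl2 <- fake_clustering(cents2, c(5e7, 1e7, 1e7))
  hyp <- list(wgd = FALSE, anchor1 = "1", omega1 = 2)
  fr1 <- scale_to_fractional(cl1, hyp)
  fr2 <- scale_to_fractional(cl2, hyp)
  expect_equal(fr1$FA, fr2$FA)
  expect_equal(fr1$FB, fr2$FB)
})

test_that("the WGD second anchor obeys the identifiability inequality", {
  # candidate violating r_s' (w_z - 2) != r_z (w_s' - 2) must be skipped:
  # with anchor (2,2) (omega 4), a candidate with omega 2 fails when
  # r_z = 0 is impossible, so build r_z = r_anchor * (omega_z-2)/(omega_s'-2)
  expect_null(clonecna:::solve_wgd_system(1, 0, 4, 2))
  # degenerate omega pair (equal omegas) is always singular
  expect_null(clonecna:::solve_wgd_system(c(1, 1.2), c(1, 1.2), 4, 4))
  # u1 outside [0, 1] -> infeasible
  expect_null(clonecna:::solve_wgd_system(1, 2, 4, 2))
})

test_that("second-anchor search finds a pre-WGD deletion state", {
  # truth: WGD tumor, u1 = 0.4 across two samples; cluster 2 is (2,0)
  u1 <- c(0.4, 0.25)
  f_anchor <- 2 * u1 + 4 * (1 - u1)
  f_z <- 2 * u1 + 2 * (1 - u1)
  gamma <- 1.1 # arbitrary RDR scale absorbed per sample
  cents <- tibble::tibble(
    cluster = rep(1:2, each = 2), sample = rep(c("s1", "s2"), 2),
    rdr = c(f_anchor, f_z) / gamma,
    baf = c(0.5, 0.5, u1[1] / (2 * u1[1] + 2 * (1 - u1[1])),
            u1[2] / (2 * u1[2] + 2 * (1 - u1[2]))))
  cl <- fake_clustering(cents, c(6e7, 2e7))
  second <- find_second_anchor(cl, anchor = "1")
  expect_equal(second$cluster, "2")
  expect_equal(second$omega, 2)
  expect_equal(second$state, c(2L, 0L))
  fr <- scale_to_fractional(cl, list(wgd = TRUE, anchor1 = "1", omega1 = 4,
                                     anchor2 = "2", omega2 = 2))
  expect_equal(unname(fr$u1), u1, tolerance = 1e-9)
})

test_that("noiseless simulator clusters are scaled back exactly", {
  # clusters from true states and proportions; RDR computed analytically
  set.seed(21)
  inst <- random_instance(m = 8, n = 3, k = 2, theta = 1)
  inst$A[1, ] <- 1; inst$B[1, ] <- 1 # guarantee a diploid cluster
  Ctot <- inst$A + inst$B
  f <- Ctot %*% inst$U
  fa <- inst$A %*% inst$U
  lens <- inst$lengths * 1e7
  denom <- colSums(lens * f) / (2 * sum(lens))
  rdr <- sweep(f, 2, 2 * denom, `/`)
  baf <- pmin((f - fa) / f, 1)
  cents <- tibble::tibble(
    cluster = rep(seq_len(8), each = 2),
    sample = rep(c("s1", "s2"), 8),
    rdr = as.vector(t(rdr)), baf = as.vector(t(baf)))
  cl <- fake_clustering(cents, lens)
  fr <- scale_to_fractional(cl, list(wgd = FALSE, anchor1 = "1",
                                     omega1 = 2))
  expect_equal(unname(fr$FA + fr$FB), unname(f), tolerance = 1e-9)
})
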