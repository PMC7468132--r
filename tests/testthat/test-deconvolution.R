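test_that("the factorization distance is the length-weighted L1 norm", {
  set.seed(1)
  inst <- random_instance(m = 5, n = 3, k = 2)
  expect_equal(cacf_objective(inst$FA, inst$FB, inst$A, inst$B, inst$U,
                              inst$lengths), 0)
  # 1 cluster, 1 sample, l = 10, |dA| = 0.2, |dB| = 0.1 -> D = 3
  A <- matrix(c(1L, 2L), 1); B <- matrix(c(1L, 1L), 1)
  U <- matrix(c(0.4, 0.6), 2)
  FA <- A %*% U + 0.2; FB <- B %*% U - 0.1
  expect_equal(cacf_objective(FA, FB, A, B, U, 10), 3.0)
  # doubling lengths doubles D
  expect_equal(cacf_objective(FA, FB, A, B, U, 20), 6.0)
  expect_error(cacf_objective(FA, FB, A, B, U[1, , drop = FALSE], 10),
               "conformable")
})

test_that("the integer update recovers true states with known proportions", {
  set.seed(2)
  for (rep in 1:10) {
    inst <- random_instance(m = 10, n = 2, k = 2)
    res <- update_copy_numbers(inst$FA, inst$FB, inst$U, inst$lengths)
    expect_equal(unname(res$A), unname(inst$A))
    expect_equal(unname(res$B), unname(inst$B))
    # closed form for one tumor clone: a = round((fA - u1) / u2)
    u <- inst$U[, 1]
    if (u[2] > 0.1) {
      a_closed <- round((inst$FA[, 1] - u[1]) / u[2])
      expect_equal(unname(res$A[, 2]), pmax(pmin(a_closed, 12), 0))
    }
  }
})

test_that("integer-fit ties break toward the theta-near state", {
  # f^A exactly midway between integer fits
  U <- matrix(c(0.5, 0.5), 2)
  FA <- matrix(0.5 * 1 + 0.5 * 1.5) # midway between a = 1 and a = 2
  FB <- matrix(0.5 * 1 + 0.5 * 0.5) # midway between b = 0 and b = 1
  res <- update_copy_numbers(FA, FB, U, 1, cmax = 12, theta = 1)
  expect_equal(unname(res$A[1, 2]), 1)
  expect_equal(unname(res$B[1, 2]), 1)
})

test_that("both coordinate updates never increase the objective", {
  set.seed(3)
  for (rep in 1:5) {
    inst <- random_instance(m = 12, n = 3, k = 2, sigma = 0.08)
    U <- clonecna:::random_u(3, 2, 0.03)
    D_prev <- Inf
    for (it in 1:6) {
      ab <- update_copy_numbers(inst$FA, inst$FB, U, inst$lengths)
      D1 <- cacf_objective(inst$FA, inst$FB, ab$A, ab$B, U, inst$lengths)
      expect_lte(D1, D_prev + 1e-9)
      U <- update_proportions(inst$FA, inst$FB, ab$A, ab$B, inst$lengths)
      D_prev <- cacf_objective(inst$FA, inst$FB, ab$A, ab$B, U, inst$lengths)
      expect_lte(D_prev, D1 + 1e-9)
    }
  }
})

test_that("proportion updates return exact semi-continuous minimizers", {
  set.seed(4)
  # pure normal fractional profile -> all mass on the normal clone
  A <- cbind(1L, c(3L, 2L, 0L)); B <- cbind(1L, c(1L, 0L, 0L))
  FA <- matrix(1, 3, 1); FB <- matrix(1, 3, 1)
  U <- update_proportions(FA, FB, A, B, rep(1, 3))
  expect_equal(unname(U[, 1]), c(1, 0))

  # noiseless two-clone mixture: exact recovery
  inst <- random_instance(m = 15, n = 3, k = 2)
  U2 <- update_proportions(inst$FA, inst$FB, inst$A, inst$B, inst$lengths)
  expect_equal(unname(U2), unname(inst$U), tolerance = 1e-7)

  # semi-continuity: proportions are 0 or >= umin
  inst3 <- random_instance(m = 10, n = 4, k = 2, sigma = 0.1)
  U3 <- update_proportions(inst3$FA, inst3$FB, inst3$A, inst3$B,
                           inst3$lengths, umin = 0.1)
  tum <- U3[-1, ]
  expect_true(all(tum == 0 | tum >= 0.1 - 1e-9))
  expect_equal(colSums(U3), rep(1, 2))

  # against a fine grid oracle for one tumor clone
  inst4 <- random_instance(m = 8, n = 2, k = 1, sigma = 0.05)
  U4 <- update_proportions(inst4$FA, inst4$FB, inst4$A, inst4$B,
                           inst4$lengths)
  obj <- function(mu) {
    u <- c(1 - mu, mu)
    sum(inst4$lengths * (abs(inst4$FA - inst4$A %*% u) +
                           abs(inst4$FB - inst4$B %*% u)))
  }
  grid_best <- min(sapply(c(0, seq(0.03, 1, 5e-4)), obj))
  expect_lte(obj(U4[2, 1]), grid_best + 1e-8)
})

test_that("coordinate descent recovers noiseless factorizations", {
  set.seed(5)
  ok <- 0
  for (rep in 1:5) {
    inst <- random_instance(m = 20, n = 3, k = 3)
    sol <- solve_cacf_cd(inst$FA, inst$FB, inst$lengths, n = 3,
                         restarts = 10, seed = rep)
    expect_lt(sol$objective, 1e-6)
    if (same_up_to_permutation(sol, inst$A, inst$B, inst$U, tol = 1e-5)) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
})

test_that("coordinate descent is deterministic and monotone in restarts", {
  set.seed(6)
  inst <- random_instance(m = 10, n = 3, k = 2, sigma = 0.1)
  s1 <- solve_cacf_cd(inst$FA, inst$FB, inst$lengths, n = 3, restarts = 1,
                      seed = 9)
  s20 <- solve_cacf_cd(inst$FA, inst$FB, inst$lengths, n = 3, restarts = 20,
                       seed = 9)
  expect_lte(s20$objective, s1$objective + 1e-12)
  s20b <- solve_cacf_cd(inst$FA, inst$FB, inst$lengths, n = 3, restarts = 20,
                        seed = 9)
  expect_identical(s20$U, s20b$U)
  expect_identical(s20$A, s20b$A)
})

test_that("a pure-normal profile yields no active tumor clone", {
  FA <- matrix(1, 6, 2); FB <- matrix(1, 6, 2)
  sol <- solve_cacf_cd(FA, FB, rep(1, 6), n = 2, restarts = 5, seed = 1)
  dup <- all(sol$A[, 2] == 1 & sol$B[, 2] == 1)
  expect_true(all(sol$U[2, ] == 0) || dup)
  expect_lt(sol$objective, 1e-9)
})

test_that("duplicate clones are merged into a canonical solution", {
  set.seed(7)
  inst <- random_instance(m = 10, n = 2, k = 2)
  # ask for more clones than the data supports on noiseless input
  sol <- solve_cacf_cd(inst$FA, inst$FB, inst$lengths, n = 4, restarts = 5,
                       seed = 3)
  expect_lt(sol$objective, 1e-6)
  states <- apply(rbind(sol$A, sol$B), 2, paste, collapse = ",")
  expect_equal(anyDuplicated(states[-1]), 0)
})

test_that("the exact solver dominates coordinate descent on small instances", {
  set.seed(8)
  worse <- 0
  for (rep in 1:8) {
    inst <- random_instance(m = 8, n = 2, k = 2, sigma = 0.04)
    ex <- solve_cacf_exact(inst$FA, inst$FB, inst$lengths)
    cd <- solve_cacf_cd(inst$FA, inst$FB, inst$lengths, n = 2,
                        restarts = 10, seed = rep)
    expect_gte(cd$objective, ex$objective - 1e-6)
    if (cd$objective > ex$objective + 1e-6) worse <- worse + 1
    # noiseless instances reach zero
    ex0 <- solve_cacf_exact(inst$A %*% inst$U, inst$B %*% inst$U,
                            inst$lengths)
    expect_lt(ex0$objective, 1e-9)
  }
  expect_lte(worse, 2)
})

test_that("the grid phase agrees with exhaustive enumeration at m = 1", {
  set.seed(9)
  for (rep in 1:3) {
    inst <- random_instance(m = 1, n = 2, k = 2, sigma = 0.05)
    ex <- solve_cacf_exact(inst$FA, inst$FB, inst$lengths, polish = 0)
    states <- expand.grid(a = 0:12, b = 0:12)
    states <- states[states$a + states$b <= 12, ]
    grid <- c(0, seq(0.03, 1, 0.01))
    best <- Inf
    for (i in seq_len(nrow(states))) {
      aa <- c(1, states$a[i]); bb <- c(1, states$b[i])
      for (g1 in grid) for (g2 in grid) {
        d <- inst$lengths *
          (abs(inst$FA[1] - sum(aa * c(1 - g1, g1))) +
             abs(inst$FB[1] - sum(bb * c(1 - g1, g1))) +
             abs(inst$FA[2] - sum(aa * c(1 - g2, g2))) +
             abs(inst$FB[2] - sum(bb * c(1 - g2, g2))))
        if (d < best) best <- d
      }
    }
    expect_equal(ex$objective, best, tolerance = 1e-9)
  }
})

test_that("the exact solver guard rejects oversized instances", {
  inst <- random_instance(m = 30, n = 2, k = 2)
  expect_error(solve_cacf_exact(inst$FA, inst$FB, inst$lengths), "guard")
})
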