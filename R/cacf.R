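#' Length-weighted L1 factorization distance
#'
#' `D = ||FA - AU|| + ||FB - BU||` where
#' `||X - Y|| = sum_s sum_p l_s |x_sp - y_sp|` weights every cluster by its
#' genomic length.
#'
#' @param FA,FB Fractional copy-number matrices (clusters x samples).
#' @param A,B Integer allele-specific copy-number matrices (clusters x
#'   clones, first column the diploid normal clone).
#' @param U Clone-proportion matrix (clones x samples, columns on the
#'   simplex).
#' @param lengths Cluster genomic lengths.
#' @return The distance `D` (scalar).
#' @export
cacf_objective <- function(FA, FB, A, B, U, lengths) {
  if (nrow(FA) != nrow(A) || ncol(A) != nrow(U) || ncol(U) != ncol(FA) ||
      !all(dim(FA) == dim(FB)) || !all(dim(A) == dim(B)) ||
      length(lengths) != nrow(FA)) {
    abort("Non-conformable shapes in factorization objective.")
  }
  RA <- abs(FA - A %*% U)
  RB <- abs(FB - B %*% U)
  sum(lengths * (rowSums(RA) + rowSums(RB)))
}

#' Exact integer copy-number update for fixed proportions
#'
#' Minimizes the factorization distance over integer `A`, `B` with the
#' proportions fixed. The objective separates by cluster; each cluster is
#' solved exactly by enumeration of tumor-clone copy vectors subject to the
#' maximum total copy number and the one-sided (theta-separation)
#' evolutionary constraint. Ties are broken toward states nearest
#' `(theta, theta)`, then lexicographically.
#'
#' @inheritParams cacf_objective
#' @param cmax Maximum total copy number per clone (default 12).
#' @param theta Separation pivot: 1 without WGD, 2 with WGD.
#' @return List with integer matrices `A`, `B` and the achieved `objective`.
#' @export
update_copy_numbers <- function(FA, FB, U, lengths, cmax = 12, theta = 1) {
  res <- cacf_update_ab(FA, FB, as.numeric(lengths), U, as.integer(cmax),
                        as.integer(theta))
  dimnames(res$A) <- dimnames(res$B) <- list(rownames(FA), rownames(U))
  res
}

#' Exact proportion update for fixed copy numbers
#'
#' Per sample, minimizes the weighted-L1 distance over the simplex with the
#' semi-continuity constraint that every tumor-clone proportion is either 0
#' or at least `umin`. The relaxed problem is a linear program; the
#' disjunction is resolved exactly by branch and bound on the violating
#' clones, pruning with LP lower bounds (equivalent to enumerating clone
#' supports, but typically solving a handful of LPs).
#'
#' @inheritParams update_copy_numbers
#' @param umin Minimum tumor-clone proportion (default 0.03).
#' @return The updated proportion matrix `U`.
#' @export
update_proportions <- function(FA, FB, A, B, lengths, umin = 0.03,
                               U_prev = NULL) {
  n <- ncol(A); m <- nrow(A); k <- ncol(FA)
  U <- matrix(0, n, k, dimnames = list(colnames(A), colnames(FA)))
  for (p in seq_len(k)) {
    u0 <- if (!is.null(U_prev)) U_prev[, p]
    U[, p] <- if (n == 2) {
      solve_u_sample_1d(FA[, p], FB[, p], A, B, as.numeric(lengths), umin)
    } else {
      solve_u_sample(FA[, p], FB[, p], A, B, as.numeric(lengths), umin,
                     u_start = u0)
    }
  }
  U
}

# exact 1-D minimization for a single tumor clone: the objective is convex
# piecewise linear in the purity, so the optimum lies at a residual
# breakpoint or at a bound; the mu = 0 branch is checked separately
solve_u_sample_1d <- function(fa, fb, A, B, lens, umin) {
  cand <- c(umin, 1,
            (fa - 1) / (A[, 2] - 1), (fb - 1) / (B[, 2] - 1))
  cand <- cand[is.finite(cand) & cand >= umin & cand <= 1]
  cand <- unique(c(cand, umin, 1))
  m <- length(fa)
  obj <- function(mu) {
    RA <- abs(matrix(fa - 1, m, length(mu)) + outer(1 - A[, 2], mu))
    RB <- abs(matrix(fb - 1, m, length(mu)) + outer(1 - B[, 2], mu))
    colSums(lens * (RA + RB))
  }
  vals <- obj(cand)
  best <- which.min(vals)
  zero <- sum(lens * (abs(fa - 1) + abs(fb - 1)))
  if (zero <= vals[best]) c(1, 0) else c(1 - cand[best], cand[best])
}

# branch-and-bound over the {0} vs [umin, 1] disjunction for one sample;
# the relaxation is convex (sum of absolute affine terms), each node an LP
solve_u_sample <- function(fa, fb, A, B, lens, umin, tol = 1e-7,
                           u_start = NULL) {
  n <- ncol(A); m <- nrow(A)
  cc <- c(rep(0, n), lens, lens)
  ZA <- matrix(0, m, m)
  base_ub <- rbind(cbind(A, -diag(m), ZA), cbind(-A, -diag(m), ZA),
                   cbind(B, ZA, -diag(m)), cbind(-B, ZA, -diag(m)))
  base_rhs <- c(fa, -fa, fb, -fb)
  Aeq <- matrix(c(rep(1, n), rep(0, 2 * m)), 1)
  solve_node <- function(zero, atleast) {
    A_ub <- base_ub; rhs <- base_rhs
    for (i in atleast) {
      row <- rep(0, n + 2 * m); row[i] <- -1
      A_ub <- rbind(A_ub, row); rhs <- c(rhs, -umin)
    }
    A_eq <- Aeq; beq <- 1
    for (i in zero) {
      row <- rep(0, n + 2 * m); row[i] <- 1
      A_eq <- rbind(A_eq, row); beq <- c(beq, 0)
    }
    res <- simplex_lp(cc, A_ub, rhs, A_eq, beq)
    if (res$status != 0) return(NULL)
    list(u = res$x[seq_len(n)], value = res$value)
  }
  best_u <- c(1, rep(0, n - 1))
  best_val <- sum(lens * (abs(fa - A %*% best_u) + abs(fb - B %*% best_u)))
  if (!is.null(u_start) &&
      all(u_start[-1] == 0 | u_start[-1] >= umin) && sum(u_start) > 0) {
    u_start <- u_start / sum(u_start)
    v <- sum(lens * (abs(fa - A %*% u_start) + abs(fb - B %*% u_start)))
    if (v < best_val) { best_u <- u_start; best_val <- v }
  }
  nodes <- list(list(zero = integer(), atleast = integer()))
  while (length(nodes) > 0) {
    node <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    sol <- solve_node(node$zero, node$atleast)
    if (is.null(sol) || sol$value >= best_val - 1e-12) next
    u <- sol$u
    viol <- setdiff(which(u[-1] > tol & u[-1] < umin - tol) + 1,
                    c(node$zero, node$atleast))
    if (length(viol) == 0) {
      u[u < tol] <- 0
      u <- u / sum(u)
      best_u <- u
      best_val <- sol$value
    } else {
      i <- viol[1]
      nodes[[length(nodes) + 1]] <- list(zero = c(node$zero, i),
                                         atleast = node$atleast)
      nodes[[length(nodes) + 1]] <- list(zero = node$zero,
                                         atleast = c(node$atleast, i))
    }
  }
  best_u
}

new_cna_solution <- function(A, B, U, lengths, objective, hypothesis,
                             method = "cd", n = ncol(A), converged = NA,
                             iterations = NA_integer_) {
  structure(list(A = A, B = B, U = U, lengths = lengths,
                 objective = objective, hypothesis = hypothesis,
                 method = method, n = n, converged = converged,
                 iterations = iterations, samples = colnames(U)),
            class = "cna_solution")
}

#' Coordinate-descent solver for the constrained factorization
#'
#' Alternates the exact integer copy-number update and the exact proportion
#' update from multiple random initializations of `U`, keeping the best
#' final distance. The distance is non-increasing across iterations because
#' both updates are exact minimizers of their coordinate block. After
#' convergence, tumor clones with identical state vectors are merged
#' (proportions summed) and clones are ordered by decreasing total
#' proportion for a deterministic representation.
#'
#' @inheritParams update_copy_numbers
#' @inheritParams update_proportions
#' @param n Number of clones including the diploid normal (n >= 2).
#' @param restarts Number of random restarts (default 10).
#' @param max_iter Maximum coordinate-descent iterations (default 50).
#' @param tol Convergence threshold on the distance decrease (default 1e-6).
#' @param seed Integer seed; deterministic given the seed.
#' @param theta Separation pivot: 1 without WGD, 2 with WGD.
#' @param wgd Logical recorded in the solution's hypothesis slot.
#' @param init Optional list of warm-start `U` matrices tried in addition
#'   to the random restarts.
#' @param hierarchical When `n > 2`, additionally warm-start from the
#'   solved `n - 1` problem with its largest clone split (default TRUE;
#'   disabled inside the model grid, which provides its own warm starts).
#' @return A `cna_solution` object.
#' @export
solve_cacf_cd <- function(FA, FB, lengths, n, cmax = 12, umin = 0.03,
                          theta = 1, restarts = 10, max_iter = 50,
                          tol = 1e-6, seed = 1, wgd = theta >= 2,
                          init = NULL, hierarchical = TRUE) {
  stopifnot(n >= 2, cmax >= 2, umin > 0, umin < 1)
  m <- nrow(FA); k <- ncol(FA)
  samples <- colnames(FA)
  if (is.null(samples)) samples <- paste0("sample", seq_len(k))
  clones <- c("normal", if (n > 1) paste0("clone", seq_len(n - 1) + 1))
  init <- c(init, if (hierarchical && n > 2) {
    # random initializations rarely land in the right basin jointly for
    # many clones and samples; seed one start from the solved (n-1)-clone
    # problem with its largest clone split
    sub <- if (n - 1 == 2 && k <= 2 && m <= 25) {
      # globally solved two-clone base (grid search over purity)
      solve_cacf_exact(FA, FB, lengths, cmax = cmax, umin = umin,
                       theta = theta, wgd = wgd)
    } else {
      solve_cacf_cd(FA, FB, lengths, n - 1, cmax = cmax, umin = umin,
                    theta = theta, restarts = max(3, restarts %/% 2),
                    max_iter = max_iter, tol = tol, seed = seed + 7919,
                    wgd = wgd)
    }
    U_sub <- sub$U
    if (nrow(U_sub) < n) {
      # duplicate clones may have been merged; pad back to n - 1 rows
      U_sub <- rbind(U_sub, matrix(0, n - 1 - nrow(U_sub), k))
    }
    # one warm start per split clone (small true clones can hide in any)
    lapply(seq_len(nrow(U_sub)), function(i) {
      U0 <- U_sub
      newrow <- U0[i, ] / 2
      U0[i, ] <- U0[i, ] / 2
      unname(rbind(U0, newrow))
    })
  })
  set.seed(seed)
  inits <- lapply(seq_len(restarts), function(r) random_u(n, k, umin))
  # deterministic purity ladder: the objective is rugged in the tumor
  # purity, with basins a few percent wide at low purity and high copy
  # number; random draws alone miss them
  ladder <- lapply(seq(0.08, 0.92, by = 0.07), function(mu) {
    matrix(rep(c(1 - mu, rep(mu / (n - 1), n - 1)), k), n, k)
  })
  # per-sample purity scan: grid the single-tumor-clone relaxation of each
  # sample independently (states free per sample, a lower bound) and
  # combine the best per-sample purities
  scan <- purity_scan_inits(FA, FB, lengths, n, cmax, umin)
  inits <- c(inits, ladder, scan, init)
  cd_from <- function(U0) {
    U <- U0
    D_prev <- Inf
    res_ab <- NULL
    # fast phase: cheap exact pairwise-transfer proportion updates
    for (it in seq_len(max_iter)) {
      res_ab <- update_copy_numbers(FA, FB, U, lengths, cmax, theta)
      U <- update_proportions_fast(FA, FB, res_ab$A, res_ab$B, lengths,
                                   umin, U)
      D <- cacf_objective(FA, FB, res_ab$A, res_ab$B, U, lengths)
      if (is.finite(D_prev) && D_prev - D < tol) { D_prev <- D; break }
      D_prev <- D
    }
    # polish phase: the exact joint proportion minimizer
    for (it2 in seq_len(5)) {
      res_ab <- update_copy_numbers(FA, FB, U, lengths, cmax, theta)
      U <- update_proportions(FA, FB, res_ab$A, res_ab$B, lengths, umin,
                              U_prev = U)
      D <- cacf_objective(FA, FB, res_ab$A, res_ab$B, U, lengths)
      if (D_prev - D < tol) { D_prev <- min(D, D_prev); break }
      D_prev <- D
    }
    list(A = res_ab$A, B = res_ab$B, U = U, D = D_prev, it = it)
  }
  best <- NULL
  pool <- list()
  for (U0 in inits) {
    fit <- cd_from(U0)
    pool[[length(pool) + 1]] <- fit
    if (is.null(best) || fit$D < best$D) best <- fit
  }
  # crossover: stuck solutions typically misfit a single sample; combine
  # per-sample proportion columns of the best distinct restarts
  if (k > 1 && best$D > tol) {
    Ds <- vapply(pool, `[[`, numeric(1), "D")
    top <- pool[order(Ds)]
    keep <- list(top[[1]])
    for (f in top[-1]) {
      if (length(keep) >= 3) break
      if (all(vapply(keep, function(g) max(abs(g$U - f$U)) > 0.02,
                     logical(1)))) {
        keep[[length(keep) + 1]] <- f
      }
    }
    if (length(keep) >= 2) {
      for (a in seq_along(keep)) for (b in seq_along(keep)) {
        if (a == b) next
        for (p in seq_len(k)) {
          U0 <- keep[[a]]$U
          U0[, p] <- keep[[b]]$U[, p]
          fit <- cd_from(U0)
          if (fit$D < best$D - tol) best <- fit
        }
      }
    }
  }
  # basin hopping: coordinate descent gets trapped in solutions where one
  # sample's normal and tumor proportions are exchanged with compensating
  # state errors; restart from systematic neighbor moves of the incumbent
  for (round in seq_len(3)) {
    if (best$D <= tol) break
    improved <- FALSE
    for (p in seq_len(k)) {
      for (i in seq_len(n - 1) + 1) {
        swap <- best$U
        swap[c(1, i), p] <- swap[c(i, 1), p]
        drop <- best$U
        drop[1, p] <- drop[1, p] + drop[i, p]
        drop[i, p] <- 0
        for (U0 in list(swap, drop)) {
          if (sum(U0[, p]) <= 0) next
          fit <- cd_from(U0)
          if (fit$D < best$D - tol) { best <- fit; improved <- TRUE }
        }
      }
    }
    # perturbation hops around the incumbent
    for (r in seq_len(8)) {
      U0 <- best$U + matrix(stats::rgamma(n * k, 0.4), n, k) * 0.3
      U0 <- sweep(U0, 2, colSums(U0), `/`)
      fit <- cd_from(U0)
      if (fit$D < best$D - tol) { best <- fit; improved <- TRUE }
    }
    if (!improved) break
  }
  U <- best$U
  dimnames(U) <- list(clones, samples)
  sol <- new_cna_solution(best$A, best$B, U, lengths, best$D,
                          hypothesis = list(wgd = wgd, theta = theta),
                          n = n, converged = TRUE, iterations = best$it)
  dimnames(sol$A) <- dimnames(sol$B) <- list(rownames(FA), clones)
  canonicalize_solution(sol)
}

# fast inner-loop proportion update: exact 1-D mass transfers between
# clone pairs, cycled to a fixed point. The per-sample objective is convex
# piecewise linear, so each transfer optimum lies at a residual breakpoint
# or bound; the semi-continuity is honored by also testing the zero point.
# Not an exact joint minimizer (kinks can stall cyclic moves), so the
# solver polishes with the exact LP update at convergence.
update_proportions_fast <- function(FA, FB, A, B, lengths, umin, U) {
  lens <- as.numeric(lengths)
  n <- ncol(A); k <- ncol(FA)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  for (p in seq_len(k)) {
    u <- U[, p]
    fa <- FA[, p]; fb <- FB[, p]
    for (sweep in 1:25) {
      changed <- FALSE
      for (q in seq_len(nrow(pairs))) {
        i <- pairs[q, 1]; j <- pairs[q, 2]
        tot <- u[i] + u[j]
        if (tot <= 0) next
        rest_a <- fa - as.vector(A %*% u) + A[, i] * u[i] + A[, j] * u[j]
        rest_b <- fb - as.vector(B %*% u) + B[, i] * u[i] + B[, j] * u[j]
        da <- A[, j] - A[, i]; db <- B[, j] - B[, i]
        # residuals as functions of t = u_j: |rest - A_i tot - da t|
        ca <- rest_a - A[, i] * tot
        cb <- rest_b - B[, i] * tot
        cand <- c(0, tot, umin, tot - umin,
                  ca[da != 0] / da[da != 0], cb[db != 0] / db[db != 0])
        cand <- unique(cand[cand >= 0 & cand <= tot])
        # enforce semi-continuity for tumor clones
        ok <- rep(TRUE, length(cand))
        if (j > 1) ok <- ok & (cand == 0 | cand >= umin)
        if (i > 1) ok <- ok & (tot - cand == 0 | tot - cand >= umin)
        cand <- cand[ok]
        if (length(cand) == 0) next
        L <- length(cand)
        obj <- colSums(lens * (abs(matrix(ca, length(ca), L) -
                                     outer(da, cand)) +
                                 abs(matrix(cb, length(cb), L) -
                                       outer(db, cand))))
        tbest <- cand[which.min(obj)]
        if (abs(tbest - u[j]) > 1e-12) {
          u[j] <- tbest; u[i] <- tot - tbest
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    U[, p] <- u
  }
  U
}

# top local minima of the per-sample single-clone purity scan, combined
# across samples into joint initializations
purity_scan_inits <- function(FA, FB, lengths, n, cmax, umin, top = 3) {
  k <- ncol(FA); m <- nrow(FA)
  lens <- as.numeric(lengths)
  states <- expand.grid(a = 0:cmax, b = 0:cmax)
  states <- states[states$a + states$b <= cmax, , drop = FALSE]
  mus <- seq(umin, 0.99, by = 0.01)
  picks <- vector("list", k)
  for (p in seq_len(k)) {
    D_mu <- vapply(mus, function(mu) {
      pa <- 1 - mu + states$a * mu
      pb <- 1 - mu + states$b * mu
      sum(lens * vapply(seq_len(m), function(s) {
        min(abs(FA[s, p] - pa) + abs(FB[s, p] - pb))
      }, numeric(1)))
    }, numeric(1))
    # local minima of the scan, best first
    loc <- which(diff(sign(diff(c(Inf, D_mu, Inf)))) > 0)
    picks[[p]] <- mus[head(loc[order(D_mu[loc])], top)]
  }
  lens_ok <- vapply(picks, length, integer(1)) > 0
  if (!all(lens_ok)) return(list())
  combos <- list(vapply(picks, `[`, numeric(1), 1))
  if (all(vapply(picks, length, integer(1)) >= 2)) {
    combos <- c(combos, list(vapply(picks, `[`, numeric(1), 2)))
  }
  for (p in seq_len(k)) {
    if (length(picks[[p]]) >= 2) {
      v <- vapply(picks, `[`, numeric(1), 1)
      v[p] <- picks[[p]][2]
      combos <- c(combos, list(v))
    }
  }
  lapply(unique(combos), function(mu) {
    rbind(1 - mu, matrix(rep(mu / (n - 1), n - 1), n - 1, k, byrow = TRUE))
  })
}

random_u <- function(n, k, umin) {
  # Dirichlet columns with random sparsity: true clone-presence patterns
  # are often sparse per sample, and dense initializations rarely reach
  # those basins
  alpha <- stats::runif(1, 0.4, 1)
  U <- matrix(stats::rgamma(n * k, alpha), n, k)
  zero <- matrix(stats::runif((n - 1) * k) < stats::runif(1, 0, 0.5),
                 n - 1, k)
  U[-1, ][zero] <- 0
  U[1, ] <- pmax(U[1, ], 1e-3)
  for (p in seq_len(k)) {
    if (sum(U[-1, p]) == 0) U[2, p] <- 1
    U[, p] <- U[, p] / sum(U[, p])
    drop <- which(U[-1, p] > 0 & U[-1, p] < umin) + 1
    U[drop, p] <- 0
    U[, p] <- U[, p] / sum(U[, p])
  }
  U
}

# merge duplicate tumor clones and order by decreasing total proportion
canonicalize_solution <- function(sol) {
  A <- sol$A; B <- sol$B; U <- sol$U
  nt <- ncol(A) - 1
  if (nt >= 2) {
    key <- vapply(seq_len(nt) + 1L,
                  function(i) paste(A[, i], B[, i], collapse = ","),
                  character(1))
    groups <- split(seq_len(nt) + 1L, key)
    if (length(groups) < nt) {
      keep <- vapply(groups, `[`, integer(1), 1)
      merged <- do.call(rbind, lapply(groups, function(g) {
        colSums(U[g, , drop = FALSE])
      }))
      Unew <- rbind(U[1, , drop = FALSE], merged)
      A <- cbind(A[, 1, drop = FALSE], A[, keep, drop = FALSE])
      B <- cbind(B[, 1, drop = FALSE], B[, keep, drop = FALSE])
      U <- Unew
    }
  }
  nt <- ncol(A) - 1
  if (nt >= 1) {
    tot <- rowSums(U)[-1]
    keys <- vapply(seq_len(nt) + 1,
                   function(i) paste(A[, i], B[, i], collapse = ","),
                   character(1))
    ord <- order(-tot, keys) + 1
    A <- cbind(A[, 1, drop = FALSE], A[, ord, drop = FALSE])
    B <- cbind(B[, 1, drop = FALSE], B[, ord, drop = FALSE])
    U <- rbind(U[1, , drop = FALSE], U[ord, , drop = FALSE])
  }
  clones <- c("normal", if (nt >= 1) paste0("clone", seq_len(nt) + 1))
  dimnames(A) <- dimnames(B) <- list(rownames(sol$A), clones)
  dimnames(U) <- list(clones, colnames(sol$U))
  sol$A <- A; sol$B <- B; sol$U <- U
  sol$n <- ncol(A)
  sol
}

#' Exact small-instance solver on a discretized proportion grid
#'
#' Global minimizer of the constrained factorization distance for a single
#' tumor clone (`n = 2`) with tumor purity discretized on a grid (step
#' 0.01 by default). All copy-number states and all grid purities per
#' sample are enumerated jointly, so the result is the global optimum of
#' the grid-discretized problem and serves as the reference the
#' coordinate-descent solver is compared against.
#'
#' The grid search is followed (by default) by a polish phase: the exact
#' coordinate updates (integer states, then the continuous proportion LP)
#' are iterated from the best grid points, so the reported optimum lives in
#' the same continuous solution space as the coordinate-descent solver and
#' bounds it from below.
#'
#' @inheritParams solve_cacf_cd
#' @param grid_step Purity discretization step (default 0.01).
#' @param force Bypass the instance-size guard.
#' @param polish Number of top grid candidates refined with continuous
#'   coordinate updates (default 3; 0 disables polishing).
#' @return A `cna_solution` object.
#' @export
solve_cacf_exact <- function(FA, FB, lengths, cmax = 12, umin = 0.03,
                             theta = 1, grid_step = 0.01, force = FALSE,
                             wgd = theta >= 2, polish = 3) {
  m <- nrow(FA); k <- ncol(FA)
  if (!force && (m > 25 || k > 2)) {
    abort("Exact solver guard: m <= 25 and k <= 2 (use `force = TRUE`).")
  }
  states <- expand.grid(a = 0:cmax, b = 0:cmax)
  states <- states[states$a + states$b <= cmax, , drop = FALSE]
  # deterministic tie-break order: nearest (theta, theta), then lexicographic
  states <- states[order(abs(states$a - theta) + abs(states$b - theta),
                         states$a, states$b), , drop = FALSE]
  S <- nrow(states)
  mu <- c(0, seq(ceiling(umin / grid_step) * grid_step, 1, by = grid_step))
  G <- length(mu)
  lens <- as.numeric(lengths)
  cost_ps <- function(p) {
    # S x G cost matrix summed over clusters is not separable; return a
    # list of per-cluster S x G matrices for sample p
    lapply(seq_len(m), function(s) {
      fa <- FA[s, p]; fb <- FB[s, p]
      ca <- abs(outer(states$a, mu, function(a, u) fa - (1 - u) - a * u))
      cb <- abs(outer(states$b, mu, function(b, u) fb - (1 - u) - b * u))
      lens[s] * (ca + cb)
    })
  }
  if (k == 1) {
    costs <- cost_ps(1)
    per_mu <- vapply(costs, function(cm) apply(cm, 2, min), numeric(G))
    D_mu <- rowSums(per_mu)
    gi <- which.min(D_mu)
    best_mu <- c(mu[gi])
    Dbest <- D_mu[gi]
    st <- vapply(costs, function(cm) which.min(cm[, gi]), integer(1))
    runners <- head(order(D_mu), polish)
    starts <- lapply(runners, function(g) mu[g])
  } else {
    c1 <- cost_ps(1); c2 <- cost_ps(2)
    Dtot <- matrix(0, G, G)
    for (s in seq_len(m)) {
      Ms <- matrix(Inf, G, G)
      for (j in seq_len(S)) {
        Ms <- pmin(Ms, outer(c1[[s]][j, ], c2[[s]][j, ], `+`))
      }
      Dtot <- Dtot + Ms
    }
    gi <- arrayInd(which.min(Dtot), dim(Dtot))
    best_mu <- c(mu[gi[1]], mu[gi[2]])
    Dbest <- Dtot[gi[1], gi[2]]
    st <- vapply(seq_len(m), function(s) {
      which.min(c1[[s]][, gi[1]] + c2[[s]][, gi[2]])
    }, integer(1))
    runners <- arrayInd(head(order(Dtot), polish), dim(Dtot))
    starts <- lapply(seq_len(nrow(runners)), function(r) {
      c(mu[runners[r, 1]], mu[runners[r, 2]])
    })
  }
  A <- cbind(1L, states$a[st])
  B <- cbind(1L, states$b[st])
  U <- rbind(1 - best_mu, best_mu)
  # polish: continuous coordinate updates from the best grid basins
  for (mu0 in starts) {
    Up <- rbind(1 - mu0, mu0)
    D_prev <- Inf
    for (it in 1:50) {
      ab <- update_copy_numbers(FA, FB, Up, lens, cmax, theta)
      Up <- update_proportions(FA, FB, ab$A, ab$B, lens, umin)
      Dp <- cacf_objective(FA, FB, ab$A, ab$B, Up, lens)
      if (D_prev - Dp < 1e-9) break
      D_prev <- Dp
    }
    if (Dp < Dbest) {
      Dbest <- Dp
      A <- ab$A; B <- ab$B; U <- Up
    }
  }
  samples <- colnames(FA)
  if (is.null(samples)) samples <- paste0("sample", seq_len(k))
  dimnames(A) <- dimnames(B) <- list(rownames(FA), c("normal", "clone2"))
  dimnames(U) <- list(c("normal", "clone2"), samples)
  new_cna_solution(A, B, U, setNames(lens, rownames(FA)), Dbest,
                   hypothesis = list(wgd = wgd, theta = theta),
                   method = "exact", converged = TRUE)
}

#' @export
print.cna_solution <- function(x, ...) {
  cat(sprintf(
    "<cna_solution> %d clusters, %d clones, %d sample(s); D = %.6g (%s, %s)\n",
    nrow(x$A), ncol(x$A), ncol(x$U), x$objective, x$method,
    if (isTRUE(x$hypothesis$wgd)) "WGD" else "no-WGD"))
  invisible(x)
}

#' Tidy a factorization solution
#'
#' One row per (cluster, clone, sample) with the copy-number state and the
#' clone proportion.
#'
#' @param x A `cna_solution`.
#' @param ... Unused.
#' @export
tidy.cna_solution <- function(x, ...) {
  clusters <- rownames(x$A)
  if (is.null(clusters)) clusters <- as.character(seq_len(nrow(x$A)))
  grid <- tidyr::expand_grid(cluster = clusters, clone = colnames(x$A),
                             sample = colnames(x$U))
  si <- match(grid$cluster, clusters)
  ci <- match(grid$clone, colnames(x$A))
  pi <- match(grid$sample, colnames(x$U))
  grid$a <- x$A[cbind(si, ci)]
  grid$b <- x$B[cbind(si, ci)]
  grid$proportion <- x$U[cbind(ci, pi)]
  grid$length <- as.numeric(x$lengths[si])
  grid
}

#' Glance at a factorization solution
#'
#' @param x A `cna_solution`.
#' @param ... Unused.
#' @return One-row tibble with the distance, clone count, sample count and
#'   WGD status.
#' @export
glance.cna_solution <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, n_clones = ncol(x$A), n_clusters = nrow(x$A),
    n_samples = ncol(x$U), wgd = isTRUE(x$hypothesis$wgd), method = x$method)
}
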