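#' Find the balanced clonal anchor cluster
#'
#' Identifies the largest cluster whose pooled BAF is within `tol_baf` of
#' 0.5 in every sample. Without a WGD this cluster is interpreted as the
#' diploid state (1, 1); under a WGD it is interpreted as (2, 2), since a
#' WGD doubles all copy numbers.
#'
#' @param cl A `bin_clustering` object.
#' @param tol_baf Balance tolerance (default 0.04).
#' @return The id of the anchor cluster.
#' @export
find_diploid_anchor <- function(cl, tol_baf = 0.04) {
  cents <- cl$clusters
  ok <- tapply(abs(cents$baf - 0.5) <= tol_baf, cents$cluster, all)
  cand <- names(ok)[ok]
  if (length(cand) == 0) abort("no balanced clonal cluster")
  cand[which.max(cl$lengths[cand])]
}

# clonal copy-number states reachable by a single-copy gain or loss
# occurring before or after a WGD, given the balanced anchor is (2, 2)
wgd_candidate_states <- function() {
  list(c(2L, 0L), c(2L, 1L), c(3L, 2L), c(4L, 2L), c(3L, 1L), c(4L, 3L))
}

#' Find the second clonal anchor under the WGD hypothesis
#'
#' Under a WGD the balanced anchor has total copy number 4. A second
#' cluster with a fixed state in all tumor clones is needed to resolve the
#' scaling (two distinct clonal totals). Candidates must preserve their
#' RDR and BAF ordering relative to every other cluster across all samples
#' (a fixed clonal state keeps its relative position); each candidate is
#' matched by least squares on BAF to the clonal states produced by a
#' single-copy gain or loss before or after the WGD, and must satisfy the
#' scaling-identifiability inequality
#' `r_anchor (omega_z - 2) != r_z (omega_anchor - 2)` in every sample.
#'
#' @param cl A `bin_clustering` object.
#' @param anchor Balanced anchor cluster id from [find_diploid_anchor()].
#' @param tol_r,tol_baf Ordering and state-fit tolerances.
#' @param states Candidate clonal states (list of `c(a, b)`).
#' @return A list with `cluster`, `state`, `omega` for the chosen second
#'   anchor, or `NULL` when the WGD hypothesis is infeasible.
#' @export
find_second_anchor <- function(cl, anchor, tol_r = 0.08, tol_baf = 0.04,
                               states = wgd_candidate_states()) {
  cents <- centroid_matrix(cl)
  ids <- rownames(cents)
  k <- sum(startsWith(colnames(cents), "rdr_"))
  rmat <- cents[, seq_len(k), drop = FALSE]
  bmat <- cents[, -seq_len(k), drop = FALSE]
  r_anchor <- rmat[anchor, ]
  consistent <- function(d, tol) all(d > -tol) || all(d < tol)
  lens_all <- cl$lengths[ids]
  # length-weighted distance of every cluster to its nearest clonal-state
  # position under the scaling implied by a candidate anchor pair; anchors
  # that misread a subclonal cluster as clonal scale the whole genome to
  # positions nothing else fits, and score badly here
  global_score <- function(sol, cmax = 8) {
    f <- sweep(rmat, 2, sol$gamma, `*`)
    fB <- bmat * f
    fA <- f - fB
    mu <- 1 - sol$u1
    tot <- 0
    for (s in seq_along(ids)) {
      best <- Inf
      for (a in 0:cmax) for (b in 0:a) {
        da <- abs(fA[s, ] - (sol$u1 + a * mu)) +
          abs(fB[s, ] - (sol$u1 + b * mu))
        db <- abs(fA[s, ] - (sol$u1 + b * mu)) +
          abs(fB[s, ] - (sol$u1 + a * mu))
        best <- min(best, sum(pmin(da, db)))
      }
      tot <- tot + lens_all[s] * best
    }
    tot / sum(lens_all)
  }
  results <- list()
  for (z in setdiff(ids, anchor)) {
    ordered <- all(vapply(setdiff(ids, z), function(o) {
      consistent(rmat[z, ] - rmat[o, ], tol_r) &&
        consistent(bmat[z, ] - bmat[o, ], tol_baf)
    }, logical(1)))
    if (!ordered) next
    best <- NULL
    for (st in states) {
      omega <- sum(st)
      sol <- solve_wgd_system(r_anchor, rmat[z, ], 4, omega)
      if (is.null(sol)) next
      # degenerate near-pure-normal scalings make every state fit
      if (max(1 - sol$u1) < 0.05) next
      beta_pred <- (sol$u1 + min(st) * (1 - sol$u1)) /
        (2 * sol$u1 + omega * (1 - sol$u1))
      beta_pred <- pmin(beta_pred, 1 - beta_pred)
      beta_obs <- pmin(bmat[z, ], 1 - bmat[z, ])
      resid <- mean(abs(beta_pred - beta_obs))
      if (resid > tol_baf) next
      score <- global_score(sol)
      if (is.null(best) || score < best$score) {
        best <- list(state = st, omega = omega, resid = resid,
                     score = score)
      }
    }
    if (!is.null(best)) {
      results[[z]] <- c(best, list(cluster = z, length = cl$lengths[[z]]))
    }
  }
  if (length(results) == 0) return(NULL)
  score <- vapply(results, `[[`, numeric(1), "score")
  lens <- vapply(results, `[[`, numeric(1), "length")
  dev <- vapply(results, function(r) abs(r$omega - 4), numeric(1))
  ord <- order(score, -lens, dev)
  pick <- results[[ord[1]]]
  list(cluster = pick$cluster, state = pick$state, omega = pick$omega,
       score = pick$score)
}

# per-sample solve of gamma * r1 = 2 u1 + w1 (1 - u1),
#                     gamma * r2 = 2 u1 + w2 (1 - u1)
# returns NULL if the system is singular or yields infeasible u1 / gamma
solve_wgd_system <- function(r1, r2, w1, w2, tol = 1e-6, slack = 0.02) {
  # solve [r, w - 2] [gamma, u1]' = [w] per sample by Cramer's rule
  det <- r1 * (w2 - 2) - r2 * (w1 - 2)
  if (any(abs(det) <= tol * pmax(r1, r2, 1))) return(NULL)
  gamma <- 2 * (w2 - w1) / det
  u1 <- (r1 * w2 - r2 * w1) / det
  if (any(gamma <= 0) || any(u1 < -slack) || any(u1 > 1 + slack)) return(NULL)
  list(gamma = gamma, u1 = pmin(pmax(u1, 0), 1))
}

#' Enumerate feasible scaling hypotheses
#'
#' Builds the no-WGD hypothesis (balanced anchor interpreted as (1, 1))
#' and, when a second anchor exists, the WGD hypothesis (balanced anchor
#' (2, 2) plus the second anchor). An infeasible WGD hypothesis is simply
#' absent from the result rather than an error.
#'
#' @inheritParams find_second_anchor
#' @return Named list of hypothesis objects (`no_wgd`, possibly `wgd`).
#' @export
scaling_hypotheses <- function(cl, tol_r = 0.08, tol_baf = 0.04) {
  anchor <- find_diploid_anchor(cl, tol_baf = tol_baf)
  hyps <- list(no_wgd = list(wgd = FALSE, anchor1 = anchor, omega1 = 2,
                             anchor2 = NULL, omega2 = NULL))
  second <- find_second_anchor(cl, anchor, tol_r = tol_r, tol_baf = tol_baf)
  if (!is.null(second)) {
    hyps$wgd <- list(wgd = TRUE, anchor1 = anchor, omega1 = 4,
                     anchor2 = second$cluster, omega2 = second$omega,
                     state2 = second$state)
  }
  hyps
}

#' Scale cluster RDRs to allele-specific fractional copy numbers
#'
#' Applies the scaling identity: without a WGD the anchor has total copy
#' number 2 in every clone, so `f_{s,p} = 2 r_{s,p} / r_{anchor,p}`; with a
#' WGD the two anchors give, per sample, a 2x2 linear system in the RDR
#' scale factor `gamma_p` and the normal proportion `u_{1,p}`, and
#' `f_{s,p} = gamma_p r_{s,p}`. The allele split uses the pooled cluster
#' BAF: `f^B = beta f` (minor allele) and `f^A = f - f^B`.
#'
#' @param cl A `bin_clustering` object.
#' @param hypothesis One element of [scaling_hypotheses()].
#' @return A `fractional_cn` object: list with matrices `FA`, `FB`
#'   (clusters x samples), `lengths`, `gamma`, `u1` (WGD case), and the
#'   `hypothesis`.
#' @export
scale_to_fractional <- function(cl, hypothesis) {
  cents <- centroid_matrix(cl)
  ids <- rownames(cents)
  k <- sum(startsWith(colnames(cents), "rdr_"))
  samples <- sub("^rdr_", "", colnames(cents)[seq_len(k)])
  rmat <- cents[, seq_len(k), drop = FALSE]
  bmat <- cents[, -seq_len(k), drop = FALSE]
  a1 <- hypothesis$anchor1
  if (!hypothesis$wgd) {
    if (any(rmat[a1, ] <= 0)) abort("Anchor cluster has zero RDR.")
    gamma <- 2 / rmat[a1, ]
    u1 <- rep(NA_real_, k)
  } else {
    sol <- solve_wgd_system(rmat[a1, ], rmat[hypothesis$anchor2, ],
                            hypothesis$omega1, hypothesis$omega2)
    if (is.null(sol)) {
      abort("WGD scaling system is singular or infeasible for these anchors.")
    }
    gamma <- sol$gamma
    u1 <- sol$u1
  }
  f <- sweep(rmat, 2, gamma, `*`)
  f[f < 0] <- 0
  # bmat is allele-consistent across samples (cluster-level orientation);
  # entries above 0.5 mean the cluster's minor-on-average allele is the
  # major one in that sample
  FB <- bmat * f
  FA <- f - FB
  dimnames(FA) <- dimnames(FB) <- list(ids, samples)
  noise <- fractional_noise(cl, f, bmat, ids, samples)
  structure(list(FA = FA, FB = FB, lengths = cl$lengths[ids],
                 gamma = setNames(gamma, samples),
                 u1 = setNames(u1, samples),
                 SA = noise$SA, SB = noise$SB,
                 hypothesis = hypothesis, samples = samples),
            class = "fractional_cn")
}

# counting-statistics standard errors of the fractional copy numbers:
# binomial noise of the pooled cluster read counts propagated through the
# RDR scaling, plus the (phase-inflated) binomial noise of the pooled BAF
# propagated through the allele split
fractional_noise <- function(cl, f, bmat, ids, samples) {
  pull <- function(col) {
    if (!(col %in% names(cl$clusters))) return(NULL)
    w <- tidyr::pivot_wider(cl$clusters[, c("cluster", "sample", col)],
                            names_from = "sample",
                            values_from = tidyr::all_of(col))
    w <- dplyr::arrange(w, .data$cluster)
    m <- as.matrix(w[, -1, drop = FALSE])
    rownames(m) <- w$cluster
    m[as.character(ids), samples, drop = FALSE]
  }
  Tm <- pull("bin_reads"); Nm <- pull("normal_reads"); Rm <- pull("snp_reads")
  if (is.null(Tm) || is.null(Nm) || is.null(Rm) ||
      anyNA(Tm) || anyNA(Nm) || anyNA(Rm)) {
    return(list(SA = NULL, SB = NULL))
  }
  sf <- f * sqrt(1 / pmax(Tm, 1) + 1 / pmax(Nm, 1))
  sb <- 1.5 * sqrt(pmax(bmat * (1 - bmat), 0.0025) / pmax(Rm, 1))
  list(SA = (1 - bmat) * sf + f * sb, SB = bmat * sf + f * sb)
}

#' Odd-total clonal genome mass under a WGD scaling
#'
#' A spurious WGD reading of a genome without one contains only doubled,
#' even-total clonal states; a detectable true WGD leaves clonal states of
#' odd total copy number (single-copy gains or losses after the
#' duplication). This measures the genome fraction in clusters whose best
#' rigid clonal state — one `(a, b)` per cluster shared by all samples,
#' purity fixed at the anchor-implied value — has odd total and fits
#' within `fit_tol` per sample.
#'
#' @param fr A `fractional_cn` under the WGD hypothesis.
#' @param cmax State search bound (default 8).
#' @param fit_tol Mean per-sample L1 tolerance for a cluster to count as
#'   clonally placed (default 0.1).
#' @return Fraction of total cluster length (scalar in `[0, 1]`).
#' @export
wgd_odd_clonal_mass <- function(fr, cmax = 8, fit_tol = 0.1) {
  if (is.null(fr$u1) || anyNA(fr$u1)) return(NA_real_)
  k <- ncol(fr$FA); m <- nrow(fr$FA)
  lens <- as.numeric(fr$lengths)
  u1 <- fr$u1
  mass <- 0
  for (i in seq_len(m)) {
    best <- Inf; best_odd <- FALSE
    for (a in 0:cmax) for (b in 0:a) {
      d <- 0
      for (p in seq_len(k)) {
        mu <- 1 - u1[p]
        d1 <- abs(fr$FA[i, p] - (u1[p] + a * mu)) +
          abs(fr$FB[i, p] - (u1[p] + b * mu))
        d2 <- abs(fr$FA[i, p] - (u1[p] + b * mu)) +
          abs(fr$FB[i, p] - (u1[p] + a * mu))
        d <- d + min(d1, d2)
      }
      if (d < best) { best <- d; best_odd <- (a + b) %% 2 == 1 }
    }
    if (best_odd && best / k <= fit_tol) mass <- mass + lens[i]
  }
  mass / sum(lens)
}

#' @export
print.fractional_cn <- function(x, ...) {
  cat(sprintf("<fractional_cn> %d clusters x %d samples (%s hypothesis)\n",
              nrow(x$FA), ncol(x$FA),
              if (x$hypothesis$wgd) "WGD" else "no-WGD"))
  invisible(x)
}
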