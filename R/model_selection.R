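#' Fit the factorization over a grid of clone numbers and hypotheses
#'
#' For each feasible scaling hypothesis (no-WGD, and WGD when a second
#' anchor exists) and each number of clones `n` in `[2, n_max]`, runs the
#' coordinate-descent solver. Each `n` is additionally warm-started from
#' the solution at `n - 1` (the largest tumor clone is split in two), which
#' makes the distance non-increasing in `n` within a hypothesis.
#'
#' @param fractionals Named list of `fractional_cn` objects from
#'   [scale_to_fractional()] (names `no_wgd`, `wgd`).
#' @inheritParams solve_cacf_cd
#' @param n_max Largest number of clones considered (default 6).
#' @param tau Elbow threshold used for early stopping: once the relative
#'   improvement of a hypothesis falls below `tau`, larger `n` cannot be
#'   selected and are not fitted (default 0.05, matching
#'   [select_solution()]).
#' @return A `model_grid` object: tibble of solutions indexed by
#'   (hypothesis, n) with the attained distance.
#' @export
fit_model_grid <- function(fractionals, n_max = 6, cmax = 12, umin = 0.03,
                           restarts = 10, max_iter = 50, seed = 1,
                           tau = 0.05, noise_floor = 2) {
  rows <- list()
  for (hyp_name in names(fractionals)) {
    fr <- fractionals[[hyp_name]]
    if (is.null(fr)) next
    theta <- if (fr$hypothesis$wgd) 2 else 1
    prev <- NULL
    base <- NULL
    # the anchor scaling implies per-sample normal proportions: a purity
    # warm start pulls the search into the clonal-dominated basin
    u1_init <- if (!is.null(fr$u1) && !anyNA(fr$u1)) {
      pmin(pmax(fr$u1, 0), 1 - umin)
    }
    for (n in 2:n_max) {
      warm <- if (!is.null(prev)) list(split_largest_clone(prev$U, umin))
      if (!is.null(u1_init)) {
        U0 <- rbind(u1_init, matrix((1 - u1_init) / (n - 1), n - 1,
                                    length(u1_init), byrow = TRUE))
        warm <- c(warm, list(unname(U0)))
      }
      # deeper searches need fewer random restarts thanks to the warm start
      r_n <- if (n <= 3) restarts else max(3, restarts %/% 2)
      sol <- solve_cacf_cd(fr$FA, fr$FB, fr$lengths, n = n, cmax = cmax,
                           umin = umin, theta = theta,
                           restarts = r_n, max_iter = max_iter,
                           seed = seed + 1000 * n, wgd = fr$hypothesis$wgd,
                           init = warm, hierarchical = is.null(warm))
      sol$hypothesis <- fr$hypothesis
      sol$hypothesis$theta <- theta
      # total fractional mass: the scale of the distances under this
      # hypothesis (the WGD scaling roughly doubles it)
      sol$phi <- sum(fr$lengths * rowSums(fr$FA + fr$FB))
      # expected distance at the counting-noise floor: E|N(0, s)| per entry
      sol$noise <- if (!is.null(fr$SA)) {
        sqrt(2 / pi) * sum(fr$lengths * rowSums(fr$SA + fr$SB))
      } else {
        NA_real_
      }
      sol$odd_mass <- if (fr$hypothesis$wgd) {
        wgd_odd_clonal_mass(fr)
      } else {
        NA_real_
      }
      # enforce monotonicity: a larger n can always replicate the smaller fit
      if (!is.null(prev) && sol$objective > prev$objective) {
        sol <- prev
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        hypothesis = hyp_name, n = n, objective = sol$objective,
        phi = sol$phi, noise = sol$noise, odd_mass = sol$odd_mass,
        solution = list(sol))
      if (is.null(base)) base <- max(sol$objective, sol$phi * 1e-4)
      # stop once the fit reaches the expected noise floor, or once the
      # improvement is negligible (neither larger n can be selected)
      if (!is.na(sol$noise) && sol$objective <= noise_floor * sol$noise) {
        break
      }
      if (!is.null(prev) &&
          (prev$objective - sol$objective) / max(base, 1e-9) < tau) {
        break
      }
      prev <- sol
    }
  }
  if (length(rows) == 0) abort("No feasible hypothesis to fit.")
  structure(dplyr::bind_rows(rows), class = c("model_grid", "tbl_df", "tbl",
                                              "data.frame"))
}

# warm start for n + 1 clones: split the largest tumor clone's proportions
split_largest_clone <- function(U, umin) {
  n <- nrow(U)
  if (n >= 2) {
    tot <- rowSums(U[-1, , drop = FALSE])
    i <- which.max(tot) + 1
    newrow <- U[i, ] / 2
    U[i, ] <- U[i, ] / 2
    U <- rbind(U, newrow)
  } else {
    U <- rbind(U, 0)
  }
  unname(U)
}

#' Select the final solution across clone numbers and WGD status
#'
#' Distances are made comparable across the no-WGD and WGD hypotheses by
#' normalizing each by its total fractional mass
#' `Phi = sum_{s,p} l_s f_{s,p}` (the WGD scaling roughly doubles all
#' fractional copy numbers and hence the raw distance of an equally good
#' fit). Within each hypothesis, `n*` is the smallest `n` whose
#' normalized improvement `d(n) - d(n+1)` falls below `tau` times the
#' common baseline `max_h d_h(2)`; the baseline (rather than the current
#' distance) keeps negligible absolute gains near the noise floor from
#' registering as large relative ones. Across hypotheses, the smaller
#' `n*` wins; on ties the WGD solution is chosen only when its normalized
#' distance beats the no-WGD one by the margin `sqrt(Phi_w / Phi_n)`,
#' since the finer copy-number grid available after a WGD can always
#' absorb slightly more noise (the no-WGD model is the simpler
#' explanation and wins otherwise).
#'
#' @param grid A `model_grid` from [fit_model_grid()].
#' @param tau Elbow threshold on the relative improvement (default 0.05).
#' @param eps Guard against division by a zero distance (default 1e-9).
#' @param noise_floor Multiple of the expected counting-noise distance at
#'   which a fit counts as complete (default 2).
#' @param wgd_margin Factor by which the WGD fit must beat the no-WGD fit
#'   on the noise-normalized distance to win without structural evidence
#'   (default 0.8).
#' @param odd_min Minimum odd-total clonal genome mass
#'   ([wgd_odd_clonal_mass()]) counting as structural WGD evidence
#'   (default 0.02).
#' @return The selected `cna_solution`.
#' @export
select_solution <- function(grid, tau = 0.05, eps = 1e-9, noise_floor = 2,
                            wgd_margin = 0.8, odd_min = 0.02) {
  if (nrow(grid) == 0) abort("Empty model grid.")
  grid$d <- grid$objective / pmax(grid$phi, eps)
  if (!("noise" %in% names(grid))) grid$noise <- NA_real_
  if (!("odd_mass" %in% names(grid))) grid$odd_mass <- NA_real_
  base <- max(tapply(grid$d, grid$hypothesis,
                     function(x) x[1]), 1e-4)
  pick_n <- function(sub) {
    sub <- sub[order(sub$n), ]
    nz <- sub$noise[1]
    if (!is.na(nz) && nz > 0) {
      # smallest n whose fit reaches the expected noise floor
      hit <- which(sub$objective <= noise_floor * nz)
      if (length(hit) > 0) {
        out <- sub[hit[1], ]
        out$chi <- out$objective / nz
        return(out)
      }
    }
    for (i in seq_len(nrow(sub))) {
      if (i == nrow(sub) ||
          sub$d[i] - sub$d[i + 1] < tau * base) {
        out <- sub[i, ]
        out$chi <- if (!is.na(nz) && nz > 0) out$objective / nz else NA_real_
        return(out)
      }
    }
  }
  picks <- dplyr::bind_rows(lapply(split(grid, grid$hypothesis), pick_n))
  if (nrow(picks) == 1) return(picks$solution[[1]])
  pw <- picks[picks$hypothesis == "wgd", ]
  pn <- picks[picks$hypothesis != "wgd", ]
  if (!is.na(pw$chi) && !is.na(pn$chi)) {
    # Noise-normalized distances are scale-free and comparable across
    # hypotheses. The WGD explanation wins either when positive structural
    # evidence exists (clonal clusters at odd total copy number, which a
    # doubled reading of a diploid genome cannot produce) together with at
    # least as good a fit, or when its fit is decisively better on its
    # own; otherwise the simpler no-WGD reading stands.
    odd <- pw$odd_mass
    structural <- !is.na(odd) && odd >= odd_min &&
      (pw$chi <= pn$chi || (pw$n < pn$n && pw$chi <= 1.2 * pn$chi))
    decisive <- pw$chi < wgd_margin * pn$chi
    # fewer clones at no fit cost: the simpler explanation of the data
    dominant <- pw$n < pn$n && pw$chi <= pn$chi
    wgd_wins <- structural || decisive || dominant
  } else {
    margin <- sqrt(pw$phi / pn$phi)
    wgd_wins <- pw$n < pn$n || (pw$n == pn$n && pw$d * margin < pn$d)
  }
  if (wgd_wins) pw$solution[[1]] else pn$solution[[1]]
}

#' Classify clusters as clonal or subclonal
#'
#' A cluster is sample-clonal in a sample when all tumor clones present
#' there (`u > 0`) share one copy-number state (the normal clone is not
#' counted: an aberrant cluster carried by a single tumor clone is a clonal
#' CNA, not a subclonal one), and tumor-clonal when all tumor clones share
#' one state regardless of presence. Sample-subclonal anywhere implies
#' tumor-subclonal.
#'
#' @param solution A `cna_solution`.
#' @return List with `per_sample` (tibble `cluster`, `sample`,
#'   `sample_clonal`) and `per_cluster` (tibble `cluster`, `tumor_clonal`).
#' @export
classify_clusters <- function(solution) {
  A <- solution$A; B <- solution$B; U <- solution$U
  clusters <- rownames(A)
  if (is.null(clusters)) clusters <- as.character(seq_len(nrow(A)))
  samples <- colnames(U)
  per_sample <- tidyr::expand_grid(cluster = clusters, sample = samples)
  per_sample$sample_clonal <- vapply(seq_len(nrow(per_sample)), function(r) {
    s <- match(per_sample$cluster[r], clusters)
    p <- match(per_sample$sample[r], samples)
    present <- which(U[, p] > 0)
    present <- present[present > 1] # tumor clones only
    if (length(present) == 0) return(TRUE)
    states <- paste(A[s, present], B[s, present])
    length(unique(states)) == 1
  }, logical(1))
  tumor <- seq_len(ncol(A))[-1]
  per_cluster <- tibble::tibble(
    cluster = clusters,
    tumor_clonal = vapply(seq_along(clusters), function(s) {
      states <- paste(A[s, tumor], B[s, tumor])
      length(unique(states)) == 1
    }, logical(1)))
  list(per_sample = per_sample, per_cluster = per_cluster)
}

#' Per-sample summary of a solution
#'
#' Reports, per sample: tumor purity `mu = 1 - u_normal`; tumor ploidy
#' `rho = (1/mu) * sum_i u_i L_i / L` over tumor clones, with
#' `L_i = sum_s c_{s,i} l_s`; the WGD flag; the fraction of the genome in
#' sample-subclonal clusters; and the number of tumor clones present.
#'
#' @param solution A `cna_solution`.
#' @return A tibble with one row per sample.
#' @export
summarize_solution <- function(solution) {
  A <- solution$A; B <- solution$B; U <- solution$U
  lens <- as.numeric(solution$lengths)
  L <- sum(lens)
  C <- A + B
  Li <- as.numeric(t(C) %*% lens) # genome length per clone
  cls <- classify_clusters(solution)
  samples <- colnames(U)
  out <- lapply(seq_along(samples), function(p) {
    mu <- 1 - U[1, p]
    rho <- if (mu > 0) sum(U[-1, p] * Li[-1]) / (mu * L) else NA_real_
    sub <- cls$per_sample[cls$per_sample$sample == samples[p], ]
    subfrac <- sum(lens[match(sub$cluster[!sub$sample_clonal],
                              rownames(A))]) / L
    tibble::tibble(
      sample = samples[p], purity = mu, ploidy = rho,
      wgd = isTRUE(solution$hypothesis$wgd),
      n_clones = sum(U[-1, p] > 0),
      subclonal_fraction = subfrac)
  })
  dplyr::bind_rows(out)
}
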