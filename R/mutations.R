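#' Equal-tailed credible interval for a variant-allele frequency
#'
#' Binomial model with a uniform Beta(1, 1) prior: the posterior of the
#' VAF after observing `v` variant reads out of `t` is
#' `Beta(v + 1, t - v + 1)`; the interval is equal-tailed at the given
#' level, with the boundaries closed at 0 and 1 when `v = 0` or `v = t`.
#'
#' @param v Variant read counts.
#' @param t Total read counts (> 0).
#' @param level Credible level (default 0.95).
#' @return Tibble with columns `lo`, `hi`.
#' @export
vaf_credible_interval <- function(v, t, level = 0.95) {
  if (any(t <= 0)) abort("Total read count must be positive.")
  if (any(v < 0 | v > t)) abort("`v` must satisfy 0 <= v <= t.")
  a <- (1 - level) / 2
  lo <- qbeta(a, v + 1, t - v + 1)
  hi <- qbeta(1 - a, v + 1, t - v + 1)
  lo[v == 0] <- 0
  hi[v == t] <- 1
  tibble::tibble(lo = lo, hi = hi)
}

#' Attainable predicted VAFs at a genomic cluster
#'
#' Given the allele-specific copy-number states of the clones at a cluster
#' and the clone proportions of one sample, enumerates the VAF values
#' attainable by a mutation on either allele, assuming no homoplasy (the
#' normal clone carries 0 mutated copies; each tumor clone carries between
#' 0 and its allele copy number). The predicted VAF of an assignment is
#' `sum_i ctilde_i u_i / sum_i c_i u_i`. The all-zero assignment is
#' excluded and duplicates are collapsed. When the full enumeration
#' exceeds `cap` assignments, the per-clone mutated-copy choices are
#' reduced to the deterministic subset {0, 1, full allele copy number}.
#'
#' @param a_row,b_row Integer copy numbers per clone (normal first).
#' @param u Clone proportions of the sample (sums to 1).
#' @param cap Enumeration cap (default 1e4).
#' @return Sorted numeric vector of distinct attainable VAFs.
#' @export
predicted_vafs <- function(a_row, b_row, u, cap = 1e4) {
  n <- length(u)
  stopifnot(length(a_row) == n, length(b_row) == n)
  ctot <- sum((a_row + b_row) * u)
  if (ctot <= 0) abort("Total deletion: zero copy content at this cluster.")
  out <- numeric(0)
  for (x_row in list(a_row, b_row)) {
    choices <- lapply(seq_len(n), function(i) {
      if (i == 1) 0L else 0:x_row[i]
    })
    sizes <- prod(vapply(choices, length, numeric(1)))
    if (sizes > cap) {
      choices <- lapply(seq_len(n), function(i) {
        if (i == 1) 0L else unique(c(0L, min(1L, x_row[i]), x_row[i]))
      })
    }
    combos <- as.matrix(expand.grid(choices))
    vals <- as.vector(combos %*% u) / ctot
    # assignments whose mutated copies all sit in absent clones are
    # unobservable and excluded along with the all-zero assignment
    out <- c(out, vals[rowSums(combos) > 0 & vals > 0])
  }
  sort(unique(out))
}

#' Cancer cell fraction of a mutation
#'
#' CCF at multiplicity `m` is
#' `VAF * (mu * cbar + 2 (1 - mu)) / (m * mu)` where `cbar` is the
#' proportion-weighted mean tumor copy number of the locus and `mu` the
#' tumor purity. The multiplicity is the positive integer (up to the
#' largest allele copy number among tumor clones) whose CCF is closest to
#' 1 subject to `CCF <= 1 + tol`; if no multiplicity is feasible, the one
#' with the smallest CCF is used. CCF is clipped to `[0, 1.5]`.
#'
#' @param vaf Observed variant-allele frequency.
#' @param purity Tumor purity `mu` of the sample (> 0).
#' @param cbar Proportion-weighted mean tumor copy number of the locus.
#' @param max_mult Largest admissible multiplicity (>= 1).
#' @param tol Feasibility slack above 1 (default 0.1).
#' @return List with `ccf` and `multiplicity`.
#' @export
mutation_ccf <- function(vaf, purity, cbar, max_mult = 1, tol = 0.1) {
  if (is.na(purity) || purity <= 0) {
    return(list(ccf = NA_real_, multiplicity = NA_integer_))
  }
  max_mult <- max(1L, as.integer(max_mult))
  ms <- seq_len(max_mult)
  ccfs <- vaf * (purity * cbar + 2 * (1 - purity)) / (ms * purity)
  feasible <- which(ccfs <= 1 + tol)
  pick <- if (length(feasible) > 0) {
    feasible[which.min(abs(ccfs[feasible] - 1))]
  } else {
    which.min(ccfs)
  }
  list(ccf = min(max(ccfs[pick], 0), 1.5), multiplicity = as.integer(pick))
}

#' Assess whether a solution explains observed mutations
#'
#' Maps each mutation to its cluster, computes the credible interval of
#' its observed VAF, enumerates the VAFs attainable under the inferred
#' copy numbers and proportions, and flags the mutation as explained when
#' some attainable VAF falls inside the interval. Also reports the CCF.
#' Summary counts exclude mutations with observed VAF below `min_vaf`,
#' which are likely to postdate the CNAs at their locus.
#'
#' @param mutations Tibble from [read_mutation_counts()] or
#'   [simulate_mutations()].
#' @param solution A `cna_solution`.
#' @param clustering The `bin_clustering` the solution was fitted on, used
#'   to map positions to clusters; alternatively supply `cluster_of`, a
#'   function(chrom, pos) returning cluster ids.
#' @param bins Bin tibble matching the clustering.
#' @param min_vaf Low-frequency exclusion threshold for the summary
#'   (default 0.2).
#' @param level Credible level (default 0.95).
#' @return List with `assessment` (one row per mutation and sample:
#'   `vaf`, `ci_lo`, `ci_hi`, `explained`, `ccf`, `multiplicity`) and
#'   `summary` (per sample counts of explained/unexplained mutations with
#'   VAF >= `min_vaf`).
#' @export
assess_mutations <- function(mutations, solution, clustering = NULL,
                             bins = NULL, cluster_of = NULL, min_vaf = 0.2,
                             level = 0.95) {
  if (is.null(cluster_of)) {
    stopifnot(!is.null(clustering), !is.null(bins))
    cluster_of <- function(chrom, pos) {
      b <- assign_to_bins(bins, chrom, pos)
      clustering$assignment$cluster[match(b, clustering$assignment$bin)]
    }
  }
  A <- solution$A; B <- solution$B; U <- solution$U
  clusters <- rownames(A)
  df <- mutations
  df$cluster <- as.character(cluster_of(df$chrom, df$pos))
  missing_cl <- is.na(df$cluster) | !(df$cluster %in% clusters)
  if (any(missing_cl)) {
    warn(sprintf("%d mutation record(s) outside the covered genome; skipped.",
                 sum(missing_cl)))
    df <- df[!missing_cl, , drop = FALSE]
  }
  if (nrow(df) == 0) abort("No mutation overlaps the inferred clusters.")
  df$vaf <- ifelse(df$total_reads > 0, df$var_reads / df$total_reads, NA_real_)
  ci <- vaf_credible_interval(df$var_reads, pmax(df$total_reads, 1), level)
  df$ci_lo <- ci$lo; df$ci_hi <- ci$hi
  res <- lapply(seq_len(nrow(df)), function(r) {
    s <- match(df$cluster[r], clusters)
    p <- match(df$sample[r], colnames(U))
    u <- U[, p]
    cand <- predicted_vafs(A[s, ], B[s, ], u)
    explained <- any(cand >= df$ci_lo[r] & cand <= df$ci_hi[r])
    mu <- 1 - u[1]
    cbar <- if (mu > 0) sum((A[s, -1] + B[s, -1]) * u[-1]) / mu else NA_real_
    cc <- mutation_ccf(df$vaf[r], mu, cbar,
                       max_mult = max(A[s, -1], B[s, -1]))
    tibble::tibble(explained = explained, ccf = cc$ccf,
                   multiplicity = cc$multiplicity)
  })
  df <- dplyr::bind_cols(df, dplyr::bind_rows(res))
  high <- df[!is.na(df$vaf) & df$vaf >= min_vaf, , drop = FALSE]
  summary <- dplyr::summarise(
    dplyr::group_by(high, .data$sample),
    n = dplyr::n(), explained = sum(.data$explained),
    unexplained = sum(!.data$explained),
    fraction_explained = mean(.data$explained), .groups = "drop")
  list(assessment = tibble::as_tibble(df), summary = summary)
}
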