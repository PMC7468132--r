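#' Cluster genomic bins by RDR and BAF across samples
#'
#' Globally clusters all unmasked bins in the joint feature space formed by
#' the RDR and BAF of every sample (`2k` features for `k` samples), using a
#' variational Dirichlet-process Gaussian mixture with diagonal covariance.
#' Bins in the same cluster putatively share one copy-number state per
#' clone; clustering is global along the genome and joint across samples,
#' not a local segmentation. Features are standardized per sample before
#' fitting. Clusters whose genomic length falls below `min_fraction` of the
#' total unmasked length are reassigned to the nearest centroid.
#'
#' @param signals Per-bin signal tibble from [bin_signals()].
#' @param max_components Truncation level of the mixture (default 50).
#' @param alpha Dirichlet-process concentration (default 0.01).
#' @param restarts Random restarts, best variational score kept (default 10).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param min_fraction Minimum cluster genomic-length fraction (default 1e-3).
#' @param snp_counts Optional SNP table used to re-pool cluster BAF with
#'   the cross-sample phase EM (see [pool_signals()]).
#' @param bins Bin tibble (required when `snp_counts` is given).
#' @return A `bin_clustering` object: list with `assignment` (tibble
#'   `bin`, `cluster`), `clusters` (per-cluster per-sample centroid tibble
#'   `cluster`, `sample`, `rdr`, `baf`, `length`, `n_bins`), `lengths`
#'   (named vector of cluster genomic lengths) and `bins` (bin metadata).
#' @export
cluster_bins <- function(signals, max_components = 50, alpha = 0.01,
                         restarts = 10, seed = 1, min_fraction = 1e-3,
                         snp_counts = NULL, bins = NULL) {
  samples <- sort(unique(signals$sample))
  if (length(samples) == 0) abort("No samples in `signals`.")
  usable <- signals[!signals$masked & is.finite(signals$rdr) &
                      is.finite(signals$baf), , drop = FALSE]
  # keep bins unmasked in every sample
  cnt <- table(usable$bin)
  keep <- as.integer(names(cnt)[cnt == length(samples)])
  usable <- usable[usable$bin %in% keep, , drop = FALSE]
  if (nrow(usable) == 0) abort("All bins are masked; nothing to cluster.")
  wide_r <- tidyr::pivot_wider(usable[, c("bin", "sample", "rdr")],
                               names_from = "sample", values_from = "rdr")
  wide_b <- tidyr::pivot_wider(usable[, c("bin", "sample", "baf")],
                               names_from = "sample", values_from = "baf")
  wide_r <- dplyr::arrange(wide_r, .data$bin)
  wide_b <- dplyr::arrange(wide_b, .data$bin)
  X <- cbind(as.matrix(as.data.frame(wide_r)[, samples, drop = FALSE]),
             as.matrix(as.data.frame(wide_b)[, samples, drop = FALSE]))
  Xs <- scale(X)
  sds <- attr(Xs, "scaled:scale")
  Xs[, sds == 0 | !is.finite(sds)] <- 0
  n_distinct <- nrow(unique(round(Xs, 10)))
  if (nrow(Xs) < 2 || n_distinct < 2) {
    labels <- rep(1L, nrow(Xs))
  } else {
    fit <- dpgmm_fit(Xs, max_components = max_components, alpha = alpha,
                     restarts = restarts, seed = seed)
    labels <- fit$labels
  }
  assignment <- tibble::tibble(bin = wide_r$bin,
                               cluster = match(labels, unique(labels)))
  cl <- build_clustering(assignment, signals, NULL, NULL)
  cl <- reassign_small_clusters(cl, signals, min_fraction, NULL, NULL)
  build_clustering(cl$assignment, signals, snp_counts, bins)
}

build_clustering <- function(assignment, signals, snp_counts = NULL,
                             bins_tbl = NULL) {
  meta <- signals[!duplicated(signals$bin),
                  c("bin", "chrom", "start", "end")]
  pooled <- pool_signals(signals, assignment, snp_counts, bins_tbl)
  lens <- tapply(pooled$length, pooled$cluster, function(x) x[1])
  structure(list(
    assignment = assignment,
    clusters = pooled,
    lengths = lens,
    bins = meta,
    samples = sort(unique(signals$sample))
  ), class = "bin_clustering")
}

reassign_small_clusters <- function(cl, signals, min_fraction, snp_counts,
                                    bins_tbl) {
  total <- sum(cl$lengths)
  small <- names(cl$lengths)[cl$lengths < min_fraction * total]
  if (length(small) == 0 || length(cl$lengths) - length(small) < 1) return(cl)
  cents <- centroid_matrix(cl)
  big <- setdiff(rownames(cents), small)
  feats <- feature_matrix(signals, cl$assignment)
  asg <- cl$assignment
  movers <- asg$cluster %in% as.integer(small)
  if (any(movers)) {
    d2 <- as.matrix(stats::dist(rbind(cents[big, , drop = FALSE],
                                      feats[movers, , drop = FALSE])))
    nb <- length(big)
    nearest <- apply(d2[-(seq_len(nb)), seq_len(nb), drop = FALSE], 1,
                     which.min)
    asg$cluster[movers] <- as.integer(big)[nearest]
  }
  asg$cluster <- match(asg$cluster, sort(unique(asg$cluster)))
  build_clustering(asg, signals, snp_counts, bins_tbl)
}

# per-cluster centroid matrix, rows = cluster id, cols = (rdr, baf) x sample
centroid_matrix <- function(cl) {
  wr <- tidyr::pivot_wider(cl$clusters[, c("cluster", "sample", "rdr")],
                           names_from = "sample", values_from = "rdr")
  wb <- tidyr::pivot_wider(cl$clusters[, c("cluster", "sample", "baf")],
                           names_from = "sample", values_from = "baf")
  wr <- dplyr::arrange(wr, .data$cluster); wb <- dplyr::arrange(wb, .data$cluster)
  m <- cbind(as.matrix(wr[, -1, drop = FALSE]), as.matrix(wb[, -1, drop = FALSE]))
  rownames(m) <- wr$cluster
  colnames(m) <- c(paste0("rdr_", names(wr)[-1]), paste0("baf_", names(wb)[-1]))
  m
}

feature_matrix <- function(signals, assignment) {
  usable <- signals[signals$bin %in% assignment$bin, , drop = FALSE]
  wr <- tidyr::pivot_wider(usable[, c("bin", "sample", "rdr")],
                           names_from = "sample", values_from = "rdr")
  wb <- tidyr::pivot_wider(usable[, c("bin", "sample", "baf")],
                           names_from = "sample", values_from = "baf")
  wr <- dplyr::arrange(wr, .data$bin); wb <- dplyr::arrange(wb, .data$bin)
  ord <- match(assignment$bin, wr$bin)
  cbind(as.matrix(wr[ord, -1, drop = FALSE]),
        as.matrix(wb[ord, -1, drop = FALSE]))
}

#' Merge clusters with indistinguishable centroids
#'
#' Iteratively merges the pair of clusters whose centroids differ by less
#' than `tol_r` in RDR and `tol_baf` in BAF in every sample (the closest
#' such pair first), until no pair qualifies. Lengths and pooled signals are
#' re-aggregated after each merge.
#'
#' @param cl A `bin_clustering` object.
#' @param signals The per-bin signal tibble the clustering was built from.
#' @param tol_r,tol_baf Per-sample merge tolerances (defaults 0.08, 0.04).
#' @inheritParams pool_signals
#' @return A merged `bin_clustering`.
#' @export
merge_clusters <- function(cl, signals, tol_r = 0.08, tol_baf = 0.04,
                           snp_counts = NULL, bins = NULL) {
  stopifnot(tol_r >= 0, tol_baf >= 0)
  asg <- cl$assignment
  repeat {
    # cheap centroids (length-weighted means) during the loop; the pooled
    # EM BAF is recomputed once on the final clustering below
    cur <- build_clustering(asg, signals, NULL, NULL)
    cents <- centroid_matrix(cur)
    ids <- rownames(cents)
    if (length(ids) < 2) return(cur)
    k <- sum(startsWith(colnames(cents), "rdr_"))
    rmat <- cents[, seq_len(k), drop = FALSE]
    bmat <- cents[, -seq_len(k), drop = FALSE]
    best <- NULL; bestd <- Inf
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in seq(i + 1, length(ids))) {
        dr <- abs(rmat[i, ] - rmat[j, ]); db <- abs(bmat[i, ] - bmat[j, ])
        if (all(dr < tol_r) && all(db < tol_baf)) {
          d <- max(c(dr / tol_r, db / tol_baf))
          if (d < bestd) { bestd <- d; best <- c(i, j) }
        }
      }
    }
    if (is.null(best)) {
      return(build_clustering(asg, signals, snp_counts, bins))
    }
    from <- as.integer(ids[best[2]]); to <- as.integer(ids[best[1]])
    asg$cluster[asg$cluster == from] <- to
    asg$cluster <- match(asg$cluster, sort(unique(asg$cluster)))
  }
}

#' @export
print.bin_clustering <- function(x, ...) {
  cat(sprintf("<bin_clustering> %d clusters over %d bins, %d sample(s)\n",
              length(x$lengths), nrow(x$assignment), length(x$samples)))
  invisible(x)
}

#' @export
tidy.bin_clustering <- function(x, ...) {
  x$clusters
}
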