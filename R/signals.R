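#' Compute per-bin read-depth ratios
#'
#' The read-depth ratio (RDR) of bin `s` in sample `p` is
#' `(tumor_reads / total_tumor) / (normal_reads / total_normal)`,
#' i.e. the tumor read share of the bin normalized by its matched-normal
#' share. The RDR is directly proportional to the fractional copy number of
#' the bin in the sample. Bins with zero normal coverage are flagged
#' `masked` rather than propagating non-finite values.
#'
#' @param bin_counts Tibble from [read_bin_counts()] or the simulator.
#' @param correction Optional numeric vector (one entry per bin id) of
#'   multiplicative RDR corrections, e.g. for GC or mappability bias
#'   estimated externally. Default none.
#' @return A tibble with columns `bin`, `sample`, `rdr`, `bin_reads`,
#'   `masked`.
#' @export
compute_rdr <- function(bin_counts, correction = NULL) {
  totals <- tapply(bin_counts$tumor_reads, bin_counts$sample, sum)
  if (any(totals <= 0)) abort("Each sample must have positive total reads.")
  normal <- bin_counts[!duplicated(bin_counts$bin), c("bin", "normal_reads")]
  total_normal <- sum(normal$normal_reads)
  if (total_normal <= 0) abort("The matched normal must have positive total reads.")
  df <- bin_counts
  df$total_tumor <- as.numeric(totals[df$sample])
  share_t <- df$tumor_reads / df$total_tumor
  share_n <- df$normal_reads / total_normal
  rdr <- ifelse(df$normal_reads > 0, share_t / share_n, NA_real_)
  if (!is.null(correction)) {
    rdr <- rdr * correction[df$bin]
  }
  tibble::tibble(
    bin = df$bin, sample = df$sample, rdr = rdr,
    bin_reads = df$tumor_reads, normal_reads = df$normal_reads,
    masked = df$normal_reads == 0
  )
}

#' Compute per-bin mirrored B-allele frequencies
#'
#' Estimates the mirrored B-allele frequency (BAF) of each (bin, sample)
#' from the allele counts of the heterozygous germline SNPs it contains.
#' Because the "B" (minor) allele of a bin is carried by the reference
#' allele at some SNPs and by the alternate allele at others, a two-component
#' binomial EM assigns each SNP's B side before pooling: starting from the
#' min-count side, 20 iterations alternate posterior phase weights and the
#' pooled frequency estimate. The pooled estimate is mirrored to `[0, 0.5]`.
#' Naive min-side pooling would bias the estimate downward at balanced bins;
#' the EM estimator is unbiased there.
#'
#' @param snp_counts Tibble from [read_snp_counts()].
#' @param bins Bin tibble from [make_bins()].
#' @param min_snps Minimum number of SNPs per (bin, sample) below which the
#'   bin is masked (default 5).
#' @param iterations Number of EM iterations (default 20).
#' @return A tibble with columns `bin`, `sample`, `baf`, `snp_reads`,
#'   `n_snps`, `masked`.
#' @export
compute_baf <- function(snp_counts, bins, min_snps = 5, iterations = 20) {
  df <- snp_counts
  df$bin <- assign_to_bins(bins, df$chrom, df$pos)
  df <- df[!is.na(df$bin), , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(bin = integer(), sample = character(),
                          baf = numeric(), snp_reads = numeric(),
                          n_snps = integer(), masked = logical()))
  }
  grp <- paste(df$bin, df$sample, sep = "\r")
  est <- baf_em(df$ref_reads, df$alt_reads, grp, iterations = iterations)
  out <- tibble::tibble(
    key = names(est$baf), baf = unname(est$baf),
    snp_reads = unname(est$tot), n_snps = unname(est$n)
  )
  parts <- strsplit(out$key, "\r", fixed = TRUE)
  out$bin <- as.integer(vapply(parts, `[`, character(1), 1))
  out$sample <- vapply(parts, `[`, character(1), 2)
  out$masked <- out$n_snps < min_snps | out$snp_reads == 0
  out[, c("bin", "sample", "baf", "snp_reads", "n_snps", "masked")]
}

#' Two-component binomial EM for pooled mirrored allele frequency
#'
#' @param ref,alt Per-SNP counts; `grp` a grouping key (one estimate per
#'   group).
#' @return List with per-group `baf` (mirrored), `tot` read totals and `n`
#'   SNP counts, named by group.
#' @keywords internal
baf_em <- function(ref, alt, grp, iterations = 20) {
  grp <- factor(grp)
  tot <- ref + alt
  totals <- tapply(tot, grp, sum)
  ns <- tapply(tot, grp, length)
  # init: min-side pooling
  beta <- tapply(pmin(ref, alt), grp, sum) / pmax(totals, 1)
  beta <- pmin(pmax(beta, 1e-6), 0.5)
  gi <- as.integer(grp)
  for (it in seq_len(iterations)) {
    b <- beta[gi]
    # posterior that the B allele is the alt allele at each SNP
    la <- dbinom(alt, tot, b, log = TRUE)
    lr <- dbinom(ref, tot, b, log = TRUE)
    w <- 1 / (1 + exp(lr - la))
    bcount <- w * alt + (1 - w) * ref
    beta <- as.numeric(tapply(bcount, grp, sum)) / pmax(as.numeric(totals), 1)
    beta <- setNames(beta, levels(grp))
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
    beta <- ifelse(beta > 0.5, 1 - beta, beta) # mirror (idempotent)
  }
  # The symmetric two-component mixture is degenerate at beta = 0.5: on
  # truly balanced data the EM settles slightly below 0.5. Snap to 0.5
  # unless a likelihood-ratio test favors the mixture over a plain
  # Binomial(0.5) model (1% level).
  b <- beta[gi]
  l_mix <- log(0.5 * dbinom(alt, tot, b) + 0.5 * dbinom(alt, tot, 1 - b))
  l_null <- dbinom(alt, tot, 0.5, log = TRUE)
  lrt <- 2 * (as.numeric(tapply(l_mix, grp, sum)) -
                as.numeric(tapply(l_null, grp, sum)))
  beta[lrt < stats::qchisq(0.99, 1)] <- 0.5
  # allow exact 0 at LOH extremes
  zero <- tapply(pmin(ref, alt), grp, sum) == 0
  beta[zero] <- 0
  list(baf = setNames(as.numeric(beta), names(beta)),
       tot = as.numeric(totals), n = as.integer(ns))
}

#' Join RDR and BAF into per-bin signals
#'
#' Convenience constructor of the per-(bin, sample) signal table consumed by
#' [cluster_bins()]. A bin is masked if it is masked in either signal, lies
#' on an excluded chromosome, or lacks SNP coverage.
#'
#' @inheritParams compute_rdr
#' @inheritParams compute_baf
#' @return A tibble with columns `bin`, `chrom`, `start`, `end`, `sample`,
#'   `rdr`, `baf`, `snp_reads`, `bin_reads`, `masked`.
#' @export
bin_signals <- function(bin_counts, snp_counts, bins, min_snps = 5,
                        correction = NULL) {
  rdr <- compute_rdr(bin_counts, correction = correction)
  baf <- compute_baf(snp_counts, bins, min_snps = min_snps)
  out <- dplyr::left_join(rdr, baf, by = c("bin", "sample"),
                          suffix = c("_rdr", "_baf"))
  out$masked <- out$masked_rdr | dplyr::coalesce(out$masked_baf, TRUE)
  out$baf[is.na(out$baf)] <- NA_real_
  meta <- bins[, c("bin", "chrom", "start", "end", "excluded")]
  out <- dplyr::inner_join(meta, out, by = "bin")
  out$masked <- out$masked | out$excluded
  tibble::as_tibble(out[, c("bin", "chrom", "start", "end", "sample", "rdr",
                            "baf", "snp_reads", "bin_reads", "normal_reads",
                            "masked")])
}

#' Joint-phase binomial EM across samples at cluster level
#'
#' One phase assignment per SNP shared by all samples, with a free
#' B-allele frequency per (cluster, sample): the E-step multiplies each
#' SNP's likelihood across samples, so an allele-imbalanced sample pins the
#' phase for the balanced ones. Per cluster, frequencies are flipped so
#' their mean is at most 0.5 (the "B" side is the genome-wide minor one);
#' individual samples may then legitimately exceed 0.5. Clusters whose
#' joint likelihood does not beat the all-balanced null (1% LRT) are set
#' to 0.5 everywhere.
#'
#' @param ref,alt Per-row counts; `cluster`, `sample`, `snp` parallel keys.
#' @return Tibble with `cluster`, `sample`, `baf`.
#' @keywords internal
baf_em_joint <- function(ref, alt, cluster, sample, snp, iterations = 15) {
  grp <- factor(paste(cluster, sample, sep = "\r"))
  snpf <- factor(paste(cluster, snp, sep = "\r"))
  clf <- factor(cluster)
  tot <- ref + alt
  gi <- as.integer(grp); si <- as.integer(snpf)
  totals <- as.numeric(rowsum(tot, gi))
  beta <- as.numeric(rowsum(pmin(ref, alt), gi)) / pmax(totals, 1)
  beta <- pmin(pmax(beta, 1e-6), 0.5)
  # binomial log-likelihood up to the (phase-independent) binomial
  # coefficient, which cancels in every comparison below
  llik <- function(x, size, p) x * log(p) + (size - x) * log1p(-p)
  for (it in seq_len(iterations)) {
    b <- beta[gi]
    la <- llik(alt, tot, b)
    lr <- llik(ref, tot, b)
    # one phase per SNP: pool evidence across samples
    sa <- as.numeric(rowsum(la, si))
    sr <- as.numeric(rowsum(lr, si))
    w_snp <- 1 / (1 + exp(sr - sa))
    w <- w_snp[si]
    bcount <- w * alt + (1 - w) * ref
    beta <- as.numeric(rowsum(bcount, gi)) / pmax(totals, 1)
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  }
  # orient each cluster so the mean frequency is <= 0.5
  key <- strsplit(levels(grp), "\r", fixed = TRUE)
  gcl <- vapply(key, `[`, character(1), 1)
  flip <- tapply(beta, gcl, mean) > 0.5
  beta <- ifelse(flip[gcl], 1 - beta, beta)
  # balanced-null LRT per cluster
  b <- beta[gi]
  l_mix <- log(0.5 * exp(llik(alt, tot, b)) + 0.5 * exp(llik(alt, tot, 1 - b)))
  l_null <- llik(alt, tot, 0.5)
  ci <- as.integer(clf)
  lrt <- 2 * (as.numeric(rowsum(l_mix, ci)) - as.numeric(rowsum(l_null, ci)))
  names(lrt) <- levels(clf)[sort(unique(ci))]
  k_cl <- tapply(seq_along(beta), gcl, length)
  snap <- lrt < stats::qchisq(0.99, 1) * as.numeric(k_cl[names(lrt)])
  beta[snap[gcl]] <- 0.5
  tibble::tibble(
    cluster = gcl,
    sample = vapply(key, `[`, character(1), 2),
    baf = unname(beta))
}

#' Pool bin signals to cluster level
#'
#' Cluster RDR is the length-weighted mean of member-bin RDRs; cluster BAF
#' re-runs the binomial phase EM on the pooled member SNP read counts with
#' the phase shared across samples ([baf_em_joint()]), so the result is
#' invariant to the order of the bins and allele-consistent across samples.
#'
#' @param signals Per-bin signal tibble from [bin_signals()].
#' @param assignment Tibble with columns `bin`, `cluster`.
#' @param snp_counts SNP table used to re-pool cluster BAF; if `NULL`, the
#'   length-weighted mean of bin BAFs is used instead.
#' @param bins Bin tibble (required when `snp_counts` is given).
#' @return A tibble with columns `cluster`, `sample`, `rdr`, `baf`,
#'   `length`, `n_bins`.
#' @export
pool_signals <- function(signals, assignment, snp_counts = NULL, bins = NULL) {
  df <- dplyr::inner_join(signals[!signals$masked, , drop = FALSE],
                          assignment, by = "bin")
  if (nrow(df) == 0) abort("No unmasked bins to pool.")
  df$len <- df$end - df$start
  if (!("normal_reads" %in% names(df))) df$normal_reads <- NA_real_
  if (!("snp_reads" %in% names(df))) df$snp_reads <- NA_real_
  pooled <- dplyr::summarise(
    dplyr::group_by(df, .data$cluster, .data$sample),
    rdr = sum(.data$rdr * .data$len) / sum(.data$len),
    baf = sum(.data$baf * .data$len) / sum(.data$len),
    length = sum(.data$len),
    n_bins = dplyr::n(),
    bin_reads = sum(.data$bin_reads),
    normal_reads = sum(.data$normal_reads),
    snp_reads = sum(.data$snp_reads), .groups = "drop")
  if (!is.null(snp_counts)) {
    stopifnot(!is.null(bins))
    sc <- snp_counts
    sc$bin <- assign_to_bins(bins, sc$chrom, sc$pos)
    sc <- dplyr::inner_join(sc, assignment, by = "bin")
    if (nrow(sc) > 0) {
      em <- baf_em_joint(sc$ref_reads, sc$alt_reads, sc$cluster, sc$sample,
                         paste(sc$chrom, sc$pos))
      em$cluster <- utils::type.convert(em$cluster, as.is = TRUE)
      names(em)[names(em) == "baf"] <- "baf_em"
      pooled <- dplyr::left_join(pooled, em, by = c("cluster", "sample"))
      pooled$baf <- dplyr::coalesce(pooled$baf_em, pooled$baf)
      pooled$baf_em <- NULL
    }
  }
  dplyr::arrange(pooled, .data$cluster, .data$sample)
}
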