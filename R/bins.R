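#' Tile a genome into fixed-width bins
#'
#' Partitions each chromosome into consecutive, non-overlapping bins of a
#' fixed width, left to right; the last bin of a chromosome is truncated at
#' the chromosome end. Coordinates are 0-based, half-open (BED convention).
#'
#' Sex and mitochondrial chromosomes (names matching X, Y, M/MT, with or
#' without a "chr" prefix) are retained but flagged `excluded`, and are left
#' out of clustering and scaling by downstream steps, which analyze
#' autosomes only.
#'
#' @param chrom_lengths Named numeric vector or list mapping chromosome name
#'   to its length in bp.
#' @param width Bin width in bp (default 50000).
#' @return A tibble with columns `chrom`, `start`, `end`, `bin` (integer id,
#'   unique genome-wide) and `excluded` (logical).
#' @examples
#' make_bins(c(chr1 = 120000), width = 50000)
#' @export
make_bins <- function(chrom_lengths, width = 50000) {
  chrom_lengths <- unlist(chrom_lengths)
  if (length(chrom_lengths) == 0) {
    abort("`chrom_lengths` must name at least one chromosome.")
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be named by chromosome.")
  }
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    abort("`width` must be a single positive number.")
  }
  if (any(chrom_lengths <= 0)) {
    abort("All chromosome lengths must be positive.")
  }
  res <- purrr::imap(as.list(chrom_lengths), function(len, chrom) {
    starts <- seq(0, len - 1, by = width)
    tibble::tibble(
      chrom = chrom,
      start = starts,
      end = pmin(starts + width, len)
    )
  })
  out <- dplyr::bind_rows(res)
  out$bin <- seq_len(nrow(out))
  out$excluded <- is_sex_or_mito(out$chrom)
  out
}

is_sex_or_mito <- function(chrom) {
  stripped <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
  stripped %in% c("X", "Y", "M", "MT")
}

#' Assign 1-based positions to bins
#'
#' @param bins Bin tibble from [make_bins()].
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions (VCF convention).
#' @return Integer vector of bin ids (`NA` for positions outside any bin).
#' @keywords internal
assign_to_bins <- function(bins, chrom, pos) {
  # regular tiling per chromosome: direct index arithmetic
  per_chrom <- split(seq_len(nrow(bins)), bins$chrom)
  out <- rep(NA_integer_, length(pos))
  for (cn in names(per_chrom)) {
    idx <- per_chrom[[cn]]
    sel <- which(chrom == cn)
    if (length(sel) == 0) next
    b <- bins[idx, ]
    width <- b$end[1] - b$start[1]
    p0 <- pos[sel] - 1 # to 0-based
    j <- findInterval(p0, b$start)
    ok <- j >= 1 & p0 < b$end[pmax(j, 1)]
    out[sel[ok]] <- b$bin[j[ok]]
  }
  out
}

check_bins <- function(bins) {
  stopifnot(all(c("chrom", "start", "end", "bin") %in% names(bins)))
  if (any(bins$end <= bins$start)) abort("Bins must satisfy end > start.")
  by_chrom <- split(bins, bins$chrom)
  for (b in by_chrom) {
    b <- b[order(b$start), ]
    if (any(b$start[-1] < b$end[-nrow(b)])) {
      abort("Bins on a chromosome must be non-overlapping.")
    }
  }
  invisible(bins)
}
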