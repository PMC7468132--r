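#' Read a per-bin read-count table
#'
#' Reads a tab-separated file with mandatory header
#' `CHROM START END SAMPLE TUMOR_READS NORMAL_READS`, one row per
#' (bin, tumor sample). The matched-normal read count of a bin is repeated
#' on each of its rows and must agree across samples.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chrom`, `start`, `end`, `bin`, `sample`,
#'   `tumor_reads`, `normal_reads`, validated so that every bin is present
#'   for every sample and all counts are non-negative integers.
#' @export
read_bin_counts <- function(path) {
  df <- read_tsv_checked(path,
    c("CHROM", "START", "END", "SAMPLE", "TUMOR_READS", "NORMAL_READS"))
  names(df) <- c("chrom", "start", "end", "sample", "tumor_reads", "normal_reads")
  check_nonnegative_int(df, c("tumor_reads", "normal_reads"), path)
  validate_bin_counts(df)
}

#' @keywords internal
validate_bin_counts <- function(df) {
  df <- dplyr::arrange(df, .data$chrom, .data$start, .data$sample)
  key <- paste(df$chrom, df$start, df$end)
  df$bin <- match(key, unique(key))
  # every bin present for every sample
  tab <- table(df$bin, df$sample)
  if (any(tab != 1)) {
    abort("Every bin must appear exactly once for every sample.")
  }
  # normal reads consistent per bin across samples
  nr <- tapply(df$normal_reads, df$bin, function(x) length(unique(x)))
  if (any(nr != 1)) {
    abort("NORMAL_READS must be identical across samples for each bin.")
  }
  tibble::as_tibble(df[, c("chrom", "start", "end", "bin", "sample",
                           "tumor_reads", "normal_reads")])
}

#' Read a per-SNP allele-count table
#'
#' Tab-separated file with header `CHROM POS SAMPLE REF_READS ALT_READS`,
#' one row per (heterozygous germline SNP, sample). Positions are 1-based
#' (VCF convention).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chrom`, `pos`, `sample`, `ref_reads`,
#'   `alt_reads`.
#' @export
read_snp_counts <- function(path) {
  df <- read_tsv_checked(path, c("CHROM", "POS", "SAMPLE", "REF_READS", "ALT_READS"))
  names(df) <- c("chrom", "pos", "sample", "ref_reads", "alt_reads")
  check_nonnegative_int(df, c("ref_reads", "alt_reads"), path)
  if (anyDuplicated(df[, c("chrom", "pos", "sample")])) {
    abort(sprintf("Duplicated SNP positions per sample in '%s'.", path))
  }
  tibble::as_tibble(df)
}

#' Read a somatic-mutation count table
#'
#' Tab-separated file with header `CHROM POS SAMPLE VAR_READS TOTAL_READS`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chrom`, `pos`, `sample`, `var_reads`,
#'   `total_reads`, with `0 <= var_reads <= total_reads`.
#' @export
read_mutation_counts <- function(path) {
  df <- read_tsv_checked(path, c("CHROM", "POS", "SAMPLE", "VAR_READS", "TOTAL_READS"))
  names(df) <- c("chrom", "pos", "sample", "var_reads", "total_reads")
  check_nonnegative_int(df, c("var_reads", "total_reads"), path)
  bad <- which(df$var_reads > df$total_reads)
  if (length(bad) > 0) {
    abort(sprintf("VAR_READS exceeds TOTAL_READS at line %d of '%s'.",
                  bad[1] + 1L, path))
  }
  tibble::as_tibble(df)
}

read_tsv_checked <- function(path, expected) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected)) {
    abort(sprintf("Malformed header in '%s': expected '%s', found '%s'.",
                  path, paste(expected, collapse = " "),
                  paste(header, collapse = " ")))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  as.data.frame(df)
}

check_nonnegative_int <- function(df, cols, path) {
  for (col in cols) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      abort(sprintf("Column %s of '%s' must be numeric.", col, path))
    }
    bad <- which(x < 0 | x != floor(x))
    if (length(bad) > 0) {
      # +1 for the header line
      abort(sprintf("Invalid count in column %s at line %d of '%s'.",
                    col, bad[1] + 1L, path))
    }
  }
  invisible(df)
}

#' Write a per-bin count table
#'
#' Inverse of [read_bin_counts()]; writing then reading reproduces the
#' table.
#'
#' @param bin_counts Tibble as returned by [read_bin_counts()] or the
#'   simulator.
#' @param path Output path.
#' @export
write_bin_counts <- function(bin_counts, path) {
  out <- data.frame(
    CHROM = bin_counts$chrom, START = bin_counts$start, END = bin_counts$end,
    SAMPLE = bin_counts$sample, TUMOR_READS = bin_counts$tumor_reads,
    NORMAL_READS = bin_counts$normal_reads)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a per-SNP allele-count table
#' @param snp_counts Tibble as returned by [read_snp_counts()].
#' @param path Output path.
#' @export
write_snp_counts <- function(snp_counts, path) {
  out <- data.frame(
    CHROM = snp_counts$chrom, POS = snp_counts$pos, SAMPLE = snp_counts$sample,
    REF_READS = snp_counts$ref_reads, ALT_READS = snp_counts$alt_reads)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a somatic-mutation count table
#' @param mutations Tibble as returned by [read_mutation_counts()].
#' @param path Output path.
#' @export
write_mutation_counts <- function(mutations, path) {
  out <- data.frame(
    CHROM = mutations$chrom, POS = mutations$pos, SAMPLE = mutations$sample,
    VAR_READS = mutations$var_reads, TOTAL_READS = mutations$total_reads)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a clone copy-number profile
#'
#' Serializes a fitted solution to a BED-like TSV with header
#' `CHROM START END CLUSTER`, one `a|b` copy-number-state column per clone,
#' and one clone-proportion column per sample. If a clustering is supplied,
#' one row is written per run of consecutive bins sharing a cluster;
#' otherwise one row per cluster with its aggregate genomic length.
#' Proportions are written at full precision so that re-reading reproduces
#' `A`, `B` and `U` exactly.
#'
#' @param solution A `cna_solution` object (see [solve_cacf_cd()]).
#' @param path Output path.
#' @param clustering Optional `bin_clustering` used to expand clusters to
#'   genomic intervals.
#' @export
write_clone_profile <- function(solution, path, clustering = NULL) {
  stopifnot(inherits(solution, "cna_solution"))
  A <- solution$A; B <- solution$B; U <- solution$U
  clusters <- rownames(A)
  if (is.null(clustering)) {
    seg <- tibble::tibble(chrom = paste0("cluster_", clusters), start = 0,
                          end = solution$lengths, cluster = clusters)
  } else {
    bins <- dplyr::inner_join(clustering$bins, clustering$assignment, by = "bin")
    bins <- dplyr::arrange(bins, .data$chrom, .data$start)
    bins$run <- cumsum(c(TRUE, bins$cluster[-1] != bins$cluster[-nrow(bins)] |
                           bins$chrom[-1] != bins$chrom[-nrow(bins)] |
                           bins$start[-1] != bins$end[-nrow(bins)]))
    seg <- dplyr::summarise(dplyr::group_by(bins, .data$run),
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      cluster = as.character(.data$cluster[1]), .groups = "drop")
    seg <- seg[seg$cluster %in% clusters, c("chrom", "start", "end", "cluster")]
  }
  idx <- match(seg$cluster, clusters)
  states <- vapply(seq_len(ncol(A)), function(i) {
    paste0(A[idx, i], "|", B[idx, i])
  }, character(nrow(seg)))
  states <- matrix(states, nrow = nrow(seg))
  colnames(states) <- colnames(A)
  # per-sample proportion columns: the full clone-proportion vector of the
  # sample, constant across rows (comma-separated, full precision)
  upcols <- do.call(cbind, lapply(seq_len(ncol(U)), function(p) {
    rep(paste(sprintf("%.17g", U[, p]), collapse = ";"), nrow(seg))
  }))
  colnames(upcols) <- paste0("u_", colnames(U))
  out <- data.frame(CHROM = seg$chrom, START = seg$start, END = seg$end,
                    CLUSTER = seg$cluster, states, upcols,
                    check.names = FALSE)
  # also store lengths to allow exact reconstruction
  out$LENGTH <- as.numeric(solution$lengths[idx])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a clone copy-number profile
#'
#' Inverse of [write_clone_profile()]; reconstructs the copy-number
#' matrices `A`, `B`, the proportion matrix `U` and the cluster lengths.
#'
#' @param path Path to a profile TSV.
#' @return A `cna_solution` object (without an objective value).
#' @export
read_clone_profile <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  need <- c("CHROM", "START", "END", "CLUSTER")
  if (!all(need %in% names(df))) abort("Malformed clone-profile header.")
  state_cols <- names(df)[grepl("\\|", vapply(df[1, , drop = FALSE],
                                              as.character, character(1)))]
  state_cols <- setdiff(state_cols, need)
  u_cols <- names(df)[startsWith(names(df), "u_")]
  first <- df[!duplicated(df$CLUSTER), , drop = FALSE]
  clusters <- as.character(first$CLUSTER)
  A <- B <- matrix(0L, nrow(first), length(state_cols),
                   dimnames = list(clusters, state_cols))
  for (j in seq_along(state_cols)) {
    parts <- strsplit(as.character(first[[state_cols[j]]]), "|", fixed = TRUE)
    A[, j] <- as.integer(vapply(parts, `[`, character(1), 1))
    B[, j] <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  U <- vapply(u_cols, function(cn) {
    as.numeric(strsplit(as.character(first[[cn]][1]), ";", fixed = TRUE)[[1]])
  }, numeric(length(state_cols)))
  U <- matrix(U, nrow = length(state_cols),
              dimnames = list(state_cols, sub("^u_", "", u_cols)))
  lengths <- if ("LENGTH" %in% names(df)) {
    as.numeric(first$LENGTH)
  } else {
    tapply(df$END - df$START, df$CLUSTER, sum)[clusters]
  }
  new_cna_solution(A = A, B = B, U = U, lengths = setNames(lengths, clusters),
                   objective = NA_real_, hypothesis = NULL)
}
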