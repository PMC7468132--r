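#' Run the full copy-number deconvolution pipeline
#'
#' Five stages: (1) per-bin RDR/BAF computation; (2) global clustering of
#' bins jointly across samples, with post-hoc merging; (3) scaling of
#' cluster RDRs to allele-specific fractional copy numbers under the
#' no-WGD and (when feasible) WGD hypotheses; (4) constrained
#' factorization over a grid of clone numbers for each hypothesis;
#' (5) model selection, cluster classification and per-sample summary.
#' Deterministic given `seed`. When `out_dir` is given, writes the signal,
#' cluster, profile and summary TSVs plus the resolved configuration.
#'
#' @param bin_counts Per-bin count tibble ([read_bin_counts()]).
#' @param snp_counts Per-SNP count tibble ([read_snp_counts()]).
#' @param bins Optional bin tibble; inferred from `bin_counts` if absent.
#' @param out_dir Optional output directory.
#' @param cmax,umin,n_max,tau Core model parameters (defaults 12, 0.03, 6,
#'   0.05).
#' @param min_snps Minimum SNPs per bin (default 5).
#' @param tol_r,tol_baf Cluster merge / anchor tolerances (defaults 0.08,
#'   0.04).
#' @param max_components,restarts Clustering truncation and solver
#'   restarts (defaults 50, 10).
#' @param seed Integer seed (default 1).
#' @return A `cna_run` list: `signals`, `clustering`, `hypotheses`,
#'   `fractionals`, `grid`, `solution`, `classification`, `summary`.
#' @export
run_pipeline <- function(bin_counts, snp_counts, bins = NULL, out_dir = NULL,
                         cmax = 12, umin = 0.03, n_max = 6, tau = 0.05,
                         min_snps = 5, tol_r = 0.08, tol_baf = 0.04,
                         max_components = 50, restarts = 10, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  if (is.null(bins)) {
    meta <- bin_counts[!duplicated(bin_counts$bin),
                       c("chrom", "start", "end", "bin")]
    bins <- tibble::as_tibble(meta[order(meta$bin), ])
    bins$excluded <- is_sex_or_mito(bins$chrom)
  }
  signals <- stage("rdr_baf",
    bin_signals(bin_counts, snp_counts, bins, min_snps = min_snps))
  clustering <- stage("global_cluster", {
    cl <- cluster_bins(signals, max_components = max_components, seed = seed,
                       snp_counts = snp_counts, bins = bins)
    merge_clusters(cl, signals, tol_r = tol_r, tol_baf = tol_baf,
                   snp_counts = snp_counts, bins = bins)
  })
  hyps <- stage("fractional_scaling",
    scaling_hypotheses(clustering, tol_r = tol_r, tol_baf = tol_baf))
  fractionals <- stage("fractional_scaling",
    lapply(hyps, function(h) scale_to_fractional(clustering, h)))
  grid <- stage("deconvolution",
    fit_model_grid(fractionals, n_max = n_max, cmax = cmax, umin = umin,
                   restarts = restarts, seed = seed, tau = tau))
  solution <- stage("model_selection", select_solution(grid, tau = tau))
  classification <- stage("model_selection", classify_clusters(solution))
  summary <- stage("model_selection", summarize_solution(solution))
  run <- structure(list(
    signals = signals, clustering = clustering, hypotheses = hyps,
    fractionals = fractionals, grid = grid, solution = solution,
    classification = classification, summary = summary,
    params = list(cmax = cmax, umin = umin, n_max = n_max, tau = tau,
                  min_snps = min_snps, tol_r = tol_r, tol_baf = tol_baf,
                  max_components = max_components, restarts = restarts,
                  seed = seed)), class = "cna_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig <- run$signals
  readr::write_tsv(data.frame(
    CHROM = sig$chrom, START = sig$start, END = sig$end, SAMPLE = sig$sample,
    RDR = sig$rdr, BAF = sig$baf), file.path(out_dir, "signals.tsv"),
    progress = FALSE)
  asg <- dplyr::inner_join(run$clustering$bins, run$clustering$assignment,
                           by = "bin")
  readr::write_tsv(data.frame(
    CHROM = asg$chrom, START = asg$start, END = asg$end, CLUSTER = asg$cluster),
    file.path(out_dir, "clusters.tsv"), progress = FALSE)
  cent <- as.data.frame(run$clustering$clusters)
  cent[] <- lapply(cent, function(x) if (is.numeric(x)) as.numeric(x) else x)
  readr::write_tsv(cent, file.path(out_dir, "centroids.tsv"),
                   progress = FALSE)
  write_clone_profile(run$solution, file.path(out_dir, "clone_profile.tsv"),
                      clustering = run$clustering)
  readr::write_tsv(run$summary, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  jsonlite::write_json(run$params, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(c(
    sprintf("clusters: %d", length(run$clustering$lengths)),
    sprintf("hypotheses: %s", paste(names(run$hypotheses), collapse = ", ")),
    sprintf("selected: n = %d, wgd = %s, D = %.6g",
            ncol(run$solution$A), isTRUE(run$solution$hypothesis$wgd),
            run$solution$objective),
    sprintf("samples: %s", paste(run$summary$sample, collapse = ", "))),
    file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.cna_run <- function(x, ...) {
  cat(sprintf("<cna_run> %d clusters; selected %d clones (%s); D = %.4g\n",
              length(x$clustering$lengths), ncol(x$solution$A),
              if (isTRUE(x$solution$hypothesis$wgd)) "WGD" else "no-WGD",
              x$solution$objective))
  print(x$summary)
  invisible(x)
}

#' Glance at a pipeline run
#' @param x A `cna_run`.
#' @param ... Unused.
#' @export
glance.cna_run <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$clustering$lengths),
    n_clones = ncol(x$solution$A),
    wgd = isTRUE(x$solution$hypothesis$wgd),
    objective = x$solution$objective,
    mean_purity = mean(x$summary$purity))
}
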