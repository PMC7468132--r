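# Shared fixture builders: everything is generated in code at test time.

# a valid random factorization instance (noiseless unless sigma > 0)
random_instance <- function(m, n, k, cmax = 12, theta = 1, sigma = 0,
                            umin = 0.03) {
  # theta-sided tumor copy vectors per allele
  draw_side <- function() {
    if (runif(1) < 0.5) sample(0:theta, n - 1, replace = TRUE)
    else sample(theta:min(cmax, theta + 4), n - 1, replace = TRUE)
  }
  A <- matrix(1L, m, n); B <- matrix(1L, m, n)
  for (s in seq_len(m)) {
    repeat {
      a <- draw_side(); b <- draw_side()
      if (all(a + b <= cmax)) break
    }
    A[s, -1] <- a; B[s, -1] <- b
  }
  U <- matrix(rgamma(n * k, 1), n, k)
  U <- sweep(U, 2, colSums(U), `/`)
  for (p in seq_len(k)) {
    drop <- which(U[-1, p] < umin) + 1
    U[drop, p] <- 0
    U[, p] <- U[, p] / sum(U[, p])
  }
  lengths <- runif(m, 1, 3)
  FA <- A %*% U + matrix(rnorm(m * k, 0, sigma), m, k)
  FB <- B %*% U + matrix(rnorm(m * k, 0, sigma), m, k)
  FA[FA < 0] <- 0; FB[FB < 0] <- 0
  list(A = A, B = B, U = U, FA = FA, FB = FB, lengths = lengths)
}

# tumor-clone-permutation-invariant comparison of two solutions
same_up_to_permutation <- function(sol, A, B, U, tol = 1e-6) {
  nt <- ncol(sol$A) - 1
  if (ncol(A) - 1 != nt) return(FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  for (p in perms(seq_len(nt) + 1)) {
    idx <- c(1, p)
    if (max(abs(sol$A[, idx] - A)) < tol && max(abs(sol$B[, idx] - B)) < tol &&
        max(abs(sol$U[idx, ] - U)) < tol) {
      return(TRUE)
    }
  }
  FALSE
}

# a tiny two-sample bin-count tibble with known shares
toy_bin_counts <- function() {
  bins <- make_bins(c(chr1 = 100000), width = 50000)
  tibble::tibble(
    chrom = "chr1", start = rep(c(0, 50000), 2), end = rep(c(50000, 1e5), 2),
    bin = rep(1:2, 2), sample = rep(c("s1", "s2"), each = 2),
    tumor_reads = c(300, 700, 500, 500), normal_reads = rep(c(500, 500), 2))
}

# build a bin_clustering object directly from a centroid specification
fake_clustering <- function(centroids, lengths) {
  # centroids: tibble(cluster, sample, rdr, baf)
  ids <- unique(centroids$cluster)
  centroids$length <- lengths[match(centroids$cluster, ids)]
  centroids$n_bins <- 1L
  structure(list(
    assignment = tibble::tibble(bin = seq_along(ids), cluster = ids),
    clusters = centroids,
    lengths = stats::setNames(lengths, ids),
    bins = tibble::tibble(bin = seq_along(ids), chrom = "chr1",
                          start = 0, end = lengths),
    samples = sort(unique(centroids$sample))
  ), class = "bin_clustering")
}

quick_patient <- function(seed, wgd = FALSE, n_clones = 3, n_samples = 2,
                          coverage = 30, genome_size = 4e7) {
  simulate_patient(sim_config(
    n_clones = n_clones, n_samples = n_samples, wgd = wgd,
    coverage = coverage, genome_size = genome_size, seed = seed))
}
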