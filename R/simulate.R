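# Counts-level simulator of multi-sample bulk tumor sequencing.
#
# Clone genomes accumulate CNAs (and at most one clonal WGD) along a random
# phylogeny; per-sample read counts are multinomial with bin probabilities
# proportional to the mixture's genome content, so clones with longer
# genomes contribute proportionally more reads (the genome-length
# correction v_{i,p} = u_{i,p} L_i / sum_j u_{j,p} L_j).

# sample() without the length-1 surprise
resample <- function(x, size = 1) x[sample.int(length(x), size)]

# approximate human autosome lengths (Mb), used as relative proportions
hg_autosome_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
                    134, 115, 107, 102, 90, 81, 78, 59, 63, 48, 51)

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulate_patient()]. Event
#' sizes follow pan-cancer size classes (focal < 1 Mb, small 3-5 Mb,
#' medium 10-20 Mb, arm- and chromosome-level), scaled linearly with the
#' configured genome size relative to a 3 Gb reference so that the same
#' class structure holds on reduced test genomes.
#'
#' @param n_clones Total clones including the diploid normal (2-4 typical).
#' @param n_samples Number of bulk samples (3-5 typical).
#' @param wgd Whether a clonal whole-genome duplication occurs (on the
#'   trunk, so it affects all tumor clones).
#' @param coverage Haploid-genome-normalized sequencing coverage (default
#'   30).
#' @param read_length Nominal read length used to convert coverage to a
#'   total read count (default 100).
#' @param genome_size Total reference genome length in bp (default 3e9;
#'   reduced profiles such as 1e8 scale the 22 autosomes proportionally).
#' @param bin_width Bin width for the emitted count table (default 50000).
#' @param snp_spacing Average spacing of heterozygous germline SNPs
#'   (default 2000 bp).
#' @param event_counts Named counts of CNA events per tumor branch.
#' @param umin Minimum tumor-clone proportion in a sample (default 0.03).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clones = 3, n_samples = 3, wgd = FALSE,
                       coverage = 30, read_length = 100, genome_size = 3e9,
                       bin_width = 50000, snp_spacing = 2000,
                       event_counts = c(focal = 6, small = 4, medium = 3,
                                        arm = 2, chromosome = 1),
                       umin = 0.03, seed) {
  if (missing(seed)) abort("`seed` is mandatory in `sim_config()`.")
  stopifnot(n_clones >= 2, n_samples >= 1, coverage > 0, genome_size > 0,
            bin_width > 0, snp_spacing > 0, umin > 0, umin < 1)
  structure(list(n_clones = n_clones, n_samples = n_samples, wgd = wgd,
                 coverage = coverage, read_length = read_length,
                 genome_size = genome_size, bin_width = bin_width,
                 snp_spacing = snp_spacing, event_counts = event_counts,
                 umin = umin, seed = as.integer(seed)), class = "sim_config")
}

sim_chrom_lengths <- function(genome_size) {
  props <- hg_autosome_mb / sum(hg_autosome_mb)
  lens <- round(props * genome_size)
  setNames(lens, paste0("chr", seq_along(lens)))
}

# draw one CNA event of a size class; sizes scale with genome_size / 3 Gb.
# Breakpoints are placed on the bin grid: the simulator emulates
# segment-level CNAs at the granularity the method consumes, so sub-bin
# breakpoint placement (which would only blur bin signals) is not modeled.
draw_event <- function(kind, chrom_lengths, scale, bin_width) {
  chrom <- sample(names(chrom_lengths), 1)
  clen <- chrom_lengths[[chrom]]
  span <- switch(kind,
    focal = runif(1, 0.1e6, 1e6) * scale,
    small = runif(1, 3e6, 5e6) * scale,
    medium = runif(1, 10e6, 20e6) * scale,
    arm = NA, chromosome = NA)
  snap <- function(x) round(x / bin_width) * bin_width
  if (kind == "chromosome") {
    start <- 0; end <- clen
  } else if (kind == "arm") {
    if (runif(1) < 0.5) { start <- 0; end <- min(snap(clen / 2), clen) }
    else { start <- min(snap(clen / 2), clen); end <- clen }
  } else {
    span <- max(bin_width, snap(min(span, clen)))
    start <- snap(runif(1, 0, max(clen - span, 0)))
    end <- min(start + span, clen)
  }
  list(kind = kind, chrom = chrom, start = start, end = end,
       allele = sample(c("a", "b"), 1),
       delta = sample(c(-1L, 1L), 1))
}

# apply one event to a clone genome (tibble chrom, start, end, a, b)
apply_event <- function(genome, ev) {
  if (identical(ev$kind, "WGD")) {
    genome$a <- genome$a * 2L
    genome$b <- genome$b * 2L
    return(genome)
  }
  sel <- genome$chrom == ev$chrom & genome$end > ev$start &
    genome$start < ev$end
  if (!any(sel)) return(genome)
  rows <- genome[sel, , drop = FALSE]
  untouched <- genome[!sel, , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$start < ev$start) {
      pieces[[length(pieces) + 1]] <- transform(r, end = ev$start)
    }
    if (r$end > ev$end) {
      pieces[[length(pieces) + 1]] <- transform(r, start = ev$end)
    }
    mid <- r
    mid$start <- max(r$start, ev$start)
    mid$end <- min(r$end, ev$end)
    x <- mid[[ev$allele]]
    if (ev$delta > 0 && x >= 1) mid[[ev$allele]] <- x + 1L
    if (ev$delta < 0 && x >= 1) mid[[ev$allele]] <- x - 1L
    pieces[[length(pieces) + 1]] <- mid
  }
  out <- dplyr::bind_rows(c(list(untouched), pieces))
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Simulate one multi-sample bulk tumor patient at counts level
#'
#' Four generative steps: (1) a diploid normal genome over 22
#' proportionally scaled autosomes; (2) tumor-clone genomes accumulating
#' CNAs of the configured size classes in random order along a random clone
#' phylogeny, with at most one WGD placed on the trunk; (3) per sample, a
#' random tumor-clone subset (every tumor clone appears in at least one
#' sample) with Dirichlet proportions respecting `umin`; (4) per-bin tumor
#' read counts drawn multinomially with probabilities proportional to the
#' mixed genome content of the bin (the genome-length-corrected read
#' proportions), matched-normal counts multinomially by bin length, and
#' per-SNP allele counts from the mixed allele-specific content.
#'
#' @param config A [sim_config()].
#' @return A `sim_patient` list: `bins`, `bin_counts`, `snp_counts`,
#'   `truth` (clone segment genomes, per-bin states, `U`, clone genome
#'   lengths `L_i`, event log, `wgd`), and the `config`.
#' @export
simulate_patient <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_lengths <- sim_chrom_lengths(config$genome_size)
  bins <- make_bins(chrom_lengths, config$bin_width)
  scale <- config$genome_size / 3e9
  n <- config$n_clones
  nt <- n - 1
  parent <- c(NA_integer_, 1L, if (nt > 1) {
    vapply(seq_len(nt - 1) + 2, function(j) resample(2:(j - 1)), integer(1))
  })
  normal <- tibble::tibble(
    chrom = names(chrom_lengths), start = 0,
    end = as.numeric(chrom_lengths), a = 1L, b = 1L)
  genomes <- vector("list", n)
  genomes[[1]] <- normal
  event_log <- list()
  for (j in 2:n) {
    evs <- unlist(lapply(names(config$event_counts), function(kind) {
      replicate(config$event_counts[[kind]],
                draw_event(kind, chrom_lengths, scale, config$bin_width),
                simplify = FALSE)
    }), recursive = FALSE)
    evs <- evs[sample.int(length(evs))]
    if (config$wgd && j == 2) {
      pos <- sample.int(length(evs) + 1, 1)
      evs <- append(evs, list(list(kind = "WGD")), after = pos - 1)
    }
    g <- genomes[[parent[j]]]
    for (ev in evs) g <- apply_event(g, ev)
    genomes[[j]] <- g
    event_log[[j]] <- evs
  }
  U <- draw_proportions(n, config$n_samples, config$umin)
  samples <- paste0("sample", seq_len(config$n_samples))
  dimnames(U) <- list(c("normal", paste0("clone", seq_len(nt) + 1)), samples)

  contentA <- sapply(genomes, function(g) clone_bin_content(g, bins, "a"))
  contentB <- sapply(genomes, function(g) clone_bin_content(g, bins, "b"))
  Li <- colSums(contentA + contentB)
  total_reads <- round(config$coverage * config$genome_size /
                         config$read_length)
  blen <- bins$end - bins$start
  normal_reads <- as.vector(rmultinom(1, total_reads, blen / sum(blen)))
  bc <- list()
  for (p in seq_len(config$n_samples)) {
    w <- as.vector((contentA + contentB) %*% U[, p])
    reads <- as.vector(rmultinom(1, total_reads, w / sum(w)))
    bc[[p]] <- tibble::tibble(
      chrom = bins$chrom, start = bins$start, end = bins$end,
      bin = bins$bin, sample = samples[p], tumor_reads = reads,
      normal_reads = normal_reads)
  }
  bin_counts <- dplyr::bind_rows(bc)
  snp_counts <- simulate_snps(genomes, U, chrom_lengths, Li, config, samples)
  truth <- list(
    genomes = genomes, parent = parent, U = U, L = Li,
    bin_states = truth_bin_states(genomes, bins),
    events = event_log, wgd = config$wgd,
    chrom_lengths = chrom_lengths)
  structure(list(bins = bins, bin_counts = bin_counts,
                 snp_counts = snp_counts, truth = truth, config = config),
            class = "sim_patient")
}

draw_proportions <- function(n, k, umin) {
  nt <- n - 1
  for (try in 1:100) {
    U <- matrix(0, n, k)
    for (p in seq_len(k)) {
      subset <- which(stats::runif(nt) < 0.7)
      if (length(subset) == 0) subset <- sample.int(nt, 1)
      repeat {
        w <- stats::rgamma(length(subset) + 1, 1)
        u <- w / sum(w)
        normal_u <- u[1]
        tum <- u[-1]
        tum[tum < umin] <- 0
        tot <- normal_u + sum(tum)
        u <- c(normal_u, tum) / tot
        if (all(u[-1] == 0 | u[-1] >= umin) && sum(u[-1]) > 0) break
      }
      U[1, p] <- u[1]
      U[subset + 1, p] <- u[-1]
    }
    if (all(rowSums(U[-1, , drop = FALSE]) > 0)) return(U)
  }
  abort("Could not draw proportions covering every tumor clone.")
}

# bp-weighted allele content of every bin for one clone genome
clone_bin_content <- function(genome, bins, allele) {
  out <- numeric(nrow(bins))
  width <- bins$end[1] - bins$start[1]
  first_bin <- tapply(bins$bin, bins$chrom, min)
  chrom_end <- tapply(bins$end, bins$chrom, max)
  for (i in seq_len(nrow(genome))) {
    g <- genome[i, ]
    cn <- g[[allele]]
    if (cn == 0) next
    fb <- first_bin[[g$chrom]]
    b0 <- fb + floor(g$start / width)
    b1 <- fb + ceiling(g$end / width) - 1
    idx <- b0:b1
    ov <- pmin(bins$end[idx], g$end) - pmax(bins$start[idx], g$start)
    out[idx] <- out[idx] + cn * ov
  }
  out
}

# per-bin majority copy-number state per clone (truth labels)
truth_bin_states <- function(genomes, bins) {
  lapply(genomes, function(g) {
    a <- clone_bin_content(g, bins, "a")
    b <- clone_bin_content(g, bins, "b")
    blen <- bins$end - bins$start
    tibble::tibble(bin = bins$bin, a = round(a / blen), b = round(b / blen))
  })
}

simulate_snps <- function(genomes, U, chrom_lengths, Li, config, samples) {
  positions <- dplyr::bind_rows(purrr::imap(as.list(chrom_lengths),
    function(len, chrom) {
      pos <- seq(config$snp_spacing, len, by = config$snp_spacing)
      tibble::tibble(chrom = chrom, pos = pos)
    }))
  # which haplotype carries the alternate allele at each SNP
  alt_is_a <- stats::runif(nrow(positions)) < 0.5
  n <- length(genomes)
  a_cn <- sapply(genomes, function(g) state_at(g, positions, "a"))
  b_cn <- sapply(genomes, function(g) state_at(g, positions, "b"))
  L <- config$genome_size
  out <- list()
  for (p in seq_len(ncol(U))) {
    denom <- sum(U[, p] * Li)
    mixa <- as.vector(a_cn %*% U[, p])
    mixb <- as.vector(b_cn %*% U[, p])
    cmix <- mixa + mixb
    depth <- rpois(length(cmix), config$coverage * 2 * L * cmix / denom / 2)
    palt <- ifelse(cmix > 0, ifelse(alt_is_a, mixa, mixb) / cmix, 0)
    alt <- rbinom(length(depth), depth, palt)
    keep <- depth > 0
    out[[p]] <- tibble::tibble(
      chrom = positions$chrom[keep], pos = positions$pos[keep],
      sample = samples[p], ref_reads = (depth - alt)[keep],
      alt_reads = alt[keep])
  }
  dplyr::bind_rows(out)
}

# allele copy number of one clone at arbitrary 1-based positions
state_at <- function(genome, positions, allele) {
  out <- numeric(nrow(positions))
  for (cn in unique(genome$chrom)) {
    segs <- genome[genome$chrom == cn, , drop = FALSE]
    segs <- segs[order(segs$start), ]
    sel <- which(positions$chrom == cn)
    if (length(sel) == 0) next
    j <- findInterval(positions$pos[sel] - 1, segs$start)
    out[sel] <- segs[[allele]][pmax(j, 1)]
  }
  out
}

#' Genome-length-corrected read proportions
#'
#' For clone proportions `U` and clone copy-number profiles, computes the
#' expected fraction of reads originating from each clone,
#' `v_{i,p} = u_{i,p} L_i / sum_j u_{j,p} L_j`, and from each (segment,
#' clone), `v_{s,i} = l_s c_{s,i} u_{i,p} / sum_j u_{j,p} L_j`. These are
#' the correct read-mixing weights when clone genome lengths differ (a
#' WGD clone contributes twice the reads of a diploid clone at equal cell
#' proportions).
#'
#' @param C Total copy-number matrix (segments x clones).
#' @param lengths Segment lengths `l_s`.
#' @param U Clone-proportion matrix (clones x samples).
#' @return List with `v_clone` (clones x samples) and `v_segment` (list,
#'   per sample, of segments x clones matrices); within each sample
#'   `sum_i v_{i,p} = 1` and `sum_s v_{s,i} = v_{i,p}`.
#' @export
mixing_proportions <- function(C, lengths, U) {
  C <- as.matrix(C); U <- as.matrix(U)
  lengths <- as.numeric(lengths)
  Li <- as.numeric(t(C) %*% lengths)
  denom <- as.numeric(t(U) %*% Li)
  if (any(denom <= 0)) abort("Zero total genome content in a sample.")
  v_clone <- sweep(U * Li, 2, denom, `/`)
  v_segment <- lapply(seq_len(ncol(U)), function(p) {
    sweep(C, 2, U[, p], `*`) * lengths / denom[p]
  })
  list(v_clone = v_clone, v_segment = v_segment)
}

#' Simulate somatic mutations with ground truth
#'
#' Places `n_mutations` somatic single-nucleotide mutations on random tumor
#' branches of a simulated patient, on one allele with at least one copy in
#' the originating clone (no homoplasy: each position mutates once). A
#' mutation drawn "early" on its branch precedes the subsequent
#' amplifications of its allele and carries the full allele copy number in
#' each descendant clone; a "late" mutation carries a single copy. Variant
#' read counts are binomial around the expected VAF implied by the mixed
#' copy numbers.
#'
#' @param patient A `sim_patient`.
#' @param n_mutations Number of mutations (default 100).
#' @param coverage Sequencing coverage for the mutation reads (default
#'   100).
#' @param seed Integer seed.
#' @return List with `mutations` (tibble `chrom`, `pos`, `sample`,
#'   `var_reads`, `total_reads`) and `truth` (origin clone, allele, early
#'   flag, per-clone mutated-copy matrix, expected VAF per sample).
#' @export
simulate_mutations <- function(patient, n_mutations = 100, coverage = 100,
                               seed = patient$config$seed + 1) {
  set.seed(seed)
  truth <- patient$truth
  n <- length(truth$genomes)
  U <- truth$U
  chrom_lengths <- truth$chrom_lengths
  desc <- descendants_matrix(truth$parent)
  rows <- list(); infos <- list()
  tries <- 0
  while (length(rows) < n_mutations && tries < n_mutations * 50) {
    tries <- tries + 1
    origin <- resample(2:n)
    chrom <- sample(names(chrom_lengths), 1)
    pos <- sample.int(chrom_lengths[[chrom]], 1)
    allele <- sample(c("a", "b"), 1)
    ptab <- tibble::tibble(chrom = chrom, pos = pos)
    x_origin <- state_at(truth$genomes[[origin]], ptab, allele)
    if (x_origin < 1) next
    early <- runif(1) < 0.5
    carriers <- which(desc[origin, ])
    ctilde <- numeric(n)
    for (i in carriers) {
      xi <- state_at(truth$genomes[[i]], ptab, allele)
      ctilde[i] <- if (early) xi else min(1, xi)
    }
    cmix_i <- vapply(seq_len(n), function(i) {
      state_at(truth$genomes[[i]], ptab, "a") +
        state_at(truth$genomes[[i]], ptab, "b")
    }, numeric(1))
    for (p in seq_len(ncol(U))) {
      denom <- sum(U[, p] * truth$L)
      cmix <- sum(cmix_i * U[, p])
      evaf <- if (cmix > 0) sum(ctilde * U[, p]) / cmix else 0
      Tp <- rpois(1, coverage * 2 * sum(chrom_lengths) * cmix / denom / 2)
      v <- rbinom(1, Tp, evaf)
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = chrom, pos = pos, sample = colnames(U)[p],
        var_reads = v, total_reads = Tp,
        mutation = length(infos) + 1L, expected_vaf = evaf)
    }
    infos[[length(infos) + 1]] <- tibble::tibble(
      mutation = length(infos) + 1L, chrom = chrom, pos = pos,
      origin = origin, allele = allele, early = early,
      ctilde = list(ctilde))
  }
  muts <- dplyr::bind_rows(rows)
  list(mutations = muts[, c("chrom", "pos", "sample", "var_reads",
                            "total_reads")],
       detail = muts, truth = dplyr::bind_rows(infos))
}

descendants_matrix <- function(parent) {
  n <- length(parent)
  D <- diag(n) > 0
  for (i in seq_len(n)) {
    j <- parent[i]
    while (!is.na(j)) { D[j, i] <- TRUE; j <- parent[j] }
  }
  D
}
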