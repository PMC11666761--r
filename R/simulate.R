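#' Simulation configuration
#'
#' Defines a synthetic dataset with the statistical structure the downstream
#' analysis assumes: several populations drifted from a common ancestor
#' (Balding-Nichols model), a minority of adaptive loci with a fixed frequency
#' shift in designated populations on an otherwise near-undifferentiated
#' background, and optional non-recombining inversion blocks segregating two
#' ancient haplotype classes (Northern "N" and Southern "S") plus, optionally,
#' a recombinant haplotype carrying an N segment on an S background.
#'
#' @param n_populations number of populations.
#' @param samples_per_pop diploid individuals per population (scalar or vector).
#' @param n_neutral_sites neutral SNPs.
#' @param n_adaptive_sites adaptive SNPs (frequency shifted in
#'   `adaptive_pops`).
#' @param drift_F per-population Balding-Nichols differentiation parameter in
#'   `[0, 1)`; the expected neutral FST. Default 0.02, the magnitude typical of
#'   weakly diverged marine ecotypes.
#' @param adaptive_delta frequency shift at adaptive sites in `[0, 1]`.
#' @param adaptive_pops indices of populations receiving the shift.
#' @param inversions list of inversion specs, each a list with `n_sites`,
#'   `s_freq` (Southern-haplotype frequency per population, recycled),
#'   optional `recombinant = list(start, end, freq)` (1-based site indices
#'   within the block; `freq` = fraction of Southern-arrangement haplotypes
#'   carrying the recombinant N segment, scalar or per-population vector), and
#'   optional `chrom`, `start_bp`,
#'   `spacing`.
#' @param missing_rate independent per-call missingness probability.
#' @param ancestral_range range of the uniform ancestral-frequency draw
#'   (default 0.05-0.95, avoiding degenerate invariant sites).
#' @param chrom,spacing chromosome name and inter-SNP spacing (bp) for the
#'   neutral/adaptive sites.
#' @param seed integer seed; identical configs and seeds give identical data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4, samples_per_pop = 20,
                       n_neutral_sites = 2000, n_adaptive_sites = 50,
                       drift_F = 0.02, adaptive_delta = 0.4,
                       adaptive_pops = 1L, inversions = list(),
                       missing_rate = 0.02, ancestral_range = c(0.05, 0.95),
                       chrom = "chr1", spacing = 100L, seed = 1L) {
  stopifnot(n_populations >= 1, n_neutral_sites >= 0, n_adaptive_sites >= 0)
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_populations)
  if (any(samples_per_pop < 1)) stop("samples_per_pop must be positive")
  if (!is.finite(drift_F) || drift_F < 0 || drift_F >= 1)
    stop("drift_F must lie in [0, 1)")
  if (adaptive_delta < 0 || adaptive_delta > 1)
    stop("adaptive_delta must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (ancestral_range[1] <= 0 || ancestral_range[2] >= 1 ||
      ancestral_range[1] > ancestral_range[2])
    stop("ancestral_range must lie strictly inside (0, 1)")
  if (any(adaptive_pops < 1 | adaptive_pops > n_populations))
    stop("adaptive_pops out of range")
  inversions <- lapply(seq_along(inversions), function(i) {
    iv <- inversions[[i]]
    if (is.null(iv$n_sites) || iv$n_sites < 1)
      stop("inversion ", i, ": n_sites must be positive")
    iv$s_freq <- rep_len(iv$s_freq, n_populations)
    if (any(iv$s_freq < 0 | iv$s_freq > 1))
      stop("inversion ", i, ": s_freq must lie in [0,1]")
    if (!is.null(iv$recombinant)) {
      rc <- iv$recombinant
      if (rc$start < 1 || rc$end > iv$n_sites || rc$start > rc$end)
        stop("inversion ", i, ": recombinant segment outside site range")
      if (any(rc$freq < 0 | rc$freq > 1))
        stop("inversion ", i, ": recombinant freq must lie in [0,1]")
    }
    if (is.null(iv$chrom)) iv$chrom <- paste0("chr_inv", i)
    if (is.null(iv$start_bp)) iv$start_bp <- 1e6
    if (is.null(iv$spacing)) iv$spacing <- 100L
    if (is.null(iv$id)) iv$id <- paste0("inv", i)
    iv
  })
  structure(list(n_populations = n_populations,
                 samples_per_pop = samples_per_pop,
                 n_neutral_sites = n_neutral_sites,
                 n_adaptive_sites = n_adaptive_sites,
                 drift_F = drift_F, adaptive_delta = adaptive_delta,
                 adaptive_pops = as.integer(adaptive_pops),
                 inversions = inversions, missing_rate = missing_rate,
                 ancestral_range = ancestral_range, chrom = chrom,
                 spacing = as.integer(spacing), seed = as.integer(seed)),
            class = "sim_config")
}

#' Balding-Nichols drifted population frequencies
#'
#' Each population's frequency at each site is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` (the ancestral
#' frequency) and variance `F p (1-p)`, so the expected FST among populations
#' equals `drift_F`. `drift_F = 0` returns the ancestral frequencies exactly
#' (the zero-variance limit).
#'
#' @param ancestral ancestral frequencies in (0, 1).
#' @param drift_F differentiation parameter in `[0, 1)`.
#' @param n_pops number of populations.
#' @param seed optional integer seed.
#' @return `n_pops` x `length(ancestral)` frequency matrix.
#' @export
simulate_neutral_freqs <- function(ancestral, drift_F, n_pops, seed = NULL) {
  if (any(!is.finite(ancestral)) || any(ancestral <= 0 | ancestral >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  if (!is.finite(drift_F) || drift_F < 0 || drift_F >= 1)
    stop("drift_F must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  L <- length(ancestral)
  if (drift_F == 0)
    return(matrix(ancestral, nrow = n_pops, ncol = L, byrow = TRUE))
  k <- (1 - drift_F) / drift_F
  m <- matrix(stats::rbeta(n_pops * L,
                           shape1 = rep(ancestral * k, each = n_pops),
                           shape2 = rep((1 - ancestral) * k, each = n_pops)),
              nrow = n_pops, ncol = L)
  m
}

#' Simulate an inversion block's reference haplotypes
#'
#' Builds the Northern (N) and Southern (S) consensus haplotypes of a
#' non-recombining block: they differ at every site (all sites diagnostic by
#' construction; which consensus carries the alternate allele is randomised
#' per site). If a recombinant is specified, a third haplotype equals S
#' everywhere except the `[start, end]` run of sites copied from N.
#'
#' @param iv one inversion spec from [sim_config()].
#' @param n_pops number of populations.
#' @param seed optional integer seed.
#' @return list with `ref` (site table: `chrom`, `pos`, `n_allele`,
#'   `s_allele`, `diagnostic`), `haplotypes` (named list of alt-dosage vectors
#'   `N`, `S` and optionally `R`), and `class_probs` (per-population
#'   probabilities of drawing each haplotype class).
#' @export
simulate_inversion_block <- function(iv, n_pops, seed = NULL) {
  if (is.null(iv$n_sites) || iv$n_sites < 1) stop("empty inversion")
  if (!is.null(seed)) set.seed(seed)
  L <- iv$n_sites
  s_is_alt <- stats::runif(L) < 0.5
  hap_S <- as.integer(s_is_alt)      # alt-allele dosage carried by one S haplotype
  hap_N <- 1L - hap_S
  haplotypes <- list(N = hap_N, S = hap_S)
  if (!is.null(iv$recombinant)) {
    rc <- iv$recombinant
    hap_R <- hap_S
    hap_R[rc$start:rc$end] <- hap_N[rc$start:rc$end]
    haplotypes$R <- hap_R
  }
  s_freq <- rep_len(iv$s_freq, n_pops)
  if (is.null(iv$recombinant)) {
    class_probs <- cbind(N = 1 - s_freq, S = s_freq)
  } else {
    rec_f <- rep_len(iv$recombinant$freq, n_pops)
    class_probs <- cbind(N = 1 - s_freq,
                         S = s_freq * (1 - rec_f),
                         R = s_freq * rec_f)
  }
  pos <- iv$start_bp + iv$spacing * (seq_len(L) - 1L)
  ref <- data.frame(chrom = iv$chrom, pos = pos,
                    n_allele = ifelse(s_is_alt, "ref", "alt"),
                    s_allele = ifelse(s_is_alt, "alt", "ref"),
                    diagnostic = TRUE, stringsAsFactors = FALSE)
  list(ref = ref, haplotypes = haplotypes, class_probs = class_probs)
}

#' Simulate a full genotype dataset with ground truth
#'
#' Assembles neutral, adaptive and inversion sites, samples diploid genotypes
#' (Hardy-Weinberg binomial sampling at frequency-based sites; joint haplotype
#' draws inside inversion blocks, which never recombine during sampling),
#' applies independent missingness, and returns the genotype matrix together
#' with a truth object for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list with `geno` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`): `sites` (with `site_class`, `ancestral_freq`), `pop_freqs`
#'   (population x site expected alt frequency), `inversion_genotypes`
#'   (per individual per inversion: haplotype classes and the N/S genotype),
#'   `breakpoints` (recombinant segment bounds, bp), and `refs` (generating
#'   haplotype references per inversion).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_populations
  n_ind <- sum(config$samples_per_pop)
  pop_of <- rep(paste0("pop", seq_len(K)), config$samples_per_pop)
  sample_id <- unlist(lapply(seq_len(K), function(k)
    sprintf("pop%d_%02d", k, seq_len(config$samples_per_pop[k]))))

  # -- frequency-based (neutral + adaptive) sites on config$chrom
  n_neu <- config$n_neutral_sites
  n_ada <- config$n_adaptive_sites
  L_f <- n_neu + n_ada
  anc <- stats::runif(L_f, config$ancestral_range[1], config$ancestral_range[2])
  site_class <- c(rep("neutral", n_neu), rep("adaptive", n_ada))
  pf <- simulate_neutral_freqs(anc, config$drift_F, K)
  if (n_ada > 0) {
    ada <- which(site_class == "adaptive")
    # shift is applied to a mid-range base frequency so the full delta fits
    base <- stats::runif(n_ada, 0.05, max(0.05, 0.95 - config$adaptive_delta))
    for (k in seq_len(K)) pf[k, ada] <- base
    for (k in config$adaptive_pops) pf[k, ada] <- base + config$adaptive_delta
  }
  sites <- if (L_f > 0)
    data.frame(chrom = config$chrom, pos = config$spacing * seq_len(L_f),
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)

  geno <- matrix(NA_integer_, n_ind, L_f)
  if (L_f > 0) {
    for (k in seq_len(K)) {
      rows <- which(pop_of == paste0("pop", k))
      geno[rows, ] <- matrix(stats::rbinom(length(rows) * L_f, 2,
                                           rep(pf[k, ], each = length(rows))),
                             nrow = length(rows))
    }
  }
  anc_all <- anc
  class_all <- site_class
  pf_all <- pf

  # -- inversion blocks, each fully linked
  inv_genos <- list()
  breakpoints <- list()
  refs <- list()
  for (i in seq_along(config$inversions)) {
    iv <- config$inversions[[i]]
    blk <- simulate_inversion_block(iv, K)
    refs[[iv$id]] <- blk
    Lb <- iv$n_sites
    haps <- blk$haplotypes
    cls <- colnames(blk$class_probs)
    g_blk <- matrix(NA_integer_, n_ind, Lb)
    h1 <- h2 <- character(n_ind)
    for (k in seq_len(K)) {
      rows <- which(pop_of == paste0("pop", k))
      pr <- blk$class_probs[k, ]
      h1[rows] <- sample(cls, length(rows), replace = TRUE, prob = pr)
      h2[rows] <- sample(cls, length(rows), replace = TRUE, prob = pr)
    }
    for (r in seq_len(n_ind))
      g_blk[r, ] <- haps[[h1[r]]] + haps[[h2[r]]]
    # expected alt frequency per pop: mixture over haplotype classes
    hap_mat <- do.call(rbind, haps[cls])
    pf_blk <- blk$class_probs %*% hap_mat
    geno <- cbind(geno, g_blk)
    sites <- rbind(sites, data.frame(chrom = blk$ref$chrom, pos = blk$ref$pos,
                                     ref = "A", alt = "G",
                                     stringsAsFactors = FALSE))
    anc_all <- c(anc_all, colMeans(pf_blk))
    class_all <- c(class_all, rep("inversion", Lb))
    pf_all <- cbind(pf_all, pf_blk)
    ns1 <- ifelse(h1 == "N", "N", "S")
    ns2 <- ifelse(h2 == "N", "N", "S")
    ns <- paste0(pmin(ns1, ns2), pmax(ns1, ns2))   # NN, NS, SS
    inv_genos[[i]] <- data.frame(sample_id = sample_id, inversion = iv$id,
                                 hap1 = h1, hap2 = h2,
                                 ns_genotype = c(NN = "NN", NS = "NS",
                                                 SS = "SS")[ns],
                                 stringsAsFactors = FALSE)
    if (!is.null(iv$recombinant)) {
      rc <- iv$recombinant
      breakpoints[[i]] <- data.frame(inversion = iv$id,
                                     start_index = rc$start, end_index = rc$end,
                                     start_bp = blk$ref$pos[rc$start],
                                     end_bp = blk$ref$pos[rc$end])
    }
  }

  # -- uniform independent missingness
  if (config$missing_rate > 0 && length(geno) > 0)
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_

  samples <- data.frame(sample_id = sample_id, population = pop_of,
                        ecotype = pop_of, stringsAsFactors = FALSE)
  gm <- genotype_matrix(geno, sites, samples)
  truth_sites <- cbind(sites,
                       data.frame(site_class = class_all,
                                  ancestral_freq = anc_all))
  rownames(pf_all) <- paste0("pop", seq_len(K))
  truth <- structure(list(sites = truth_sites, pop_freqs = pf_all,
                          inversion_genotypes = if (length(inv_genos))
                            do.call(rbind, inv_genos) else NULL,
                          breakpoints = if (length(breakpoints))
                            do.call(rbind, breakpoints) else NULL,
                          refs = refs),
                     class = "sim_truth")
  list(geno = gm, truth = truth)
}

#' Sample diploid genotypes from population frequencies
#'
#' Hardy-Weinberg sampling: genotype ~ Binomial(2, p) independently per site
#' and individual, with independent missingness.
#'
#' @param freqs population x site frequency matrix (rows named, or names
#'   `pop1..popK` are assigned).
#' @param samples_per_pop diploids per population (scalar or vector).
#' @param missing_rate per-call missingness probability.
#' @param seed optional integer seed.
#' @param sites optional site table; default synthetic positions 100 bp apart.
#' @return A [genotype_matrix()].
#' @export
sample_genotypes <- function(freqs, samples_per_pop, missing_rate = 0,
                             seed = NULL, sites = NULL) {
  freqs <- as.matrix(freqs)
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE))
    stop("frequencies must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(freqs); L <- ncol(freqs)
  if (is.null(rownames(freqs))) rownames(freqs) <- paste0("pop", seq_len(K))
  samples_per_pop <- rep_len(as.integer(samples_per_pop), K)
  pops <- rep(rownames(freqs), samples_per_pop)
  n_ind <- sum(samples_per_pop)
  geno <- matrix(NA_integer_, n_ind, L)
  r0 <- 0
  for (k in seq_len(K)) {
    nk <- samples_per_pop[k]
    geno[r0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * L, 2, rep(freqs[k, ], each = nk)), nrow = nk)
    r0 <- r0 + nk
  }
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  if (is.null(sites))
    sites <- data.frame(chrom = "chr1", pos = 100L * seq_len(L),
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  ids <- sprintf("%s_%02d", pops, unlist(lapply(samples_per_pop, seq_len)))
  genotype_matrix(geno, sites,
                  data.frame(sample_id = ids, population = pops,
                             ecotype = pops, stringsAsFactors = FALSE))
}

#' Neutral site-frequency-spectrum draw
#'
#' Draws derived-allele counts for `S` independent segregating sites in a
#' sample of `n` chromosomes from the standard neutral spectrum
#' `P(count = i) proportional to 1/i`, `i = 1..n-1`. Under this spectrum the
#' expected total pairwise diversity equals `S / a1` (`a1` the harmonic
#' number), so Tajima's D is centred on zero - the calibration regime for
#' neutrality tests on unlinked sites.
#'
#' @param S number of segregating sites.
#' @param n chromosomes sampled (`n >= 2`).
#' @param seed optional integer seed.
#' @return integer vector of derived-allele counts in `1..n-1`.
#' @export
sim_neutral_sfs <- function(S, n, seed = NULL) {
  stopifnot(S >= 1, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(n - 1)
  sample(i, S, replace = TRUE, prob = 1 / i)
}

#' Write simulation truth tables
#'
#' Writes plain TSVs: `<prefix>_sites.tsv`, `<prefix>_pop_freqs.tsv`,
#' `<prefix>_inversion_genotypes.tsv`, `<prefix>_breakpoints.tsv` (the last
#' two only when inversions were simulated).
#'
#' @param truth a `sim_truth` object from [simulate_dataset()].
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- character(0)
  wt <- function(df, suffix) {
    p <- paste0(prefix, "_", suffix, ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  out <- c(out, wt(truth$sites, "sites"))
  pf <- data.frame(population = rownames(truth$pop_freqs),
                   truth$pop_freqs, check.names = FALSE)
  out <- c(out, wt(pf, "pop_freqs"))
  if (!is.null(truth$inversion_genotypes))
    out <- c(out, wt(truth$inversion_genotypes, "inversion_genotypes"))
  if (!is.null(truth$breakpoints))
    out <- c(out, wt(truth$breakpoints, "breakpoints"))
  invisible(out)
}
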