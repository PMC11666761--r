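# shared fixture builders; everything generated in code, nothing on disk

# tiny hand-checkable genotype matrix: 2 populations x 2 individuals, 3 sites
tiny_gm <- function() {
  geno <- rbind(c(0L, 2L, 1L),
                c(1L, NA, 1L),
                c(2L, 2L, 0L),
                c(2L, NA, 0L))
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                        population = c("A", "A", "B", "B"),
                        ecotype = c("A", "A", "B", "B"),
                        stringsAsFactors = FALSE)
  genotype_matrix(geno, sites, samples)
}

# standard 3-population simulation with one inversion carrying a recombinant
# haplotype fixed in pop1: pop2 is a pure-N pool, pop3 a pure-S pool
sim_with_recombinant <- function(seed = 42, samples_per_pop = 20,
                                 rec_freq = c(1, 0, 0), missing_rate = 0) {
  cfg <- sim_config(
    n_populations = 3, samples_per_pop = samples_per_pop,
    n_neutral_sites = 200, n_adaptive_sites = 0,
    inversions = list(list(n_sites = 100, s_freq = c(1, 0, 1),
                           recombinant = list(start = 40, end = 51,
                                              freq = rec_freq),
                           chrom = "chr12", start_bp = 1000L)),
    missing_rate = missing_rate, seed = seed)
  simulate_dataset(cfg)
}

inv_region <- function() region("chr12", 1000, 1000 + 99 * 100)

# brute-force Pearson chi-square on one 2x2 table: explicit sum over cells
chi2_brute <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  exp <- outer(rs, cs) / n
  sum((tab - exp)^2 / exp)
}

# independently coded scalar coancestry components for one locus
reynolds_brute <- function(p1, p2, c1, c2) {
  h1 <- c1 / (c1 - 1) * 2 * p1 * (1 - p1)
  h2 <- c2 / (c2 - 1) * 2 * p2 * (1 - p2)
  al <- (p1 - p2)^2 - h1 / (2 * c1) - h2 / (2 * c2)
  c(num = al, den = al + (h1 + h2) / 2)
}
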