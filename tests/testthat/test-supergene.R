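test_that("consensus alleles follow the all-pools supermajority rule", {
  sites <- data.frame(chrom = "chr12", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "G")
  # site 1: N pools 0.9/0.95/1.0 alt -> N consensus alt; S pools fixed ref
  # site 2: one N pool at 0.6 -> no qualifying allele, site dropped
  # site 3: both sides consensus ref -> kept but non-diagnostic
  freq <- rbind(N1 = c(0.90, 0.60, 0.05), N2 = c(0.95, 0.95, 0.10),
                N3 = c(1.00, 0.90, 0.00),
                S1 = c(0.05, 0.05, 0.05), S2 = c(0.00, 0.10, 0.15))
  pf <- pop_freqs(freq, matrix(40L, 5, 3), sites)
  ref <- build_consensus(pf, c("N1", "N2", "N3"), c("S1", "S2"),
                         region("chr12", 1, 100), purity = 0.8)
  expect_equal(ref$pos, c(10L, 30L))
  expect_equal(ref$n_allele, c("alt", "ref"))
  expect_equal(ref$s_allele, c("ref", "ref"))
  expect_equal(ref$diagnostic, c(TRUE, FALSE))
  # zero diagnostic sites is an error naming the region
  pf_bad <- pop_freqs(freq[, 3, drop = FALSE], matrix(40L, 5, 1),
                      sites[3, , drop = FALSE])
  expect_error(build_consensus(pf_bad, "N1", "S1", region("chr12", 1, 100)),
               "no diagnostic sites")
})

test_that("consensus recovered from simulation equals generating haplotypes", {
  sim <- sim_with_recombinant(seed = 61)
  pf <- pop_allele_freqs(sim$geno)
  ref <- build_consensus(pf, "pop2", "pop3", inv_region(), purity = 0.8)
  blk <- sim$truth$refs$inv1
  expect_equal(nrow(ref), 100)
  expect_equal(ref$n_allele, blk$ref$n_allele)
  expect_equal(ref$s_allele, blk$ref$s_allele)
  expect_true(all(ref$diagnostic))
})

test_that("per-SNP scoring maps dosage to NN/NS/SS in consensus space", {
  # heterozygote is NS whichever allele is Northern
  expect_equal(score_snp(1, n_is_alt = TRUE), "NS")
  expect_equal(score_snp(1, n_is_alt = FALSE), "NS")
  # homozygote for the S allele (alt) is SS
  expect_equal(score_snp(2, n_is_alt = FALSE), "SS")
  expect_equal(score_snp(2, n_is_alt = TRUE), "NN")
  expect_equal(score_snp(0, n_is_alt = TRUE), "SS")
  expect_true(is.na(score_snp(NA, n_is_alt = TRUE)))
})

test_that("inversion calls use majority vote with tie and evidence rules", {
  sc <- matrix(c(rep("NN", 30), rep("NS", 5), rep("SS", 2)), nrow = 1)
  expect_equal(call_inversion(sc)$genotype, "NN")
  tie <- matrix(c(rep("NN", 10), rep("SS", 10)), nrow = 1)
  expect_equal(call_inversion(tie)$genotype, "unassigned")
  few <- matrix(c("NN", "NN", NA, NA), nrow = 1)
  expect_equal(call_inversion(few, min_sites = 5)$genotype, "unassigned")
  expect_equal(call_inversion(few, min_sites = 2)$genotype, "NN")
})

test_that("error-free inversion genotypes are recovered perfectly and degrade
           monotonically with missingness", {
  acc <- vapply(c(0, 0.3, 0.9), function(mr) {
    sim <- sim_with_recombinant(seed = 63, rec_freq = 0,
                                missing_rate = mr,
                                samples_per_pop = 30)
    pf0 <- pop_allele_freqs(sim_with_recombinant(seed = 63, rec_freq = 0,
                                                 missing_rate = 0,
                                                 samples_per_pop = 30)$geno)
    ref <- build_consensus(pf0, "pop2", "pop3", inv_region())
    calls <- call_inversion(score_genotypes(sim$geno, ref), min_sites = 5)
    mean(calls$genotype == sim$truth$inversion_genotypes$ns_genotype)
  }, numeric(1))
  expect_equal(acc[1], 1.0)
  expect_true(all(diff(acc) <= 0))
})

test_that("population site classification estimates S-haplotype frequency", {
  sim <- sim_with_recombinant(seed = 65, rec_freq = 0)
  pf <- pop_allele_freqs(sim$geno)
  ref <- build_consensus(pf, "pop2", "pop3", inv_region())
  # pop3 is fixed for S: all S-like, frequency 1
  cl3 <- classify_population_sites(pf$freq["pop3", ], ref, tau = 0.2)
  expect_true(all(cl3$sites$class == "S-like"))
  expect_equal(cl3$s_frequency, 1.0)
  # a site at frequency 0.5 is intermediate at tau = 0.2
  halfway <- classify_population_sites(
    stats::setNames(rep(0.5, nrow(ref)), paste0(ref$chrom, ":", ref$pos)),
    ref, tau = 0.2)
  expect_true(all(halfway$sites$class == "intermediate"))
})

test_that("S-haplotype frequency estimator is unbiased over replicates", {
  # 20 replicate cohorts at true S frequency 0.8 in pop1
  est <- vapply(1:20, function(s) {
    cfg <- sim_config(n_populations = 3, samples_per_pop = 20,
                      n_neutral_sites = 0, n_adaptive_sites = 0,
                      inversions = list(list(n_sites = 40,
                                             s_freq = c(0.8, 0, 1),
                                             chrom = "chr12",
                                             start_bp = 1000L)),
                      missing_rate = 0, seed = 7000 + s)
    sim <- simulate_dataset(cfg)
    pf <- pop_allele_freqs(sim$geno)
    ref <- build_consensus(pf, "pop2", "pop3",
                           region("chr12", 1000, 1000 + 39 * 100))
    classify_population_sites(pf$freq["pop1", ], ref)$s_frequency
  }, numeric(1))
  se <- sqrt(0.8 * 0.2 / 40) / sqrt(20)   # binomial SE of the replicate mean
  expect_lt(abs(mean(est) - 0.8), 2 * se)
})

test_that("recombinant segment detection honours runs and thresholds", {
  pos <- seq(100L, by = 100L, length.out = 40)
  cls <- rep("S-like", 40)
  cls[10:21] <- "N-like"   # one 12-site foreign run
  df <- data.frame(chrom = "chr12", pos = pos, f_S = 1, class = cls)
  seg <- detect_recombinant_segments(df, background = "S", min_run = 5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_diagnostic_sites, 12)
  expect_equal(seg$start_bp, pos[10])
  expect_equal(seg$end_bp, pos[21])
  # threshold boundary: min_run above the run length finds nothing
  expect_equal(nrow(detect_recombinant_segments(df, "S", min_run = 13)), 0)
  # an intermediate site breaks the run
  cls2 <- cls; cls2[15] <- "intermediate"
  df2 <- df; df2$class <- cls2
  seg2 <- detect_recombinant_segments(df2, "S", min_run = 5)
  expect_equal(seg2$n_diagnostic_sites, c(5, 6))
  # nothing on a non-recombinant simulation
  sim <- sim_with_recombinant(seed = 67, rec_freq = 0)
  pf <- pop_allele_freqs(sim$geno)
  ref <- build_consensus(pf, "pop2", "pop3", inv_region())
  c1 <- classify_population_sites(pf$freq["pop1", ], ref, tau = 0.2)
  expect_equal(nrow(detect_recombinant_segments(c1$sites, "S", 5)), 0)
})

test_that("simulated recombinant breakpoints are recovered exactly", {
  sim <- sim_with_recombinant(seed = 69, rec_freq = c(1, 0, 0))
  pf <- pop_allele_freqs(sim$geno)
  ref <- build_consensus(pf, "pop2", "pop3", inv_region())
  cls <- classify_population_sites(pf$freq["pop1", ], ref)
  seg <- detect_recombinant_segments(cls$sites, "S", min_run = 5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, sim$truth$breakpoints$start_bp)
  expect_equal(seg$end_bp, sim$truth$breakpoints$end_bp)
  expect_equal(seg$n_diagnostic_sites, 12)
})

test_that("sweep scan flags only sites differentiated from both references", {
  sites <- data.frame(chrom = "c", pos = c(10L, 20L, 30L))
  # site 1: private to focal (0.9 vs 0.05/0.05) -> flagged
  # site 2: matches N (differs from S only) -> not flagged
  # site 3: matches both -> not flagged
  sw <- sweep_scan(focal_freq = c(0.9, 0.95, 0.5),
                   freq_n = c(0.05, 0.95, 0.5),
                   freq_s = c(0.05, 0.05, 0.5),
                   sites = sites, cutoff = 0.35)
  expect_identical(sw$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(sw$subregions$start_bp, 10L)
  # null: focal equals the S reference cohort -> no flagged subregions
  sim <- sim_with_recombinant(seed = 71, rec_freq = 0)
  pf <- pop_allele_freqs(sim$geno)
  idx <- sites_in_region_test <- pf$sites$chrom == "chr12"
  sw0 <- sweep_scan(pf$freq["pop3", idx], pf$freq["pop2", idx],
                    pf$freq["pop1", idx], pf$sites[idx, ], cutoff = 0.35)
  expect_equal(nrow(sw0$subregions), 0)
})

test_that("NJ trees recover additive topologies and are order invariant", {
  # 4 populations with frequencies built so pairwise distances are additive:
  # ((A,B),(C,D)) with internal edge
  base <- rep(0.5, 400)
  mkpop <- function(shift_sites, delta) {
    f <- base; f[shift_sites] <- f[shift_sites] + delta; f
  }
  freq <- rbind(A = mkpop(1:40, 0.4), B = mkpop(41:80, 0.4),
                C = mkpop(301:400, -0.4), D = mkpop(201:300, 0.4))
  pf <- pop_freqs(freq, matrix(40L, 4, 400),
                  data.frame(chrom = "c", pos = 1:400, ref = "A", alt = "G"))
  tr <- nj_tree_region(pf, region("c", 1, 400))
  expect_s3_class(tr, "phylo")
  # A and B form a cherry
  pair <- ape::prop.part(ape::unroot(tr))
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  # permuting the population order preserves the topology
  tr2 <- nj_tree_region(pf, region("c", 1, 400),
                        populations = c("D", "B", "C", "A"))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  # two identical populations form a zero-length cherry
  freq2 <- rbind(freq, A2 = freq["A", ])
  pf2 <- pop_freqs(freq2, matrix(40L, 5, 400), pf$sites)
  tr3 <- nj_tree_region(pf2, region("c", 1, 400))
  m <- ape::cophenetic.phylo(tr3)
  expect_equal(m["A", "A2"], 0, tolerance = 1e-12)
  expect_error(nj_tree_region(pf, region("c", 1, 400), populations = c("A", "B")),
               "at least 3")
})

test_that("the RMS delta-AF distance is a metric on random tables", {
  set.seed(73)
  for (rep in 1:20) {
    f <- matrix(runif(3 * 50), 3, 50)
    d <- as.matrix(stats::dist(f)) / sqrt(50)
    expect_true(all(d >= 0))
    expect_equal(d, t(d))
    expect_lte(d[1, 2], d[1, 3] + d[3, 2] + 1e-12)
  }
})
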