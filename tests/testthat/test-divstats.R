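test_that("Watterson's theta follows the harmonic-sum formula", {
  expect_equal(watterson_theta(0, 10, 1000), 0)
  expect_equal(watterson_theta(5, 10, 1000), 5 / (sum(1 / 1:9) * 1000))
  expect_equal(watterson_theta(5, 10, 1000), 1.7674e-3, tolerance = 1e-4)
  expect_equal(watterson_theta(7, 2, 100), 7 / 100)  # a1 = 1 at n = 2
  expect_error(watterson_theta(1, 1, 100), "n >= 2")
})

test_that("pi uses the unbiased per-site heterozygosity", {
  expect_equal(nucleotide_diversity(0.5, 10, 1), 2 * 0.25 * 10 / 9)
  expect_equal(round(nucleotide_diversity(0.5, 10, 1), 4), 0.5556)
  expect_equal(nucleotide_diversity(c(0, 1, 0), 10, 100), 0)
  expect_equal(nucleotide_diversity(0.3, 12, 1), nucleotide_diversity(0.7, 12, 1))
})

test_that("Tajima's D has the textbook zero point and sign behaviour", {
  n <- 10; a1 <- sum(1 / 1:9)
  expect_equal(tajimas_d(5, 5 / a1, n), 0)
  # all-singleton configuration: pi_total below S/a1 -> negative D
  pi_singletons <- 5 * 2 * 1 * (n - 1) / (n * (n - 1))
  expect_lt(tajimas_d(5, pi_singletons, n), 0)
  expect_true(is.na(tajimas_d(0, 0, n)))
  expect_error(tajimas_d(3, 1, 3), "n >= 4")
})

test_that("mean Tajima's D is near zero under the neutral spectrum", {
  n <- 20
  d <- vapply(1:50, function(s) {
    cnt <- sim_neutral_sfs(200, n, seed = 5000 + s)
    pi_total <- sum(2 * cnt * (n - cnt) / (n * (n - 1)))
    tajimas_d(200, pi_total, n)
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.2)
})

test_that("effective population size is theta over 4 mu", {
  expect_equal(effective_population_size(0.0045, 2.0e-9), 562500)
  expect_equal(effective_population_size(0), 0)
  expect_equal(effective_population_size(0.004, 4e-9),
               effective_population_size(0.004, 2e-9) / 2)
  expect_error(effective_population_size(0.004, 0), "positive")
})

test_that("coancestry FST has the no-divergence and fixed-difference limits", {
  # equal frequencies: expectation 0, slight negatives permitted
  set.seed(81)
  p <- runif(2000, 0.05, 0.95)
  fst0 <- reynolds_fst(p, p, 100, 100)$fst
  expect_lt(abs(fst0), 0.02)
  # fixed difference: exactly 1
  expect_equal(reynolds_fst(1, 0, 200, 200)$fst, 1)
  expect_error(reynolds_fst_components(0.5, 0.5, 1, 10), "chromosomes")
})

test_that("vectorised FST equals the scalar brute-force oracle", {
  set.seed(83)
  for (i in 1:50) {
    p1 <- runif(1); p2 <- runif(1)
    c1 <- sample(4:200, 1); c2 <- sample(4:200, 1)
    got <- reynolds_fst_components(p1, p2, c1, c2)
    ora <- reynolds_brute(p1, p2, c1, c2)
    expect_equal(got$num, unname(ora["num"]), tolerance = 1e-12)
    expect_equal(got$den, unname(ora["den"]), tolerance = 1e-12)
  }
})

test_that("windows are half-open, chromosome-bounded, and keep empty rows", {
  sites <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                      pos = c(500L, 9999L, 10000L, 100L),
                      ref = "A", alt = "G")
  pf <- pop_freqs(matrix(c(0.5, 0.5, 0.5, 0.5), 1,
                         dimnames = list("P", NULL)),
                  matrix(20L, 1, 4), sites)
  wd <- windowed_diversity(pf, "P", window = 10000)
  c1 <- wd[wd$chrom == "c1", ]
  # pos 10,000 with w = 10,000 belongs to the second window
  expect_equal(c1$S, c(2, 1))
  # chromosomes do not share windows
  expect_equal(wd$S[wd$chrom == "c2"], 1)
  # an empty window between occupied ones is retained with S = 0
  sites2 <- data.frame(chrom = "c1", pos = c(500L, 25000L), ref = "A", alt = "G")
  pf2 <- pop_freqs(matrix(0.5, 1, 2, dimnames = list("P", NULL)),
                   matrix(20L, 1, 2), sites2)
  wd2 <- windowed_diversity(pf2, "P", window = 10000)
  expect_equal(wd2$S, c(1, 0, 1))
  expect_true(is.na(wd2$tajimas_d[2]))
})

test_that("genome FST is a ratio of sums, not a mean of window ratios", {
  set.seed(85)
  sites <- data.frame(chrom = "c1", pos = c(1:50 * 100L, 20000L + 1:5 * 100L),
                      ref = "A", alt = "G")
  f1 <- runif(55, 0.2, 0.8)
  f2 <- pmin(1, pmax(0, f1 + c(rep(0.02, 50), rep(0.6, 5))))
  pf <- pop_freqs(rbind(A = f1, B = f2), matrix(60L, 2, 55), sites)
  wf <- windowed_fst(pf, "A", "B", window = 10000)
  mean_of_ratios <- mean(wf$windows$fst, na.rm = TRUE)
  expect_equal(wf$genome$fst,
               sum(wf$windows$num) / sum(wf$windows$den))
  expect_false(isTRUE(all.equal(wf$genome$fst, mean_of_ratios)))
})

test_that("genome FST recovers the generating drift parameter", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 30,
                    n_neutral_sites = 5000, n_adaptive_sites = 0,
                    drift_F = 0.05, missing_rate = 0.02, seed = 87)
  sim <- simulate_dataset(cfg)
  pf <- pop_allele_freqs(sim$geno)
  wf <- windowed_fst(pf, "pop1", "pop2")
  expect_lt(abs(wf$genome$fst - 0.05), 0.015)
})

test_that("UPGMA recovers ultrametric trees with average-linkage heights", {
  # constructed ultrametric matrix: ((A:1,B:1):2,C:3)
  d <- matrix(c(0, 2, 6,
                2, 0, 6,
                6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  m <- ape::cophenetic.phylo(tr)
  expect_equal(m[rownames(d), colnames(d)], d)
  expect_true(ape::is.ultrametric(tr))
  # two populations: a single cherry at height d/2
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  tr2 <- upgma_tree(d2)
  expect_equal(sort(tr2$edge.length), c(2, 2))
  # adding a constant preserves topology
  tr3 <- upgma_tree(d + 10 - diag(10, 3))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr3)), 0,
               ignore_attr = TRUE)
  expect_error(upgma_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("tree outputs are valid newick and round-trip through a parser", {
  sim <- sim_with_recombinant(seed = 89)
  pf <- pop_allele_freqs(sim$geno)
  tr <- nj_tree_region(pf, inv_region())
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  tr2 <- ape::read.tree(f)
  expect_setequal(tr2$tip.label, rownames(pf$freq))
  d <- matrix(0.02, 3, 3, dimnames = list(rownames(pf$freq),
                                          rownames(pf$freq)))
  diag(d) <- 0
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(upgma_tree(d), f2)
  expect_s3_class(ape::read.tree(f2), "phylo")
})

test_that("nearest-ecotype fractions count winning windows per candidate", {
  win <- expand.grid(chrom = paste0("chr", 1:3), win_start = c(0, 10000),
                     candidate = c("X", "Y"), stringsAsFactors = FALSE)
  win$fst <- ifelse(win$candidate == "X", 0.01, 0.02)
  res <- nearest_ecotype_fraction(win)
  expect_equal(res$fractions$fraction[res$fractions$candidate == "X"], 1.0)
  expect_true(all(res$chromosomes$winner == "X"))
  # symmetric duplicate candidates: all ties, zero fractions, ties reported
  win2 <- win; win2$fst <- 0.01
  res2 <- nearest_ecotype_fraction(win2)
  expect_equal(res2$fractions$fraction, c(0, 0))
  expect_equal(res2$n_tied, res2$n_eligible)
  # weighting by window length changes fractions accordingly
  win$bp <- ifelse(win$chrom == "chr1", 10000, 0)
  win$fst[win$candidate == "Y" & win$chrom != "chr1"] <- 0.001
  res3 <- nearest_ecotype_fraction(win, weight = "bp")
  expect_equal(res3$fractions$fraction[res3$fractions$candidate == "X"], 1.0)
})

test_that("a candidate sharing drift history wins more of the genome", {
  # candidates A and B drift by the same total amount from the ancestor, but
  # focal and A share the first fraction w of their drift (a common
  # intermediate ancestor); A's share of won windows must grow with w
  frac_for <- function(w, seed) {
    set.seed(seed)
    F_tot <- 0.05
    anc <- runif(3000, 0.1, 0.9)
    inter <- simulate_neutral_freqs(anc, w * F_tot, 1)
    inter <- pmin(pmax(as.vector(inter), 1e-6), 1 - 1e-6)
    focal <- simulate_neutral_freqs(inter, (1 - w) * F_tot, 1)
    a <- simulate_neutral_freqs(inter, (1 - w) * F_tot, 1)
    b <- simulate_neutral_freqs(anc, F_tot, 1)
    sites <- data.frame(chrom = "c", pos = 1:3000 * 100L, ref = "A", alt = "G")
    fr <- rbind(as.vector(focal), as.vector(a), as.vector(b))
    rownames(fr) <- c("focal", "A", "B")
    pf <- pop_freqs(fr, matrix(50L, 3, 3000), sites)
    wa <- windowed_fst(pf, "focal", "A")$windows
    wb <- windowed_fst(pf, "focal", "B")$windows
    res <- nearest_ecotype_fraction(rbind(cbind(candidate = "A", wa),
                                          cbind(candidate = "B", wb)))
    res$fractions$fraction[res$fractions$candidate == "A"]
  }
  f_shared <- frac_for(0.8, 91)   # most drift shared with focal
  f_none <- frac_for(0.0, 91)     # A as unrelated to focal as B
  expect_gt(f_shared, 0.5)
  expect_gt(f_shared, f_none)
})
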