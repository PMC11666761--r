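#' Per-SNP chi-square allele test
#'
#' Pearson chi-square (1 d.f., no continuity correction) on the 2x2 table of
#' observed chromosomes carrying the reference/alternate allele in two groups,
#' the classic allelic association test of genome scans. Vectorised over
#' sites. Tables with a zero margin (monomorphic sites, or a group with no
#' observations) return `chi2 = 0`, `p = 1` and are flagged.
#'
#' @param ref_a,alt_a,ref_b,alt_b nonnegative counts (vectors) of ref/alt
#'   chromosomes in groups A and B.
#' @return data.frame with `chi2`, `p`, `monomorphic`.
#' @export
chi2_allele_test <- function(ref_a, alt_a, ref_b, alt_b) {
  cnt <- cbind(ref_a, alt_a, ref_b, alt_b)
  if (any(cnt < 0)) stop("allele counts must be nonnegative")
  n_a <- ref_a + alt_a
  n_b <- ref_b + alt_b
  n_ref <- ref_a + ref_b
  n_alt <- alt_a + alt_b
  N <- n_a + n_b
  if (any(n_a == 0 & n_b == 0)) stop("both groups empty at some site")
  denom <- n_a * n_b * n_ref * n_alt
  chi2 <- ifelse(denom > 0, N * (ref_a * alt_b - alt_a * ref_b)^2 / denom, 0)
  mono <- denom == 0
  p <- ifelse(mono, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(chi2 = chi2, p = p, monomorphic = mono)
}

#' Bonferroni adjustment with an explicit test count
#'
#' `adjusted = min(1, p * m)` with `m` the full number of tests performed
#' (which may exceed the p values supplied, e.g. when only a region is
#' reported from a genome-wide scan of m SNPs).
#'
#' @param p raw p values in (0, 1].
#' @param m total number of tests, `m >= length(p)`.
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p values must lie in (0, 1]")
  if (m < length(p)) stop("m must be at least the number of p values")
  pmin(1, p * m)
}

#' Genome-wide allelic association scan
#'
#' Builds per-site 2x2 allele-count tables for two groups from a genotype
#' matrix (observed chromosomes only), applies [chi2_allele_test()] and
#' Bonferroni correction, and tiers each site: `ns`, `genome-wide`
#' (corrected p < 0.05) or `extreme` (corrected p < 1e-10).
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b character vectors of population labels.
#' @param m Bonferroni denominator; defaults to the number of polymorphic
#'   tested sites.
#' @return data.frame: `chrom`, `pos`, `chi2`, `p`, `p_bonf`, `tier`,
#'   `monomorphic`.
#' @export
association_scan <- function(gm, group_a, group_b, m = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  rows_a <- gm$samples$population %in% group_a
  rows_b <- gm$samples$population %in% group_b
  if (!any(rows_a) || !any(rows_b)) stop("empty group in association scan")
  ga <- gm$genotypes[rows_a, , drop = FALSE]
  gb <- gm$genotypes[rows_b, , drop = FALSE]
  alt_a <- colSums(ga, na.rm = TRUE)
  alt_b <- colSums(gb, na.rm = TRUE)
  ref_a <- 2 * colSums(!is.na(ga)) - alt_a
  ref_b <- 2 * colSums(!is.na(gb)) - alt_b
  res <- chi2_allele_test(ref_a, alt_a, ref_b, alt_b)
  if (is.null(m)) m <- sum(!res$monomorphic)
  # monomorphic sites are not tests: adjusted only over polymorphic sites
  p_bonf <- rep(1, nrow(res))
  p_bonf[!res$monomorphic] <- bonferroni_adjust(res$p[!res$monomorphic], m)
  tier <- ifelse(p_bonf < 1e-10, "extreme",
                 ifelse(p_bonf < 0.05, "genome-wide", "ns"))
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             chi2 = res$chi2, p = res$p, p_bonf = p_bonf, tier = tier,
             monomorphic = res$monomorphic, stringsAsFactors = FALSE)
}

#' PCA of genotype dosages or pooled frequencies
#'
#' Columns are mean-centred with column-mean imputation of missing entries and
#' no variance scaling (the dosage-PCA convention). All-missing columns are
#' dropped with a message. Optionally, all sites inside each supplied
#' inversion region are collapsed to one synthetic locus coded by the
#' inversion genotype (NN = 0, NS = 1, SS = 2), so the block contributes as a
#' single locus regardless of its SNP count.
#'
#' @param x a [genotype_matrix()], or a plain numeric matrix (rows =
#'   individuals or populations, columns = sites).
#' @param collapse optional list of inversions, each
#'   `list(region = region(), codes = <named numeric vector, one code per
#'   row of x; NA allowed>)`.
#' @return list with `scores` (rows x components), `explained` (proportion of
#'   variance per component) and `sdev`.
#' @export
pca_genotypes <- function(x, collapse = NULL) {
  if (inherits(x, "geno_matrix")) {
    m <- x$genotypes
    sites <- x$sites
  } else {
    m <- as.matrix(x)
    sites <- attr(x, "sites")
  }
  storage.mode(m) <- "double"
  if (!is.null(collapse)) {
    if (is.null(sites)) stop("collapse requires site coordinates")
    drop_cols <- rep(FALSE, ncol(m))
    add <- NULL
    for (iv in collapse) {
      inside <- sites_in_region(sites, iv$region)
      drop_cols <- drop_cols | inside
      codes <- iv$codes
      if (length(codes) != nrow(m))
        stop("inversion codes must supply one value per row")
      add <- cbind(add, as.numeric(codes))
    }
    m <- cbind(m[, !drop_cols, drop = FALSE], add)
  }
  all_miss <- colSums(!is.na(m)) == 0
  if (any(all_miss)) {
    message(sum(all_miss), " all-missing column(s) dropped before PCA")
    m <- m[, !all_miss, drop = FALSE]
  }
  mu <- colMeans(m, na.rm = TRUE)
  for (j in which(colSums(is.na(m)) > 0)) m[is.na(m[, j]), j] <- mu[j]
  if (nrow(m) < 2) stop("PCA requires at least 2 rows")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl, sdev = pc$sdev)
}

#' K-means clustering of PCA coordinates (spawn-season style)
#'
#' Best of `n_init` random initialisations by total within-cluster sum of
#' squares. Cluster labels are arbitrary integers; map them to season names
#' via known anchor samples.
#'
#' @param x numeric matrix (e.g. leading PCA scores).
#' @param K number of clusters (default 2).
#' @param seed integer seed.
#' @param n_init random restarts.
#' @return integer vector of cluster labels, with the fitted
#'   `stats::kmeans` object as attribute `fit`.
#' @export
kmeans_season <- function(x, K = 2, seed = 1L, n_init = 25) {
  x <- as.matrix(x)
  if (K > nrow(x)) stop("K exceeds the number of rows")
  set.seed(seed)
  fit <- suppressWarnings(stats::kmeans(x, centers = K, nstart = n_init))
  out <- fit$cluster
  attr(out, "fit") <- fit
  out
}

#' Two-sided p value from a t statistic
#'
#' `p = 2 * P(T_df >= |t|)`.
#'
#' @param t t statistic.
#' @param df degrees of freedom, `df >= 1`.
#' @return two-sided p value.
#' @export
two_sided_p_from_t <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}
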