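# harmonic sums used by theta_W and Tajima's D
a1_const <- function(n) sum(1 / seq_len(n - 1))
a2_const <- function(n) sum(1 / seq_len(n - 1)^2)

#' Watterson's theta per base
#'
#' `theta_W = S / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S segregating-site count.
#' @param n chromosomes sampled (`n >= 2`).
#' @param L callable length in bp.
#' @return per-base theta_W.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("watterson_theta requires n >= 2")
  if (L <= 0) stop("L must be positive")
  S / (a1_const(n) * L)
}

#' Nucleotide diversity (pi) per base
#'
#' Unbiased per-site heterozygosity summed over sites:
#' `pi = sum_j 2 p_j (1 - p_j) n_j / (n_j - 1) / L`, with per-site sample
#' sizes `n_j` (chromosomes) so that variable missingness is handled.
#'
#' @param p per-site alternate-allele frequencies.
#' @param n per-site chromosome counts (recycled).
#' @param L callable length in bp.
#' @return per-base pi. Use `L = 1` to obtain the total (per-sequence) pi
#'   needed by [tajimas_d()].
#' @export
nucleotide_diversity <- function(p, n, L) {
  if (L <= 0) stop("L must be positive")
  n <- rep_len(n, length(p))
  ok <- !is.na(p)
  poly <- ok & p > 0 & p < 1
  if (any(poly & n < 2)) stop("polymorphic sites require n >= 2")
  contrib <- ifelse(ok & n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)
  sum(contrib[ok]) / L
}

#' Tajima's D
#'
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' constants (a1, a2, b1, b2, c1, c2, e1, e2). `pi_total` is the
#' *unnormalised* (per-sequence) pairwise diversity over the same sites that
#' contribute to `S`. `S = 0` returns `NA` (undefined, not zero).
#'
#' @param S segregating sites (`>= 0`).
#' @param pi_total total pairwise diversity (e.g.
#'   `nucleotide_diversity(p, n, L = 1)`).
#' @param n chromosomes sampled (`n >= 4`).
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(S, pi_total, n) {
  if (n < 4) stop("tajimas_d requires n >= 4")
  if (S < 0) stop("S must be nonnegative")
  if (S == 0) return(NA_real_)
  a1 <- a1_const(n); a2 <- a2_const(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Long-term effective population size from theta
#'
#' `N_e = theta_W / (4 mu)`.
#'
#' @param theta_w per-base Watterson's theta.
#' @param mu per-base, per-generation mutation rate (default 2.0e-9, the
#'   Atlantic herring estimate).
#' @return effective population size.
#' @export
effective_population_size <- function(theta_w, mu = 2.0e-9) {
  if (mu <= 0) stop("mu must be positive")
  theta_w / (4 * mu)
}

#' Reynolds-type coancestry FST components per locus
#'
#' Method-of-moments coancestry estimator for biallelic loci with sample-size
#' correction, in the Reynolds/Weir-Cockerham ratio-of-sums form. Per locus,
#' with allele frequencies `p1, p2` and chromosome counts `c1, c2`:
#' \deqn{h_i = 2 p_i (1-p_i) c_i/(c_i - 1)}
#' \deqn{num = (p_1-p_2)^2 - h_1/(2 c_1) - h_2/(2 c_2)}
#' \deqn{den = num + (h_1 + h_2)/2}
#' Under a pure-drift model with coancestry `theta`, `E[num] = 2 theta p(1-p)`
#' and `E[den] = 2 p(1-p)`, so the aggregate `sum(num)/sum(den)` estimates
#' `theta` without per-locus ratio bias. Negative per-locus estimates are
#' reported as computed (not clamped) so the ratio-of-sums stays exact; the
#' estimate is 1 at a fixed difference.
#'
#' @param p1,p2 per-locus allele frequencies.
#' @param c1,c2 per-locus chromosome counts (`>= 2`; recycled).
#' @return data.frame with `num` and `den` per locus.
#' @export
reynolds_fst_components <- function(p1, p2, c1, c2) {
  c1 <- rep_len(c1, length(p1)); c2 <- rep_len(c2, length(p2))
  if (length(p1) != length(p2)) stop("frequency vectors are not aligned")
  if (any(c1 < 2 | c2 < 2, na.rm = TRUE))
    stop("each locus needs >= 2 chromosomes per population")
  h1 <- 2 * p1 * (1 - p1) * c1 / (c1 - 1)
  h2 <- 2 * p2 * (1 - p2) * c2 / (c2 - 1)
  num <- (p1 - p2)^2 - h1 / (2 * c1) - h2 / (2 * c2)
  den <- num + (h1 + h2) / 2
  data.frame(num = num, den = den)
}

#' Aggregate Reynolds FST (ratio of sums)
#'
#' @param p1,p2,c1,c2 as in [reynolds_fst_components()]; loci with `NA` on
#'   either side are dropped.
#' @return list with `fst`, `num`, `den`, `n_loci`. `fst` is `NA` when the
#'   summed denominator is not positive.
#' @export
reynolds_fst <- function(p1, p2, c1, c2) {
  c1 <- rep_len(c1, length(p1)); c2 <- rep_len(c2, length(p2))
  ok <- !is.na(p1) & !is.na(p2)
  comp <- reynolds_fst_components(p1[ok], p2[ok], c1[ok], c2[ok])
  num <- sum(comp$num); den <- sum(comp$den)
  list(fst = if (den > 0) num / den else NA_real_,
       num = num, den = den, n_loci = sum(ok))
}

# window index for a 1-based position: half-open [k*w, (k+1)*w) on the
# position line, so pos 10,000 with w = 10,000 falls in window 1 (the second)
window_index <- function(pos, window) floor(pos / window)

#' Windowed diversity statistics for one population
#'
#' Splits a chromosome into half-open windows of `window` bp (a position `p`
#' belongs to window `floor(p / window)`), and within each window computes the
#' segregating-site count S (sites polymorphic in the sample), per-base
#' theta_W and pi, and Tajima's D. Per-site chromosome counts feed pi; S-based
#' statistics use the median per-site count across the window's polymorphic
#' sites. Empty windows are retained with `S = 0` and `D = NA`. `L` defaults
#' to the window width (callable-length masks can override via `L`).
#'
#' @param pf a `pop_freqs` table.
#' @param population one row name of `pf$freq`.
#' @param window window width in bp (default 10000).
#' @param L callable length per window (default `window`).
#' @return data.frame: `chrom`, `win_start`, `win_end` (1-based inclusive
#'   bounds of the window on the position line), `S`, `n_med`, `theta_w`,
#'   `pi`, `tajimas_d`.
#' @export
windowed_diversity <- function(pf, population, window = 10000, L = window) {
  stopifnot(inherits(pf, "pop_freqs"))
  if (!population %in% rownames(pf$freq)) stop("unknown population: ", population)
  p <- pf$freq[population, ]
  nc <- pf$chroms[population, ]
  out <- list()
  for (ch in unique(pf$sites$chrom)) {
    on_ch <- pf$sites$chrom == ch
    pos <- pf$sites$pos[on_ch]
    wi <- window_index(pos, window)
    for (w in seq(min(wi), max(wi))) {
      in_w <- on_ch
      in_w[on_ch] <- wi == w
      pj <- p[in_w]; nj <- nc[in_w]
      keep <- !is.na(pj) & nj >= 2
      pj <- pj[keep]; nj <- nj[keep]
      poly <- pj > 0 & pj < 1
      S <- sum(poly)
      n_med <- if (S > 0) stats::median(nj[poly]) else NA_real_
      theta <- if (S > 0) watterson_theta(S, n_med, L) else 0
      pi <- nucleotide_diversity(pj, nj, L)
      D <- if (S > 0 && n_med >= 4)
        tajimas_d(S, nucleotide_diversity(pj[poly], nj[poly], 1), n_med)
      else NA_real_
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, win_start = w * window, win_end = (w + 1) * window - 1,
        S = S, n_med = n_med, theta_w = theta, pi = pi, tajimas_d = D,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Windowed and genome-wide Reynolds FST for a population pair
#'
#' Per-window numerator/denominator sums and their ratio; the genome estimate
#' is the ratio of the summed components over all loci (not the mean of
#' window ratios).
#'
#' @param pf a `pop_freqs` table.
#' @param pop1,pop2 row names of `pf$freq`.
#' @param window window width in bp (default 10000).
#' @return list with `windows` (data.frame `chrom`, `win_start`, `win_end`,
#'   `n_loci`, `num`, `den`, `fst`; `fst` is `NA` where the denominator is
#'   not positive) and `genome` (as from [reynolds_fst()]).
#' @export
windowed_fst <- function(pf, pop1, pop2, window = 10000) {
  stopifnot(inherits(pf, "pop_freqs"))
  p1 <- pf$freq[pop1, ]; p2 <- pf$freq[pop2, ]
  c1 <- pf$chroms[pop1, ]; c2 <- pf$chroms[pop2, ]
  ok <- !is.na(p1) & !is.na(p2) & c1 >= 2 & c2 >= 2
  comp <- data.frame(num = rep(NA_real_, length(p1)), den = NA_real_)
  comp[ok, ] <- reynolds_fst_components(p1[ok], p2[ok], c1[ok], c2[ok])
  out <- list()
  for (ch in unique(pf$sites$chrom)) {
    on_ch <- which(pf$sites$chrom == ch & ok)
    if (length(on_ch) == 0) next
    wi <- window_index(pf$sites$pos[on_ch], window)
    agg_n <- tapply(comp$num[on_ch], wi, sum)
    agg_d <- tapply(comp$den[on_ch], wi, sum)
    cnt <- tapply(comp$num[on_ch], wi, length)
    w <- as.integer(names(agg_n))
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, win_start = w * window, win_end = (w + 1) * window - 1,
      n_loci = as.integer(cnt), num = as.numeric(agg_n),
      den = as.numeric(agg_d),
      fst = ifelse(agg_d > 0, agg_n / agg_d, NA_real_),
      stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, out)
  genome <- reynolds_fst(p1[ok], p2[ok], c1[ok], c2[ok])
  list(windows = windows, genome = genome)
}

#' UPGMA population tree from a pairwise FST matrix
#'
#' Average-linkage agglomeration (`stats::hclust(method = "average")`, i.e.
#' UPGMA), returned as a rooted ultrametric `ape::phylo` tree; ties are broken
#' deterministically by index order.
#'
#' @param d symmetric nonnegative distance matrix (e.g. genome-wide pairwise
#'   FST) with population row/column names.
#' @return a rooted `ape::phylo` tree (tip-to-root height `d/2` for a cherry).
#' @export
upgma_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be nonnegative")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Nearest-ecotype genome fraction
#'
#' Given windowed FST values of several candidate ecotypes against one focal
#' ecotype, finds per window the candidate with minimal FST (ties give no
#' winner), and reports each candidate's fraction of eligible windows won,
#' plus the winning candidate per chromosome (the candidate winning the most
#' windows there). Windows lacking a defined FST for every candidate are
#' excluded. `weight` (e.g. window bp) switches fractions from window counts
#' to weighted shares.
#'
#' @param fst_windows data.frame with columns `chrom`, `win_start`,
#'   `candidate`, `fst` (one row per window x candidate), e.g. stacked
#'   `windows` outputs of [windowed_fst()] against the focal group.
#' @param weight optional column name holding per-row weights.
#' @return list with `fractions` (data.frame `candidate`, `wins`, `fraction`),
#'   `n_eligible`, `n_tied`, and `chromosomes` (data.frame `chrom`, `winner`).
#' @export
nearest_ecotype_fraction <- function(fst_windows, weight = NULL) {
  req <- c("chrom", "win_start", "candidate", "fst")
  if (!all(req %in% names(fst_windows)))
    stop("fst_windows needs columns: ", paste(req, collapse = ", "))
  key <- paste(fst_windows$chrom, fst_windows$win_start, sep = "@")
  cands <- sort(unique(fst_windows$candidate))
  wide <- tapply(fst_windows$fst, list(key, fst_windows$candidate),
                 function(v) v[1])
  wide <- wide[, cands, drop = FALSE]
  eligible <- rowSums(is.na(wide)) == 0
  wide <- wide[eligible, , drop = FALSE]
  if (nrow(wide) == 0) stop("no eligible windows")
  winner <- apply(wide, 1, function(v) {
    m <- which(v == min(v))
    if (length(m) != 1) NA_character_ else cands[m]
  })
  w <- if (is.null(weight)) rep(1, nrow(wide)) else {
    wl <- tapply(fst_windows[[weight]], key, function(v) v[1])
    as.numeric(wl[rownames(wide)])
  }
  tot <- sum(w)
  wins <- vapply(cands, function(cd)
    sum(w[!is.na(winner) & winner == cd]), numeric(1))
  fractions <- data.frame(candidate = cands, wins = wins,
                          fraction = wins / tot, stringsAsFactors = FALSE)
  chrom_of <- sub("@.*$", "", rownames(wide))
  chr_winner <- vapply(unique(chrom_of), function(ch) {
    tab <- table(winner[chrom_of == ch & !is.na(winner)])
    if (length(tab) == 0) return(NA_character_)
    top <- names(tab)[tab == max(tab)]
    if (length(top) != 1) NA_character_ else top
  }, character(1))
  list(fractions = fractions, n_eligible = nrow(wide),
       n_tied = sum(is.na(winner)),
       chromosomes = data.frame(chrom = unique(chrom_of),
                                winner = unname(chr_winner),
                                stringsAsFactors = FALSE))
}
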