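#' Per-population allele frequencies with coverage accounting
#'
#' For each population and site, the alternate-allele frequency is the summed
#' dosage over non-missing genotypes divided by the number of observed
#' chromosomes (2 x non-missing genotypes). Sites at which a population has no
#' observed chromosomes get frequency `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param by grouping column of `gm$samples`: `"population"` (default) or
#'   `"ecotype"`, or a vector of group labels, one per individual.
#' @return An object of class `pop_freqs`: list with `freq` and `chroms`
#'   (group x site matrices) and the `sites` table.
#' @export
pop_allele_freqs <- function(gm, by = "population") {
  stopifnot(inherits(gm, "geno_matrix"))
  labels <- if (length(by) == 1 && is.character(by) && by %in% names(gm$samples))
    gm$samples[[by]] else as.character(by)
  if (length(labels) != nrow(gm$genotypes))
    stop("grouping must supply one label per individual")
  groups <- unique(labels)
  if (anyNA(labels)) stop("grouping contains NA labels")
  g <- gm$genotypes
  freq <- matrix(NA_real_, length(groups), ncol(g),
                 dimnames = list(groups, colnames(g)))
  chroms <- matrix(0L, length(groups), ncol(g),
                   dimnames = list(groups, colnames(g)))
  for (k in seq_along(groups)) {
    rows <- which(labels == groups[k])
    if (length(rows) == 0) stop("empty group: ", groups[k])
    sub <- g[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    chroms[k, ] <- 2L * n_obs
    freq[k, ] <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  }
  structure(list(freq = freq, chroms = chroms, sites = gm$sites),
            class = "pop_freqs")
}

#' Construct a pop_freqs table directly
#'
#' @param freq group x site matrix of alternate-allele frequencies in `[0,1]`
#'   (`NA` where unobserved).
#' @param chroms group x site matrix of observed-chromosome counts.
#' @param sites site table (`chrom`, `pos`, and optionally `ref`, `alt`).
#' @return A `pop_freqs` object.
#' @export
pop_freqs <- function(freq, chroms, sites) {
  freq <- as.matrix(freq); chroms <- as.matrix(chroms)
  if (!all(dim(freq) == dim(chroms)))
    stop("freq and chroms must have identical dimensions")
  if (nrow(sites) != ncol(freq))
    stop("sites rows must match freq columns")
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0,1]")
  if (any(!is.na(freq) & chroms == 0))
    stop("freq defined where observed chromosomes = 0")
  rn <- rownames(freq)
  if (is.null(rn)) rn <- rownames(chroms)
  if (is.null(rn)) rn <- paste0("pop", seq_len(nrow(freq)))
  rownames(freq) <- rownames(chroms) <- rn
  colnames(freq) <- colnames(chroms) <- paste0(sites$chrom, ":", sites$pos)
  structure(list(freq = freq, chroms = chroms, sites = sites),
            class = "pop_freqs")
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat("pop_freqs:", nrow(x$freq), "groups x", ncol(x$freq), "sites\n")
  invisible(x)
}

#' Site coverage filter
#'
#' Retains a site when the summed observed-chromosome count across the
#' contrasted groups is at least `min_observed`. By default `min_observed` is
#' derived from the possible total as `ceiling(min_fraction * total)`; with the
#' default 92% fraction, a possible total of 152 chromosomes gives a threshold
#' of 140, so 140/152 is retained and 139/152 is not.
#'
#' @param observed integer vector: per site, summed observed chromosomes over
#'   the contrasted groups (e.g. `colSums(pf$chroms[groups, ])`).
#' @param total possible chromosome total across those groups
#'   (2 x summed sample sizes).
#' @param min_fraction minimum fraction of `total` required; default 0.92.
#' @param min_observed explicit threshold overriding `min_fraction`.
#' @return logical vector, `TRUE` = site retained. Attributes `min_observed`,
#'   `total` and `fraction_pct` (the threshold as a rounded percentage) record
#'   the rule applied.
#' @export
site_coverage_filter <- function(observed, total, min_fraction = 0.92,
                                 min_observed = NULL) {
  if (is.null(min_observed)) min_observed <- ceiling(min_fraction * total)
  if (min_observed > total)
    stop("min_observed (", min_observed, ") exceeds possible total (", total, ")")
  mask <- observed >= min_observed
  attr(mask, "min_observed") <- min_observed
  attr(mask, "total") <- total
  attr(mask, "fraction_pct") <- round(100 * min_observed / total)
  mask
}

#' Pool populations into one frequency vector
#'
#' Chromosome-weighted mean of member frequencies:
#' `sum(freq_k * chroms_k) / sum(chroms_k)`. Sites with zero pooled
#' chromosomes are `NA`.
#'
#' @param pf a `pop_freqs` object.
#' @param members character vector of row names of `pf$freq` to pool.
#' @return list with `freq` and `chroms` vectors (one entry per site).
#' @export
pool_groups <- function(pf, members) {
  stopifnot(inherits(pf, "pop_freqs"))
  bad <- setdiff(members, rownames(pf$freq))
  if (length(bad) > 0) stop("unknown group(s): ", paste(bad, collapse = ", "))
  f <- pf$freq[members, , drop = FALSE]
  c2 <- pf$chroms[members, , drop = FALSE]
  w <- ifelse(is.na(f), 0, c2)
  tot <- colSums(w)
  num <- colSums(ifelse(is.na(f), 0, f * c2))
  list(freq = ifelse(tot > 0, num / tot, NA_real_), chroms = tot)
}

#' Delta allele frequency
#'
#' Signed per-site difference `freq_a - freq_b`; `NA` where either side is
#' undefined. Antisymmetric by construction.
#'
#' @param freq_a,freq_b aligned frequency vectors.
#' @return numeric vector in `[-1, 1]`.
#' @export
delta_af <- function(freq_a, freq_b) {
  if (length(freq_a) != length(freq_b))
    stop("frequency vectors are not aligned")
  freq_a - freq_b
}

#' Delta-AF heatmap matrix for a region
#'
#' Restricts a region to sites where any displayed population's |delta-AF|
#' against a pooled baseline strictly exceeds `cutoff`, and returns the
#' population x site delta-AF matrix (sites ordered by position, populations
#' in the order given).
#'
#' @param pf a `pop_freqs` object.
#' @param r a [region()].
#' @param baseline character vector of groups pooled (chromosome-weighted)
#'   into the baseline.
#' @param populations groups to display, in row order; defaults to all groups.
#' @param cutoff delta-AF cutoff (strictly-greater comparison); e.g. 0.25 or
#'   0.35 for zoom-in heatmaps.
#' @return matrix of delta-AF values with an attribute `sites` (the retained
#'   site table); zero columns (with a warning) when no site passes.
#' @export
heatmap_matrix <- function(pf, r, baseline, populations = rownames(pf$freq),
                           cutoff = 0.25) {
  stopifnot(inherits(pf, "pop_freqs"), inherits(r, "region"))
  base <- pool_groups(pf, baseline)$freq
  in_r <- which(sites_in_region(pf$sites, r))
  in_r <- in_r[order(pf$sites$pos[in_r])]
  d <- pf$freq[populations, in_r, drop = FALSE] -
    matrix(base[in_r], nrow = length(populations), ncol = length(in_r),
           byrow = TRUE)
  keep_site <- apply(abs(d), 2, function(col) any(col > cutoff, na.rm = TRUE))
  keep_site[is.na(keep_site)] <- FALSE
  if (!any(keep_site))
    warning("no sites exceed the delta-AF cutoff in ", r$chrom)
  out <- d[, keep_site, drop = FALSE]
  attr(out, "sites") <- pf$sites[in_r[keep_site], , drop = FALSE]
  out
}

#' Write a delta-AF or frequency matrix as TSV
#'
#' @param m matrix with a `sites` attribute (as from [heatmap_matrix()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  sites <- attr(m, "sites")
  df <- cbind(sites[, c("chrom", "pos")],
              as.data.frame(t(m), row.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
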