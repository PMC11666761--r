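#' Build Northern/Southern consensus reference haplotypes
#'
#' For each site in the inversion region, a side's consensus allele is the
#' allele (ref or alt) whose frequency is at least `purity` in *every* pool of
#' that side; sites where either side has no qualifying allele are dropped.
#' The diagnostic flag marks sites where the two consensus alleles differ -
#' the sites usable to score haplotype ancestry.
#'
#' @param pf a `pop_freqs` table.
#' @param pure_n,pure_s character vectors of pools fixed (or nearly so) for
#'   the Northern / Southern haplotype.
#' @param r the inversion [region()].
#' @param purity supermajority threshold in `[0.5, 1]` applied per pool.
#' @return object of class `hap_ref`: data.frame `chrom`, `pos`, `n_allele`,
#'   `s_allele` (each `"ref"` or `"alt"`), `diagnostic`; the region and pool
#'   lists are kept as attributes.
#' @export
build_consensus <- function(pf, pure_n, pure_s, r, purity = 0.8) {
  stopifnot(inherits(pf, "pop_freqs"), inherits(r, "region"))
  if (purity < 0.5 || purity > 1) stop("purity must lie in [0.5, 1]")
  if (length(pure_n) < 1 || length(pure_s) < 1)
    stop("at least one pure pool per side is required")
  bad <- setdiff(c(pure_n, pure_s), rownames(pf$freq))
  if (length(bad)) stop("unknown pool(s): ", paste(bad, collapse = ", "))
  idx <- which(sites_in_region(pf$sites, r))
  idx <- idx[order(pf$sites$pos[idx])]
  side_consensus <- function(pools) {
    f <- pf$freq[pools, idx, drop = FALSE]
    alt_ok <- apply(f, 2, function(v) all(!is.na(v) & v >= purity))
    ref_ok <- apply(f, 2, function(v) all(!is.na(v) & (1 - v) >= purity))
    ifelse(alt_ok, "alt", ifelse(ref_ok, "ref", NA_character_))
  }
  n_allele <- side_consensus(pure_n)
  s_allele <- side_consensus(pure_s)
  keep <- !is.na(n_allele) & !is.na(s_allele)
  out <- data.frame(chrom = pf$sites$chrom[idx][keep],
                    pos = pf$sites$pos[idx][keep],
                    n_allele = n_allele[keep], s_allele = s_allele[keep],
                    diagnostic = n_allele[keep] != s_allele[keep],
                    stringsAsFactors = FALSE)
  if (sum(out$diagnostic) == 0)
    stop("no diagnostic sites in region ", r$chrom, ":",
         r$start_bp, "-", r$end_bp)
  structure(out, class = c("hap_ref", "data.frame"),
            region = r, pure_n = pure_n, pure_s = pure_s, purity = purity)
}

#' Score one genotype against a diagnostic site
#'
#' Homozygous for the Northern consensus allele scores `NN`, heterozygous
#' `NS`, homozygous for the Southern allele `SS`; missing scores `NA`.
#'
#' @param dosage alternate-allele dosage (0, 1, 2 or `NA`); vectorised.
#' @param n_is_alt logical: is the Northern consensus allele the alternate
#'   allele at this site? (Recycled against `dosage`.)
#' @return character vector of `"NN"`, `"NS"`, `"SS"`, `NA`.
#' @export
score_snp <- function(dosage, n_is_alt) {
  n_dosage <- ifelse(n_is_alt, dosage, 2 - dosage)
  out <- rep(NA_character_, length(n_dosage))
  out[!is.na(n_dosage) & n_dosage == 2] <- "NN"
  out[!is.na(n_dosage) & n_dosage == 1] <- "NS"
  out[!is.na(n_dosage) & n_dosage == 0] <- "SS"
  out
}

#' Score all individuals at an inversion's diagnostic sites
#'
#' @param gm a [genotype_matrix()].
#' @param ref a `hap_ref` from [build_consensus()]; only diagnostic sites are
#'   used.
#' @return character matrix (individuals x diagnostic sites) of NN/NS/SS/NA.
#' @export
score_genotypes <- function(gm, ref) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(ref, "hap_ref"))
  d <- ref[ref$diagnostic, , drop = FALSE]
  key <- paste0(d$chrom, ":", d$pos)
  col <- match(key, colnames(gm$genotypes))
  if (anyNA(col))
    stop("diagnostic site(s) absent from genotype matrix: ",
         paste(utils::head(key[is.na(col)], 5), collapse = ", "))
  n_is_alt <- d$n_allele == "alt"
  g <- gm$genotypes[, col, drop = FALSE]
  scr <- matrix(score_snp(as.vector(g),
                          rep(n_is_alt, each = nrow(g))),
                nrow = nrow(g), dimnames = list(rownames(g), key))
  scr
}

#' Call inversion genotypes by majority vote
#'
#' The genotype of an individual is the predominant score (NN/NS/SS) across
#' diagnostic sites; ties, or fewer than `min_sites` scored sites, give
#' `unassigned`.
#'
#' @param scores character matrix from [score_genotypes()] (or a single row).
#' @param min_sites minimum scored diagnostic sites required.
#' @return data.frame: `sample_id`, `genotype`, `n_NN`, `n_NS`, `n_SS`,
#'   `n_diagnostic_used`.
#' @export
call_inversion <- function(scores, min_sites = 5) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  lv <- c("NN", "NS", "SS")
  votes <- t(apply(scores, 1, function(s) table(factor(s, levels = lv))))
  used <- rowSums(votes)
  geno <- apply(votes, 1, function(v) {
    top <- which(v == max(v))
    if (length(top) != 1) "unassigned" else lv[top]
  })
  geno[used < min_sites] <- "unassigned"
  ids <- rownames(scores)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(scores)))
  data.frame(sample_id = ids, genotype = geno,
             n_NN = votes[, 1], n_NS = votes[, 2], n_SS = votes[, 3],
             n_diagnostic_used = used, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify a population's diagnostic sites and estimate S-haplotype frequency
#'
#' At each diagnostic site, the population's pooled frequency of the Southern
#' consensus allele `f_S` classifies the site: `S-like` when `f_S > 1 - tau`,
#' `N-like` when `f_S < tau`, otherwise `intermediate`. The S-haplotype
#' frequency estimate is the mean `f_S` across diagnostic sites.
#'
#' @param pooled_freq alternate-allele frequency vector aligned to the full
#'   `hap_ref` site table (or a named vector keyed `chrom:pos`).
#' @param ref a `hap_ref`.
#' @param tau classification margin in (0, 0.5]; default 0.2.
#' @return list with `sites` (data.frame `chrom`, `pos`, `f_S`, `class`) and
#'   `s_frequency` (the mean-f_S estimate).
#' @export
classify_population_sites <- function(pooled_freq, ref, tau = 0.2) {
  stopifnot(inherits(ref, "hap_ref"))
  d <- ref[ref$diagnostic, , drop = FALSE]
  key <- paste0(d$chrom, ":", d$pos)
  f <- if (!is.null(names(pooled_freq))) pooled_freq[key]
  else {
    if (length(pooled_freq) != nrow(ref))
      stop("pooled_freq must align with the hap_ref site table")
    pooled_freq[ref$diagnostic]
  }
  f_S <- ifelse(d$s_allele == "alt", f, 1 - f)
  cls <- ifelse(is.na(f_S), NA_character_,
                ifelse(f_S > 1 - tau, "S-like",
                       ifelse(f_S < tau, "N-like", "intermediate")))
  list(sites = data.frame(chrom = d$chrom, pos = d$pos, f_S = f_S,
                          class = cls, stringsAsFactors = FALSE),
       s_frequency = mean(f_S, na.rm = TRUE))
}

#' Detect recombinant haplotype segments
#'
#' Finds maximal runs of at least `min_run` consecutive diagnostic sites
#' classified to the side opposite the declared background (e.g. N-like runs
#' on a Southern background, the signature of a historical recombination
#' between inversion arrangements). Intermediate or unclassified sites break
#' runs. Bounds are the first and last diagnostic sites of the run (1-based
#' inclusive bp).
#'
#' @param classified the `sites` data.frame from
#'   [classify_population_sites()], ordered by position.
#' @param background `"S"` or `"N"`: the population's predominant haplotype
#'   class.
#' @param min_run minimum run length in diagnostic sites (default 5).
#' @return data.frame of segments: `start_bp`, `end_bp`,
#'   `n_diagnostic_sites`, `background`, `foreign`.
#' @export
detect_recombinant_segments <- function(classified, background = c("S", "N"),
                                        min_run = 5) {
  background <- match.arg(background)
  foreign <- if (background == "S") "N-like" else "S-like"
  hit <- !is.na(classified$class) & classified$class == foreign
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- which(runs$values & runs$lengths >= min_run)
  data.frame(start_bp = classified$pos[starts[seg]],
             end_bp = classified$pos[ends[seg]],
             n_diagnostic_sites = runs$lengths[seg],
             background = rep(background, length(seg)),
             foreign = rep(substr(foreign, 1, 1), length(seg)),
             stringsAsFactors = FALSE)
}

#' Scan for sweep-like sites inside an inversion
#'
#' Flags sites whose pooled frequency in the focal population differs by more
#' than `cutoff` from *both* the N-bearing and the S-bearing reference pools -
#' differentiation from one side only is the recombination signature, from
#' both sides the sweep signature. Contiguous flagged sites are merged into
#' subregions.
#'
#' @param focal_freq,freq_n,freq_s aligned frequency vectors over the
#'   region's sites.
#' @param sites site table (`chrom`, `pos`) aligned to the vectors, ordered by
#'   position.
#' @param cutoff delta-AF cutoff (strict), e.g. 0.35.
#' @return list with `flagged` (logical per site) and `subregions`
#'   (data.frame `start_bp`, `end_bp`, `n_sites`).
#' @export
sweep_scan <- function(focal_freq, freq_n, freq_s, sites, cutoff = 0.35) {
  if (length(focal_freq) != length(freq_n) ||
      length(focal_freq) != length(freq_s) ||
      length(focal_freq) != nrow(sites))
    stop("inputs are not aligned")
  flagged <- abs(focal_freq - freq_n) > cutoff &
    abs(focal_freq - freq_s) > cutoff
  flagged[is.na(flagged)] <- FALSE
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- which(runs$values)
  sub <- data.frame(start_bp = sites$pos[starts[seg]],
                    end_bp = sites$pos[ends[seg]],
                    n_sites = runs$lengths[seg])
  list(flagged = flagged, subregions = sub)
}

#' Neighbor-joining tree from regional allele-frequency differences
#'
#' Pairwise distance between populations is the Euclidean distance of their
#' frequency vectors over the region's sites (restricted to sites defined in
#' all included populations), divided by the square root of the site count -
#' i.e. the root-mean-square delta allele frequency - so trees are comparable
#' across regions with different SNP counts. Agglomeration is Saitou-Nei
#' neighbor joining (via `ape::nj`).
#'
#' @param pf a `pop_freqs` table.
#' @param r a [region()].
#' @param populations groups to include (>= 3).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree_region <- function(pf, r, populations = rownames(pf$freq)) {
  stopifnot(inherits(pf, "pop_freqs"), inherits(r, "region"))
  if (length(populations) < 3)
    stop("neighbor joining requires at least 3 populations")
  idx <- which(sites_in_region(pf$sites, r))
  f <- pf$freq[populations, idx, drop = FALSE]
  defined <- colSums(is.na(f)) == 0
  f <- f[, defined, drop = FALSE]
  if (ncol(f) < 1) stop("no sites defined in all populations within region")
  d <- stats::dist(f) / sqrt(ncol(f))
  ape::nj(d)
}

#' Write recombinant segments as BED
#'
#' Converts the internal 1-based inclusive bounds to BED's 0-based half-open
#' convention.
#'
#' @param segments data.frame from [detect_recombinant_segments()].
#' @param chrom chromosome id for the segments.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, chrom, path) {
  bed <- data.frame(chrom = chrom,
                    start = segments$start_bp - 1L,
                    end = segments$end_bp,
                    name = paste0(segments$foreign, "_segment_",
                                  seq_len(nrow(segments))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
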