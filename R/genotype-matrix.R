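#' Genotype matrix container
#'
#' Bundles a biallelic-SNP dosage matrix (individuals x sites, values 0/1/2
#' counting copies of the VCF alternate allele, `NA` = missing call) with its
#' site table and sample table.
#'
#' @param genotypes integer matrix, individuals in rows, sites in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`; one row per column of `genotypes`. Positions must be strictly
#'   increasing within each chromosome.
#' @param samples data.frame with columns `sample_id`, `population` and
#'   optionally `ecotype`; one row per row of `genotypes`.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `genotypes`, `sites`, `samples`.
#' @export
genotype_matrix <- function(genotypes, sites, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!all(is.na(genotypes) | genotypes %in% 0:2))
    stop("genotypes must be 0, 1, 2 or NA")
  if (nrow(sites) != ncol(genotypes))
    stop("sites table has ", nrow(sites), " rows but genotype matrix has ",
         ncol(genotypes), " columns")
  if (nrow(samples) != nrow(genotypes))
    stop("samples table has ", nrow(samples), " rows but genotype matrix has ",
         nrow(genotypes), " rows")
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("samples must have columns sample_id and population")
  if (is.null(samples$ecotype)) samples$ecotype <- samples$population
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("site positions must be strictly increasing within chromosome ", ch)
  }
  rownames(genotypes) <- samples$sample_id
  if (ncol(genotypes) > 0)
    colnames(genotypes) <- paste0(sites$chrom, ":", sites$pos)
  structure(list(genotypes = genotypes, sites = sites, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "sites;",
      length(unique(x$samples$population)), "populations;",
      sum(is.na(x$genotypes)), "missing calls\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$genotypes)

#' Read a sample-to-population map
#'
#' @param path TSV with header columns `sample_id`, `population` and
#'   optionally `ecotype`.
#' @return data.frame of sample labels.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(pm)))
    stop("popmap ", path, " must have columns sample_id and population")
  if (is.null(pm$ecotype)) pm$ecotype <- pm$population
  pm
}

#' Read a VCF of biallelic SNPs into a genotype matrix
#'
#' Multiallelic records and records whose REF or ALT is not a single base are
#' skipped (a message reports the count). Genotype dosage is taken from the GT
#' field; any allele separator (`/` or `|`) is accepted and partial calls are
#' treated as missing.
#'
#' @param path VCF file (v4.x, plain text or bgzipped).
#' @param popmap optional data.frame from [read_popmap()] (or a path to one).
#'   Every VCF sample must be present; offenders are named in the error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  samples_ids <- colnames(v@gt)[-1]
  if (is.null(samples_ids)) samples_ids <- character(0)

  keep <- rep(TRUE, n_rec)
  if (n_rec > 0) {
    keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
      nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
      fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
    n_skip <- sum(!keep)
    if (n_skip > 0)
      message(n_skip, " multiallelic/non-SNP record(s) skipped")
  }

  if (n_rec > 0 && any(keep)) {
    gt <- v@gt[keep, -1, drop = FALSE]
    first <- substr(gt, 1, 1)
    second <- substr(gt, 3, 3)
    dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    ok <- first %in% c("0", "1") & second %in% c("0", "1")
    dos[ok] <- (first[ok] == "1") + (second[ok] == "1")
    geno <- t(dos)
  } else {
    geno <- matrix(integer(0), nrow = length(samples_ids), ncol = 0)
  }

  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0)
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))

  if (is.character(popmap)) popmap <- read_popmap(popmap)
  if (!is.null(popmap)) {
    missing_samples <- setdiff(samples_ids, popmap$sample_id)
    if (length(missing_samples) > 0)
      stop("samples absent from popmap: ",
           paste(missing_samples, collapse = ", "))
    idx <- match(samples_ids, popmap$sample_id)
    samples <- popmap[idx, , drop = FALSE]
    rownames(samples) <- NULL
  } else {
    samples <- data.frame(sample_id = samples_ids,
                          population = rep(NA_character_, length(samples_ids)),
                          ecotype = rep(NA_character_, length(samples_ids)),
                          stringsAsFactors = FALSE)
    # population labels unknown: bypass constructor check via placeholder
    samples$population <- "unassigned"
    samples$ecotype <- "unassigned"
  }
  genotype_matrix(geno, sites, samples)
}

#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Emits VCF v4.2 with `./.` for missing genotypes; round-trips losslessly
#' through [read_vcf()].
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ecoscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (ch in unique(gm$sites$chrom)) {
    maxp <- max(gm$sites$pos[gm$sites$chrom == ch])
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, maxp + 1L), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples$sample_id),
                   collapse = "\t"), con)
  if (ncol(gm$genotypes) > 0) {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    g <- gm$genotypes
    gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
    ok <- !is.na(g)
    gt[ok] <- gt_code[as.character(g[ok])]
    lines <- vapply(seq_len(ncol(g)), function(j) {
      paste(c(gm$sites$chrom[j], gm$sites$pos[j], ".",
              gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".", "GT",
              gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a sample-to-population map
#'
#' @param samples data.frame with `sample_id`, `population`, `ecotype`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "population", "ecotype")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
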