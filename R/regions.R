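#' Genomic region (1-based, inclusive)
#'
#' @param chrom chromosome id.
#' @param start_bp,end_bp 1-based inclusive bounds, `start_bp <= end_bp`.
#' @return A list of class `region`.
#' @export
region <- function(chrom, start_bp, end_bp) {
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (!is.finite(start_bp) || !is.finite(end_bp) || start_bp > end_bp)
    stop("invalid region: start_bp must be <= end_bp")
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp), class = "region")
}

#' Parse "chrom:start-end" into a region
#'
#' Commas in the coordinates are permitted (e.g. `"chr12:17,800,000-25,600,000"`).
#' @param x character scalar.
#' @return A [region()].
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse region: ", x)
  region(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' Region span in megabases
#'
#' The span is `end - start` in Mb, the figure conventionally quoted for a
#' region printed as e.g. "17.8-25.6 Mb" (7.8 Mb). The inclusive length in bp
#' is `end - start + 1`.
#'
#' @param r a [region()].
#' @return numeric, megabases.
#' @export
region_span_mb <- function(r) {
  stopifnot(inherits(r, "region"))
  (r$end_bp - r$start_bp) / 1e6
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%.3g Mb)\n", x$chrom,
              format(x$start_bp, big.mark = ",", scientific = FALSE),
              format(x$end_bp, big.mark = ",", scientific = FALSE),
              region_span_mb(x)))
  invisible(x)
}

# logical mask of sites inside a region
sites_in_region <- function(sites, r) {
  sites$chrom == r$chrom & sites$pos >= r$start_bp & sites$pos <= r$end_bp
}
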