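#' Genomic interval (1-based, inclusive)
#'
#' All public coordinates in crestmap are 1-based and inclusive on both ends,
#' the convention used to report the duplication as Chr33:7,587,588-7,587,784.
#' Internal array arithmetic may use 0-based half-open coordinates, but only
#' via [to_zero_based()] / [to_one_based()], which compose to the identity.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds; `end >= start >= 1`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  if (is.na(start) || start < 1L) stop("start must be >= 1")
  if (is.na(end) || end < start) stop("end must be >= start")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(gi_length(x), big.mark = ",")))
  invisible(x)
}

#' Length of a genomic interval in bp
#' @param x A `genomic_interval`.
#' @return Integer width `end - start + 1`.
#' @export
gi_length <- function(x) x$end - x$start + 1L

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' The single audited converter pair. `to_one_based(to_zero_based(s, e))`
#' is the identity.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return List with `start` (0-based) and `end` (exclusive).
#' @export
to_zero_based <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

# Reverse complement for plain character strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
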