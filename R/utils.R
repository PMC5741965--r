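#' Genome layout: named chromosome lengths
#'
#' A `genome_layout` is the coordinate space for every interval in the
#' pipeline: a named numeric vector of chromosome lengths in bp. All internal
#' intervals are 0-based half-open; variant positions are 1-based (VCF
#' convention) and converted at the I/O boundary.
#'
#' @param lengths named numeric vector, chromosome name -> length in bp
#' @return a `genome_layout` object
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(names(lengths))) stop("duplicated chromosome names")
  structure(stats::setNames(as.numeric(lengths), names(lengths)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x), "chromosomes,",
      format(sum(x), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a two-column chrom.sizes file
#' @param path path to a whitespace-separated file (chrom, length)
#' @return a [genome_layout()]
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(stats::setNames(df$length, df$chrom))
}

#' @rdname read_chrom_sizes
#' @param layout a genome_layout
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(data.frame(chrom = names(layout),
                                length = format(unclass(layout), scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Percentage with fixed rounding
#'
#' `part/total` as a percentage rounded half-up-agnostic via [round()];
#' 0 (with a warning) when `total` is 0, so summary tables never carry NaN.
#'
#' @param part,total non-negative counts
#' @param digits decimal places (summary tables use 2, fractions in running
#'   text use 1)
#' @return numeric percentage
#' @export
pct <- function(part, total, digits = 2) {
  if (length(total) == 1 && total == 0) {
    warning("pct(): zero total, reporting 0")
    return(0)
  }
  round(100 * part / total, digits)
}

# internal: GRanges from 0-based half-open triples
.granges <- function(chrom, start0, end0, ..., layout = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0))
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(gr)[names(mc)] <- mc
  gr
}

# internal: 0-based start / half-open end from a GRanges
.start0 <- function(gr) GenomicRanges::start(gr) - 1L
.end0 <- function(gr) GenomicRanges::end(gr)

.stopifnot_layout <- function(layout) {
  if (!inherits(layout, "genome_layout")) stop("need a genome_layout")
}
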