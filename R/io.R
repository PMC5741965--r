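#' Read a minimal single-sample VCF
#'
#' The pipeline's variant dialect is a minimal tab-separated VCF: CHROM, POS
#' (1-based), ID, REF, ALT, QUAL, FILTER, INFO, FORMAT, and one sample column
#' whose GT is `0/1` (het) or `1/1` (hom) against a single ALT allele.
#' Multi-allelic ALT fields (comma-separated) are decomposed into the set of
#' called alleles via the GT indices.
#'
#' @param path path to a (possibly header-carrying) VCF file
#' @return data.frame with columns chrom, pos, ref, alleles (comma-joined
#'   called alleles), zygosity ("hom"/"het")
#' @export
read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alleles = character(), zygosity = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 10)) stop("VCF record with fewer than 10 fields at line ", which(nf < 10)[1])
  m <- matrix(unlist(lapply(f, `[`, 1:10)), ncol = 10, byrow = TRUE)
  gt <- sub(":.*", "", m[, 10])
  idx <- strsplit(gt, "[/|]")
  alt <- strsplit(m[, 5], ",", fixed = TRUE)
  ref <- m[, 4]
  alleles <- vapply(seq_along(idx), function(i) {
    ai <- as.integer(idx[[i]])
    al <- unique(ifelse(ai == 0L, ref[i], alt[[i]][ai]))
    paste(sort(al), collapse = ",")
  }, character(1))
  zyg <- vapply(idx, function(ai) if (length(unique(ai)) > 1L) "het" else "hom",
                character(1))
  data.frame(chrom = m[, 1], pos = as.numeric(m[, 2]), ref = ref,
             alleles = alleles, zygosity = zyg, stringsAsFactors = FALSE)
}

#' Write a minimal single-sample VCF
#'
#' @param df data.frame with chrom, pos (1-based), ref, alt, zygosity
#' @param path output path
#' @param sample sample name for the header
#' @param layout optional [genome_layout()] for contig header lines
#' @export
write_minimal_vcf <- function(df, path, sample = "SAMPLE", layout = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(layout)) {
    writeLines(sprintf("##contig=<ID=%s,length=%s>", names(layout),
                       format(unclass(layout), scientific = FALSE, trim = TRUE)), con)
  }
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample, sep = "\t"), con)
  if (nrow(df)) {
    gt <- ifelse(df$zygosity == "het", "0/1", "1/1")
    writeLines(paste(df$chrom, format(df$pos, scientific = FALSE, trim = TRUE),
                     ".", df$ref, df$alt, ".", "PASS", ".", "GT", gt,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read/write BED (0-based half-open) as GRanges
#'
#' Columns beyond the third are kept as metadata columns `name`, `score`,
#' `strand`, then verbatim. Writing emits plain tab-separated BED with any
#' metadata columns appended in order.
#'
#' @param path file path
#' @param extra_names optional names for columns 4+
#' @return GRanges (1-based closed internally; BED convention at I/O)
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  nm <- c("chrom", "start", "end")
  if (ncol(df) > 3) {
    xs <- if (!is.null(extra_names)) extra_names
          else c("name", "score", "strand")[seq_len(min(3, ncol(df) - 3))]
    xs <- c(xs, paste0("V", seq_len(max(0, ncol(df) - 3 - length(xs)))))
    nm <- c(nm, xs[seq_len(ncol(df) - 3)])
  }
  names(df) <- nm
  gr <- .granges(df$chrom, df$start, df$end)
  if (ncol(df) > 3) S4Vectors::mcols(gr) <- df[-(1:3)]
  gr
}

#' @rdname read_bed
#' @param gr GRanges to write
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = format(.start0(gr), scientific = FALSE, trim = TRUE),
                   end = format(.end0(gr), scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene model table I/O
#'
#' Gene models travel as a TSV with one row per gene: `gene_id`, `chrom`,
#' `strand` (+/-), `tss` (0-based), `exons` and `cds` as comma-joined
#' `start-end` 0-based half-open intervals in genomic order, and `cds_seq`,
#' the spliced CDS sequence in translation order (carried with the model so
#' consequence calls need no genome FASTA).
#'
#' @param path TSV path
#' @return data.frame with list-columns `exons`, `cds` (two-column matrices)
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character", chrom = "character",
                                         strand = "character", tss = "numeric",
                                         exons = "character", cds = "character",
                                         cds_seq = "character"))
  df$exons <- lapply(df$exons, .parse_intervals)
  df$cds <- lapply(df$cds, .parse_intervals)
  df
}

.parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(numeric(), ncol = 2))
  p <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

.format_intervals <- function(m) {
  paste(sprintf("%.0f-%.0f", m[, 1], m[, 2]), collapse = ",")
}

#' @rdname read_gene_models
#' @param genes gene model data.frame (list-columns as from [read_gene_models()])
#' @export
write_gene_models <- function(genes, path) {
  out <- genes
  out$exons <- vapply(genes$exons, .format_intervals, character(1))
  out$cds <- vapply(genes$cds, .format_intervals, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-window mapping-statistics table
#'
#' TSV with columns chrom, window_index (0-based), mean_mapq, mean_coverage,
#' on the same grid as the SSV window track.
#' @param path TSV path
#' @return data.frame
#' @export
read_window_stats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# generic TSV helpers used across the pipeline
.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
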