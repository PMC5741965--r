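#' Strain-specific variant (SSV) calling
#'
#' An SSV for a query strain is a genomic position where the query carries at
#' least one allele absent from the comparison baseline. Against the
#' reference alone the baseline is `{ref}`; against a control strain the
#' baseline is the union of `{ref}` and the control's called alleles at that
#' position (a position absent from the control contributes `{ref}` only, the
#' control being reference-like there). This discards from the query the
#' variation shared identical-by-descent with the control.
#'
#' Only single-nucleotide alleles (A/C/G/T) are considered; records whose
#' called alleles are all non-ACGT (indels, symbolic) are skipped with a
#' warning. Heterozygous calls are retained.
#'
#' @param query data.frame as returned by [read_minimal_vcf()]
#' @param control optional data.frame of control-strain calls (same reference)
#' @param label comparison label stored on the result
#' @return an `ssv_set`: data.frame (chrom, pos 1-based, alleles = comma-joined
#'   novel alleles) with attributes `label` and `n_skipped`
#' @export
call_ssvs <- function(query, control = NULL, label = "query") {
  .check_sorted(query, "query")
  q_all <- .split_alleles(query$alleles)
  keep_acgt <- vapply(q_all, function(a) any(a %in% c("A", "C", "G", "T")),
                      logical(1))
  n_skip <- sum(!keep_acgt)
  if (n_skip) warning(n_skip, " record(s) without any ACGT allele skipped")
  query <- query[keep_acgt, , drop = FALSE]
  q_all <- lapply(q_all[keep_acgt], function(a) a[a %in% c("A", "C", "G", "T")])

  baseline <- lapply(query$ref, identity)          # list of {ref} per record
  if (!is.null(control) && nrow(control)) {
    .check_sorted(control, "control")
    key_q <- paste(query$chrom, query$pos)
    key_c <- paste(control$chrom, control$pos)
    m <- match(key_q, key_c)
    hit <- !is.na(m)
    if (any(hit)) {
      conflict <- query$ref[hit] != control$ref[m[hit]]
      if (any(conflict))
        stop("conflicting ref allele between query and control at ",
             key_q[hit][conflict][1])
      c_all <- .split_alleles(control$alleles[m[hit]])
      baseline[hit] <- Map(function(b, ca) unique(c(b, ca)),
                           baseline[hit], c_all)
    }
  }
  novel <- Map(function(a, b) setdiff(a, b), q_all, baseline)
  has <- lengths(novel) > 0L
  out <- data.frame(chrom = query$chrom[has], pos = query$pos[has],
                    alleles = vapply(novel[has], paste, character(1),
                                     collapse = ","),
                    stringsAsFactors = FALSE)
  structure(out, label = label, n_skipped = n_skip, class = c("ssv_set", "data.frame"))
}

#' @rdname call_ssvs
#' @export
call_ssvs_vs_reference <- function(query, label = "query_vs_ref") {
  call_ssvs(query, control = NULL, label = label)
}

#' @rdname call_ssvs
#' @export
call_ssvs_vs_control <- function(query, control, label = "query_vs_control") {
  call_ssvs(query, control = control, label = label)
}

.split_alleles <- function(x) strsplit(x, ",", fixed = TRUE)

.check_sorted <- function(df, what) {
  if (!nrow(df)) return(invisible())
  o <- order(df$chrom, df$pos)
  if (!identical(o, seq_len(nrow(df))))
    stop(what, " records must be sorted by (chrom, pos)")
  if (anyDuplicated(paste(df$chrom, df$pos)))
    stop(what, " carries duplicated positions")
  invisible()
}

#' @export
print.ssv_set <- function(x, ...) {
  cat("ssv_set '", attr(x, "label"), "': ", nrow(x), " positions\n", sep = "")
  invisible(x)
}

#' Convert an SSV set to GRanges / BED
#'
#' SSVs are written as 0-based half-open single-base intervals with the novel
#' alleles in the name column.
#' @param ssvs an `ssv_set`
#' @return GRanges with an `alleles` metadata column
#' @export
ssvs_to_granges <- function(ssvs) {
  .granges(ssvs$chrom, ssvs$pos - 1, ssvs$pos, alleles = ssvs$alleles)
}

#' @rdname ssvs_to_granges
#' @param path output BED path
#' @export
write_ssv_bed <- function(ssvs, path) {
  o <- order(ssvs$chrom, ssvs$pos)
  write_bed(ssvs_to_granges(ssvs[o, , drop = FALSE]), path)
}

#' @rdname ssvs_to_granges
#' @export
read_ssv_bed <- function(path, label = basename(path)) {
  gr <- read_bed(path, extra_names = "alleles")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    pos = .end0(gr), alleles = S4Vectors::mcols(gr)$alleles,
                    stringsAsFactors = FALSE)
  structure(out, label = label, class = c("ssv_set", "data.frame"))
}
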