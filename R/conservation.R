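#' Annotate cross-species conservation of TF peaks
#'
#' A rat peak is conserved when it overlaps (by at least 1 bp) a peak of the
#' same transcription factor in at least one comparison species; all peak
#' sets must already live in rat coordinates. The supporting species are
#' recorded per peak.
#'
#' @param rat GRanges of rat peaks; needs a `factor` metadata column (one
#'   factor per call) and optionally `species`
#' @param others list of GRanges, one per comparison species, each with
#'   `factor` and `species` metadata columns
#' @return `rat` with logical `conserved` and comma-joined `supporting`
#'   metadata columns added
#' @export
annotate_conservation <- function(rat, others) {
  fac <- unique(S4Vectors::mcols(rat)$factor)
  if (length(fac) > 1) stop("one factor per call; got: ", paste(fac, collapse = ", "))
  supp <- rep("", length(rat))
  for (o in others) {
    ofac <- unique(S4Vectors::mcols(o)$factor)
    if (length(fac) && length(ofac) && !identical(ofac, fac))
      stop("factor mismatch: rat=", fac, " other=", paste(ofac, collapse = ","))
    sp <- unique(S4Vectors::mcols(o)$species)
    if (length(sp) != 1) sp <- "unknown_species"
    hit <- IRanges::overlapsAny(rat, o, minoverlap = 1L)
    supp[hit] <- ifelse(nzchar(supp[hit]), paste(supp[hit], sp, sep = ","), sp)
  }
  S4Vectors::mcols(rat)$conserved <- nzchar(supp)
  S4Vectors::mcols(rat)$supporting <- supp
  rat
}

#' Conservation Enrichment score (CE) of HVRs
#'
#' Per HVR and transcription factor. Two readings are provided and kept as
#' configuration: `density_per_10kb` (the number of conserved peaks of the
#' factor overlapping the HVR per 10 kb of HVR length) and `fraction` (the
#' conserved fraction of all peaks of the factor overlapping the HVR; 0 when
#' no peak overlaps). The default is the density reading.
#'
#' @param hvrs GRanges of HVRs (type == "HVR" rows are used)
#' @param peaks annotated GRanges from [annotate_conservation()]
#' @param mode "density_per_10kb" or "fraction"
#' @return data.frame (hvr_id, factor, mode, n_peaks, n_conserved, value)
#' @export
compute_ce <- function(hvrs, peaks, mode = c("density_per_10kb", "fraction")) {
  mode <- match.arg(mode)
  hvrs <- .hvr_only(hvrs)
  if (any(GenomicRanges::width(hvrs) < 1)) stop("zero-length HVR")
  fac <- unique(S4Vectors::mcols(peaks)$factor)
  if (length(fac) > 1) stop("one factor per call")
  if (!length(fac)) fac <- NA_character_
  if (!length(hvrs))
    return(data.frame(hvr_id = character(), factor = character(),
                      mode = character(), n_peaks = integer(),
                      n_conserved = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  ov <- GenomicRanges::findOverlaps(hvrs, peaks, minoverlap = 1L)
  n_pk <- tabulate(S4Vectors::queryHits(ov), nbins = length(hvrs))
  cons <- S4Vectors::mcols(peaks)$conserved[S4Vectors::subjectHits(ov)]
  n_cons <- tabulate(S4Vectors::queryHits(ov)[cons], nbins = length(hvrs))
  value <- if (mode == "density_per_10kb") {
    n_cons / (GenomicRanges::width(hvrs) / 10000)
  } else {
    ifelse(n_pk > 0, n_cons / n_pk, 0)
  }
  data.frame(hvr_id = .hvr_ids(hvrs), factor = fac, mode = mode,
             n_peaks = n_pk, n_conserved = n_cons, value = value,
             stringsAsFactors = FALSE)
}

.hvr_only <- function(hvrs) {
  ty <- S4Vectors::mcols(hvrs)$type
  if (!is.null(ty)) hvrs <- hvrs[ty == "HVR"]
  hvrs
}

.hvr_ids <- function(hvrs) {
  paste0(GenomicRanges::seqnames(hvrs), ":", .start0(hvrs), "-", .end0(hvrs))
}

#' Build the prioritisation subsets of HVRs
#'
#' The seven CE-based subsets (`ALL`, `W_TFBS` = at least one peak of any
#' factor, and `CE>t` for each threshold, an HVR qualifying when any factor's
#' CE exceeds `t`) plus the factor-count subsets `NTF>=m` (HVRs with at least
#' one conserved peak for at least `m` distinct factors). Subsets are nested
#' by construction.
#'
#' @param hvrs GRanges of HVRs
#' @param ce_tables list of data.frames from [compute_ce()], one per factor
#' @param ce_thresholds numeric CE cutoffs (default 0, 0.2, 0.4, 0.6, 0.8)
#' @param ntf_levels integer factor-count cutoffs (default 1:3)
#' @return named list of character vectors of HVR ids
#' @export
build_subsets <- function(hvrs, ce_tables,
                          ce_thresholds = c(0, 0.2, 0.4, 0.6, 0.8),
                          ntf_levels = 1:3) {
  hvrs <- .hvr_only(hvrs)
  ids <- .hvr_ids(hvrs)
  if (!length(ids)) {
    nm <- c("ALL", "W_TFBS", sprintf("CE>%g", ce_thresholds),
            sprintf("NTF>=%d", ntf_levels))
    return(stats::setNames(rep(list(character(0)), length(nm)), nm))
  }
  ce <- do.call(rbind, ce_tables)
  stopifnot(all(ce$hvr_id %in% ids))
  agg <- function(v, f) stats::aggregate(list(x = v), list(hvr_id = ce$hvr_id), f)
  n_pk <- agg(ce$n_peaks, sum)
  max_ce <- agg(ce$value, max)
  ntf <- stats::aggregate(list(x = ce$n_conserved > 0),
                          list(hvr_id = ce$hvr_id), sum)
  subsets <- list(ALL = ids,
                  W_TFBS = n_pk$hvr_id[n_pk$x > 0])
  for (t in ce_thresholds)
    subsets[[sprintf("CE>%g", t)]] <- max_ce$hvr_id[max_ce$x > t]
  for (m in ntf_levels)
    subsets[[sprintf("NTF>=%d", m)]] <- ntf$hvr_id[ntf$x >= m]
  lapply(subsets, function(s) ids[ids %in% s])   # preserve genomic order
}

#' Proportion of non-synonymous vs synonymous coding SSVs
#'
#' Given most-severe consequence calls for the coding SSVs of a subset,
#' returns the NSC count (missense, stop gained/lost), the SC count
#' (synonymous) and the proportion NSC / (NSC + SC). With no coding SSVs the
#' proportion is NA and `undefined` is TRUE.
#'
#' @param consequences data.frame with a `term` column of most-severe terms
#' @return one-row data.frame (n_nsc, n_sc, prop_nsc, undefined)
#' @export
nsc_sc_ratio <- function(consequences) {
  nsc <- sum(consequences$term %in% c("missense_variant", "stop_gained", "stop_lost"))
  sc <- sum(consequences$term == "synonymous_variant")
  data.frame(n_nsc = nsc, n_sc = sc,
             prop_nsc = if (nsc + sc > 0) nsc / (nsc + sc) else NA_real_,
             undefined = nsc + sc == 0)
}
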