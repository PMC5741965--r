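#' Count SSVs in non-overlapping genome windows
#'
#' Windows tile each chromosome left to right as 0-based half-open intervals
#' `[i*w, (i+1)*w)`; the last window may be short. A 1-based SSV position `p`
#' falls in window `floor((p-1)/w)`.
#'
#' @param ssvs an `ssv_set` (see [call_ssvs()])
#' @param layout a [genome_layout()]
#' @param window_bp window width in bp (default 10 kb)
#' @return a `window_track`: data.frame (chrom, win, start, end, count) with
#'   attribute `window_bp`; `smooth` and `label` columns are added by
#'   [smooth_track()] and [call_regions()]
#' @export
count_ssvs_per_window <- function(ssvs, layout, window_bp = 10000) {
  .stopifnot_layout(layout)
  if (window_bp < 1) stop("window_bp must be positive")
  nwin <- ceiling(unclass(layout) / window_bp)
  track <- do.call(rbind, lapply(names(layout), function(ch) {
    n <- nwin[[ch]]
    data.frame(chrom = ch, win = seq_len(n) - 1L,
               start = (seq_len(n) - 1) * window_bp,
               end = pmin(seq_len(n) * window_bp, unclass(layout)[[ch]]),
               count = 0, stringsAsFactors = FALSE)
  }))
  if (nrow(ssvs)) {
    bad <- !(ssvs$chrom %in% names(layout)) |
      ssvs$pos < 1 | ssvs$pos > unclass(layout)[ssvs$chrom]
    if (any(bad, na.rm = TRUE))
      stop("SSV outside the genome layout: ",
           paste(ssvs$chrom[bad][1], ssvs$pos[bad][1]))
    widx <- floor((ssvs$pos - 1) / window_bp)
    tab <- table(paste(ssvs$chrom, widx))
    m <- match(paste(track$chrom, track$win), names(tab))
    track$count[!is.na(m)] <- as.numeric(tab[m[!is.na(m)]])
  }
  structure(track, window_bp = window_bp, class = c("window_track", "data.frame"))
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track:", nrow(x), "windows of", attr(x, "window_bp"), "bp,",
      sum(x$count), "SSVs\n")
  invisible(x)
}

#' Triangular smoothing of window counts
#'
#' Floating mean with weights `k - |i|` for offsets `i = -k..k` and a fixed
#' denominator `sum(k - |i|) = k^2` (9 for the default k = 3). Windows beyond
#' the chromosome ends contribute 0 (zero padding), so total mass is
#' conserved per chromosome and a constant interior track is a fixed point.
#' Note the weight at `|i| = k` is zero: the kernel effectively spans
#' `2k - 1` windows.
#'
#' @param track a `window_track` from [count_ssvs_per_window()]
#' @param k neighbourhood half-width in windows (default 3)
#' @return the track with a `smooth` column added
#' @export
smooth_track <- function(track, k = 3) {
  if (k < 1) stop("k must be >= 1")
  w <- k - abs(seq(-k, k))
  denom <- sum(w)
  track$smooth <- NA_real_
  for (ix in split(seq_len(nrow(track)), track$chrom)) {
    ix <- ix[order(track$win[ix])]
    cnt <- track$count[ix]
    padded <- c(rep(0, k), cnt, rep(0, k))
    sm <- rep(0, length(cnt))
    for (j in seq(-k, k)) sm <- sm + padded[seq_along(cnt) + k + j] * w[j + k + 1]
    track$smooth[ix] <- sm / denom
  }
  track
}

#' Find the bimodal-valley threshold of smoothed SSV density
#'
#' Bins the genome-wide smoothed densities (unit-width bins by default),
#' locates the two local maxima with the largest counts, and returns the
#' centre of the lowest-count bin strictly between them (ties resolved to the
#' middle tied bin). When no two separated local maxima exist the `override`
#' is returned: the default of 3 variants / 10 kb is the valley observed in
#' all three rat strain-vs-reference comparisons the method was developed on.
#'
#' @param smoothed numeric vector of smoothed densities (genome-wide)
#' @param override fallback threshold when the distribution is not bimodal
#' @param bin_width histogram bin width in variants/window
#' @return threshold `t` (windows with smoothed density > t are HVR-like)
#' @export
find_threshold <- function(smoothed, override = 3, bin_width = 1) {
  if (length(smoothed) < 2) stop("need >= 2 windows")
  bins <- floor(smoothed / bin_width)
  cnt <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  if (length(cnt) < 3) {
    message("smoothed-density distribution not bimodal; using override ", override)
    return(override)
  }
  pad <- c(-Inf, cnt, -Inf)
  is_max <- which(cnt > pad[seq_along(cnt)] & cnt >= pad[seq_along(cnt) + 2L])
  if (length(is_max) < 2) {
    message("smoothed-density distribution not bimodal; using override ", override)
    return(override)
  }
  top2 <- sort(is_max[order(cnt[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1] + 1L, length.out = max(0, top2[2] - top2[1] - 1L))
  if (!length(between)) {
    message("adjacent modes, no valley; using override ", override)
    return(override)
  }
  valley <- between[cnt[between] == min(cnt[between])]
  valley <- valley[ceiling(length(valley) / 2)]
  (valley - 1 + 0.5) * bin_width
}

#' Call unmappable regions from per-window mapping statistics
#'
#' A window is flagged when its mean mapping quality is <= `mapq_max` and/or
#' its mean coverage is >= `cov_min`; runs of at least `min_run` consecutive
#' flagged windows become UNMAP regions (the two criteria combine with OR
#' across the run).
#'
#' @param stats data.frame (chrom, window_index, mean_mapq, mean_coverage)
#'   on the same grid as the window track
#' @param layout a [genome_layout()]
#' @param window_bp window width in bp
#' @param mapq_max,cov_min flag thresholds
#' @param min_run minimum run length in windows
#' @return GRanges of UNMAP regions with `type` and `n_windows` columns
#' @export
detect_unmappable <- function(stats, layout, window_bp = 10000,
                              mapq_max = 30, cov_min = 100, min_run = 3) {
  .stopifnot_layout(layout)
  if (min_run < 1) stop("min_run must be >= 1")
  bad <- !(stats$chrom %in% names(layout)) |
    stats$window_index < 0 |
    stats$window_index >= ceiling(unclass(layout)[stats$chrom] / window_bp)
  if (any(bad, na.rm = TRUE)) stop("window stats off the layout grid")
  flag <- stats$mean_mapq <= mapq_max | stats$mean_coverage >= cov_min
  regs <- do.call(rbind, lapply(split(seq_len(nrow(stats)), stats$chrom),
                                function(ix) {
    ix <- ix[order(stats$window_index[ix])]
    r <- rle(flag[ix])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    data.frame(chrom = stats$chrom[ix[1]],
               win_from = stats$window_index[ix][starts[keep]],
               win_to = stats$window_index[ix][ends[keep]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(regs)) return(.empty_regions())
  gr <- .granges(regs$chrom, regs$win_from * window_bp,
                 pmin((regs$win_to + 1) * window_bp, unclass(layout)[regs$chrom]),
                 type = "UNMAP", n_windows = regs$win_to - regs$win_from + 1L)
  sort(gr)
}

.empty_regions <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(type = character(),
                                               n_windows = integer(),
                                               n_ssvs = integer())
  gr
}

#' Call HVR / LVR regions from a smoothed window track
#'
#' Windows with smoothed density strictly greater than `t` are HVR-like,
#' windows at or below `t` LVR-like; UNMAP windows are excluded and break
#' runs. Maximal same-label runs of at least `min_run` windows become typed
#' regions; shorter runs stay unclassified.
#'
#' @param track a smoothed `window_track`
#' @param t threshold from [find_threshold()]
#' @param min_run minimum run length in windows (default 3)
#' @param unmappable GRanges of UNMAP regions (or NULL)
#' @param layout a [genome_layout()]
#' @return GRanges with `type` (HVR/LVR), `n_windows`, `n_ssvs` columns,
#'   sorted; the UNMAP regions are appended so the result partitions the
#'   classified genome
#' @export
call_regions <- function(track, t, min_run = 3, unmappable = NULL,
                         layout = NULL) {
  if (min_run < 1) stop("min_run must be >= 1")
  if (is.null(track$smooth)) stop("run smooth_track() first")
  window_bp <- attr(track, "window_bp")
  lab <- ifelse(track$smooth > t, "H", "L")
  if (!is.null(unmappable) && length(unmappable)) {
    win_gr <- .granges(track$chrom, track$start, track$end)
    hit <- IRanges::overlapsAny(win_gr, unmappable, minoverlap = 1L)
    lab[hit] <- "U"
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(track)), track$chrom),
                               function(ix) {
    ix <- ix[order(track$win[ix])]
    r <- rle(lab[ix])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values %in% c("H", "L") & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    data.frame(chrom = track$chrom[ix[1]],
               start = track$start[ix][starts[keep]],
               end = track$end[ix][ends[keep]],
               type = ifelse(r$values[keep] == "H", "HVR", "LVR"),
               n_windows = r$lengths[keep],
               n_ssvs = vapply(which(keep), function(j)
                 sum(track$count[ix][starts[j]:ends[j]]), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  gr <- if (is.null(out)) .empty_regions()
        else .granges(out$chrom, out$start, out$end, type = out$type,
                      n_windows = out$n_windows, n_ssvs = out$n_ssvs)
  if (!is.null(unmappable) && length(unmappable)) {
    um <- unmappable
    if (is.null(S4Vectors::mcols(um)$n_ssvs)) S4Vectors::mcols(um)$n_ssvs <- NA_integer_
    gr <- c(gr, um[, c("type", "n_windows", "n_ssvs")])
  }
  sort(gr)
}

#' Descriptive summary of a comparison (Table-1 style)
#'
#' Totals of SSVs, SSVs falling in HVRs (with percentage), HVR count, and
#' total HVR size in bp (with percentage of the genome). Percentages are
#' rounded to 2 decimals; a zero SSV total is reported as 0 with
#' `undefined_pct = TRUE`.
#'
#' @param ssvs an `ssv_set`
#' @param regions GRanges from [call_regions()]
#' @param layout a [genome_layout()]
#' @return one-row data.frame
#' @export
summarize_comparison <- function(ssvs, regions, layout) {
  .stopifnot_layout(layout)
  hvr <- regions[S4Vectors::mcols(regions)$type == "HVR"]
  total <- nrow(ssvs)
  in_hvr <- if (total) sum(IRanges::overlapsAny(ssvs_to_granges(ssvs), hvr)) else 0
  hvr_bp <- sum(GenomicRanges::width(hvr))
  data.frame(
    label = attr(ssvs, "label") %||% "comparison",
    total_ssvs = total,
    ssvs_in_hvrs = in_hvr,
    pct_ssvs_in_hvrs = if (total) pct(in_hvr, total) else 0,
    n_hvrs = length(hvr),
    hvr_bp = hvr_bp,
    pct_genome_hvr = pct(hvr_bp, sum(unclass(layout))),
    undefined_pct = total == 0,
    stringsAsFactors = FALSE)
}

#' Fraction of one HVR set overlapping another
#'
#' Fraction of regions in `a` that intersect at least one region in `b`
#' (each region counted once); the pair of fractions for the two comparisons
#' is not symmetric in general.
#' @param a,b GRanges of HVRs
#' @return fraction in `[0, 1]`
#' @export
hvr_overlap_fraction <- function(a, b) {
  if (!length(a)) return(NA_real_)
  mean(IRanges::overlapsAny(a, b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
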