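#' Cluster HVRs within a maximum gap
#'
#' Single-linkage merge per chromosome: consecutive HVRs separated by at most
#' `max_gap` bp join one cluster. Clusters are permuted as rigid units so the
#' local structure of nearby, regulatorily non-independent HVRs is preserved
#' under the null.
#'
#' @param hvrs GRanges of HVRs (sorted, non-overlapping)
#' @param max_gap maximum within-cluster gap in bp (default 1 Mb)
#' @return an `hvr_clusters` object: list with `spans` (GRanges of cluster
#'   spans) and `members` (per cluster, matrix of member start offsets and
#'   widths relative to the span start)
#' @export
cluster_hvrs <- function(hvrs, max_gap = 1e6) {
  hvrs <- .hvr_only(hvrs)
  hvrs <- sort(GenomeInfoDb::sortSeqlevels(hvrs))
  if (length(GenomicRanges::reduce(hvrs)) != length(hvrs))
    stop("HVRs must be non-overlapping")
  spans <- GenomicRanges::reduce(hvrs, min.gapwidth = max_gap + 1)
  ov <- GenomicRanges::findOverlaps(hvrs, spans)
  members <- lapply(seq_along(spans), function(ci) {
    m <- hvrs[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == ci]]
    cbind(offset = .start0(m) - .start0(spans[ci]),
          width = GenomicRanges::width(m))
  })
  structure(list(spans = spans, members = members), class = "hvr_clusters")
}

#' @export
print.hvr_clusters <- function(x, ...) {
  cat("hvr_clusters:", length(x$spans), "clusters,",
      sum(vapply(x$members, nrow, integer(1))), "HVRs\n")
  invisible(x)
}

#' Randomly relocate HVR clusters across the genome
#'
#' Each cluster is placed on a chromosome drawn with probability proportional
#' to chromosome length among chromosomes long enough to contain the cluster
#' span, at a start uniform over the valid positions; member HVR offsets
#' within the cluster are preserved. Relocated clusters may overlap each
#' other and may land anywhere (no exclusion mask by default), mirroring
#' plain whole-genome shuffling. Uses the current RNG state.
#'
#' @param clusters an `hvr_clusters` object
#' @param layout a [genome_layout()]
#' @param exclude optional GRanges mask; placements overlapping it are
#'   rejection-sampled away (off by default)
#' @return GRanges of relocated HVRs
#' @export
shuffle_clusters <- function(clusters, layout, exclude = NULL) {
  .stopifnot_layout(layout)
  pl <- .shuffle_once(.prep_clusters(clusters), unclass(layout), exclude)
  .granges(pl$chrom, pl$start, pl$end)
}

# internal compact cluster form: span widths + member offset/width matrices
.prep_clusters <- function(clusters) {
  list(width = GenomicRanges::width(clusters$spans),
       members = clusters$members)
}

.shuffle_once <- function(pc, lens, exclude = NULL, chrom_idx = NULL, starts = NULL) {
  nms <- names(lens)
  n <- length(pc$width)
  if (is.null(chrom_idx)) {
    chrom_idx <- integer(n); starts <- numeric(n)
    for (ci in seq_len(n)) {
      feas <- which(lens >= pc$width[ci])
      if (!length(feas)) stop("cluster longer than every chromosome")
      k <- if (length(feas) == 1) feas else
        feas[sample.int(length(feas), 1, prob = lens[feas])]
      chrom_idx[ci] <- k
      starts[ci] <- floor(stats::runif(1) * (lens[k] - pc$width[ci] + 1))
    }
  }
  chrom <- character(0); s0 <- numeric(0); e0 <- numeric(0)
  for (ci in seq_len(n)) {
    m <- pc$members[[ci]]
    chrom <- c(chrom, rep(nms[chrom_idx[ci]], nrow(m)))
    s0 <- c(s0, starts[ci] + m[, "offset"])
    e0 <- c(e0, starts[ci] + m[, "offset"] + m[, "width"])
  }
  if (!is.null(exclude) && length(exclude)) {
    gr <- .granges(chrom, s0, e0)
    if (any(IRanges::overlapsAny(gr, exclude)))
      return(.shuffle_once(pc, lens, exclude))
  }
  list(chrom = chrom, start = s0, end = e0)
}

#' Overlap statistic between a region set and genomic elements
#'
#' Three modes: `n_elements_overlapping` counts elements intersecting at
#' least one region (each element once, however many regions it spans);
#' `n_points_in` counts point elements falling inside regions (each point
#' once); `mean_score` averages the `score` metadata column over elements
#' intersecting at least one region (NA with attribute `undefined` when no
#' element intersects).
#'
#' @param regions GRanges
#' @param elements GRanges (with a `score` column for `mean_score`)
#' @param mode statistic mode
#' @return numeric scalar
#' @export
overlap_statistic <- function(regions, elements,
                              mode = c("n_elements_overlapping", "n_points_in",
                                       "mean_score")) {
  mode <- match.arg(mode)
  el <- .prep_elements(elements, mode)
  .stat_fast(as.character(GenomicRanges::seqnames(regions)),
             .start0(regions), .end0(regions), el, mode)
}

# internal: per-chromosome sorted element arrays
.prep_elements <- function(elements, mode) {
  ch <- as.character(GenomicRanges::seqnames(elements))
  s <- .start0(elements); e <- .end0(elements)
  sc <- S4Vectors::mcols(elements)$score
  if (mode == "mean_score" && is.null(sc))
    stop("mean_score needs a 'score' metadata column")
  if (is.null(sc)) sc <- rep(NA_real_, length(elements))
  out <- list()
  for (c1 in unique(ch)) {
    i <- which(ch == c1); o <- order(s[i]); i <- i[o]
    out[[c1]] <- list(start = s[i], end = e[i], score = sc[i])
  }
  out
}

# regions as plain vectors against prepped elements; union semantics
.stat_fast <- function(rchrom, rs, re, el, mode) {
  if (mode == "n_points_in") {
    total <- 0
    for (c1 in unique(rchrom)) {
      p <- el[[c1]]$start
      if (is.null(p) || !length(p)) next
      i <- rchrom == c1
      lo <- findInterval(rs[i] - 0.5, p)     # points < start
      hi <- findInterval(re[i] - 0.5, p)     # points < end
      total <- total + .count_union_ranges(lo, hi)
    }
    return(total)
  }
  hit_scores <- numeric(0); n_hit <- 0
  for (c1 in unique(rchrom)) {
    e1 <- el[[c1]]
    if (is.null(e1) || !length(e1$start)) next
    i <- which(rchrom == c1)
    marked <- rep(FALSE, length(e1$start))
    for (j in i) {
      upto <- findInterval(re[j] - 0.5, e1$start)   # elements with start < end_j
      if (upto < 1) next
      idx <- seq_len(upto)
      marked[idx] <- marked[idx] | e1$end[idx] > rs[j]
    }
    n_hit <- n_hit + sum(marked)
    if (mode == "mean_score") hit_scores <- c(hit_scores, e1$score[marked])
  }
  if (mode == "mean_score") {
    if (!n_hit) return(structure(NA_real_, undefined = TRUE))
    return(mean(hit_scores))
  }
  n_hit
}

# union size of half-open index ranges (lo, hi]
.count_union_ranges <- function(lo, hi) {
  keep <- hi > lo
  if (!any(keep)) return(0)
  lo <- lo[keep]; hi <- hi[keep]
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] >= cur_hi) {
      total <- total + cur_hi - cur_lo
      cur_lo <- lo[k]; cur_hi <- hi[k]
    } else cur_hi <- max(cur_hi, hi[k])
  }
  total + cur_hi - cur_lo
}

#' Two-tailed empirical p-value of a permutation test
#'
#' `p = (card(|EV - mean(EV)| >= |OV - mean(EV)|) + 1) / (N + 1)`, centred on
#' the mean of the null sample; the smallest attainable value is
#' `1 / (N + 1)` (1e-4 to one significant figure at N = 10,000).
#'
#' @param ov observed value
#' @param ev numeric vector of N permuted values
#' @return empirical two-tailed p
#' @export
empirical_pvalue <- function(ov, ev) {
  m <- mean(ev)
  (sum(abs(ev - m) >= abs(ov - m)) + 1) / (length(ev) + 1)
}

#' Cluster-preserving permutation test of HVR enrichment
#'
#' Observed statistic on the real HVRs versus the statistic on `N` random
#' relocations of the HVR clusters ([cluster_hvrs()], [shuffle_clusters()]);
#' significance by the two-tailed empirical p-value of [empirical_pvalue()].
#' All placement randomness is drawn up front from a single seeded stream, so
#' the null sample is reproducible and independent of evaluation order.
#'
#' @param hvrs GRanges of HVRs
#' @param elements GRanges of genomic elements
#' @param layout a [genome_layout()]
#' @param mode statistic mode, see [overlap_statistic()]
#' @param N number of permutations (default 10,000)
#' @param max_gap clustering distance in bp (default 1 Mb)
#' @param seed integer seed (NULL leaves the RNG state alone)
#' @param exclude optional exclusion mask passed to the shuffler
#' @return a `permutation_result`: list(observed, null (length N), mean_null,
#'   p_value, N, mode, seed)
#' @export
permutation_test <- function(hvrs, elements, layout,
                             mode = c("n_elements_overlapping", "n_points_in",
                                      "mean_score"),
                             N = 10000, max_gap = 1e6, seed = NULL,
                             exclude = NULL) {
  mode <- match.arg(mode)
  if (N < 1) stop("N must be >= 1")
  .stopifnot_layout(layout)
  hvrs <- .hvr_only(hvrs)
  el <- .prep_elements(elements, mode)
  ov <- .stat_fast(as.character(GenomicRanges::seqnames(hvrs)),
                   .start0(hvrs), .end0(hvrs), el, mode)
  pc <- .prep_clusters(cluster_hvrs(hvrs, max_gap))
  lens <- unclass(layout)
  if (!is.null(seed)) set.seed(seed)
  nC <- length(pc$width)
  # pre-draw all placements: chromosome index and start per cluster x permutation
  chrom_mat <- matrix(0L, N, nC)
  start_mat <- matrix(0, N, nC)
  for (ci in seq_len(nC)) {
    feas <- which(lens >= pc$width[ci])
    if (!length(feas)) stop("cluster longer than every chromosome")
    ks <- if (length(feas) == 1) rep(feas, N) else
      feas[sample.int(length(feas), N, replace = TRUE, prob = lens[feas])]
    chrom_mat[, ci] <- ks
    start_mat[, ci] <- floor(stats::runif(N) * (lens[ks] - pc$width[ci] + 1))
  }
  nms <- names(lens)
  # flatten member offsets once
  mem_cluster <- rep(seq_len(nC), vapply(pc$members, nrow, integer(1)))
  mem_off <- unlist(lapply(pc$members, function(m) m[, "offset"]))
  mem_w <- unlist(lapply(pc$members, function(m) m[, "width"]))
  ev <- numeric(N)
  use_exclude <- !is.null(exclude) && length(exclude)
  for (i in seq_len(N)) {
    if (use_exclude) {
      pl <- .shuffle_once(pc, lens, exclude,
                          chrom_idx = chrom_mat[i, ], starts = start_mat[i, ])
      rchrom <- pl$chrom; rs <- pl$start; re <- pl$end
    } else {
      rs <- start_mat[i, mem_cluster] + mem_off
      re <- rs + mem_w
      rchrom <- nms[chrom_mat[i, mem_cluster]]
    }
    ev[i] <- .stat_fast(rchrom, rs, re, el, mode)
  }
  if (mode == "mean_score" && anyNA(ev)) {
    warning(sum(is.na(ev)), " permutation(s) with no intersecting element; ",
            "treated as mean 0")
    ev[is.na(ev)] <- 0
  }
  structure(list(observed = as.numeric(ov), null = ev, mean_null = mean(ev),
                 p_value = empirical_pvalue(ov, ev), N = N, mode = mode,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: OV = %.4g, mean(EV) = %.4g, N = %d, p = %.4g\n",
              x$observed, x$mean_null, x$N, x$p_value))
  invisible(x)
}

#' Write a permutation result as JSON (optionally with the full null sample)
#' @param res a `permutation_result`
#' @param path output JSON path
#' @param null_tsv optional path for the full EV sample as TSV
#' @export
write_permutation_result <- function(res, path, null_tsv = NULL) {
  jsonlite::write_json(list(observed = res$observed, mean_null = res$mean_null,
                            p_value = res$p_value, N = res$N, mode = res$mode,
                            seed = res$seed),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(null_tsv)) .write_tsv(data.frame(ev = res$null), null_tsv)
  invisible(path)
}
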