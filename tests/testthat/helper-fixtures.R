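# Shared builders and brute-force oracles. Oracles deliberately use naive
# double loops / exhaustive enumeration, independent of the package's
# implementation paths.

gr <- function(chrom, start0, end0, ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(g)[names(mc)] <- mc
  g
}

tiny_layout <- function(...) {
  v <- c(...)
  if (!length(v)) v <- c(chr1 = 1e6)
  genome_layout(v)
}

variant_df <- function(chrom, pos, ref, alleles, zygosity = "hom") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alleles = alleles,
             zygosity = zygosity, stringsAsFactors = FALSE)
}

ssv_df <- function(chrom, pos, alleles = "A", label = "test") {
  structure(data.frame(chrom = chrom, pos = pos,
                       alleles = rep_len(alleles, length(chrom)),
                       stringsAsFactors = FALSE),
            label = label, class = c("ssv_set", "data.frame"))
}

# O(n*m) overlap oracle: which elements intersect >= 1 region (half-open)
oracle_elements_overlapping <- function(rch, rs, re, ech, es, ee) {
  hit <- rep(FALSE, length(es))
  for (i in seq_along(es))
    for (j in seq_along(rs))
      if (ech[i] == rch[j] && es[i] < re[j] && ee[i] > rs[j]) hit[i] <- TRUE
  sum(hit)
}

# gap-merge oracle for cluster_hvrs
oracle_clusters <- function(ch, s, e, max_gap) {
  o <- order(ch, s)
  ch <- ch[o]; s <- s[o]; e <- e[o]
  cl <- integer(length(s)); cur <- 0
  for (i in seq_along(s)) {
    if (i == 1 || ch[i] != ch[i - 1] || s[i] - e[i - 1] > max_gap) cur <- cur + 1
    cl[i] <- cur
  }
  cl
}

# exact two-sided Fisher p by hypergeometric enumeration
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

expect_granges_equal <- function(a, b) {
  expect_equal(as.character(GenomicRanges::seqnames(a)),
               as.character(GenomicRanges::seqnames(b)))
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
}

# one small simulated bundle shared across test files (built once per run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "hvrscan_shared_sim")
      cfg <- simulation_config(seed = 110, n_chromosomes = 2,
                               chrom_length_bp = 5e6, n_genes = 150,
                               n_promoters = 120, n_gwas_points = 80)
      cache <<- suppressWarnings(simulate_dataset(cfg, dir))
    }
    cache
  }
})
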