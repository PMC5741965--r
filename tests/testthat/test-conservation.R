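# Peak conservation annotation, CE scoring, subset construction.

test_that("conservation = >=1 bp overlap with >=1 same-factor peak elsewhere", {
  rat <- gr("chr1", 100, 200, factor = "CEBPA", name = "p1")
  one_bp <- list(gr("chr1", 199, 300, factor = "CEBPA", species = "mus1"))
  ann <- annotate_conservation(rat, one_bp)
  expect_true(S4Vectors::mcols(ann)$conserved)
  expect_equal(S4Vectors::mcols(ann)$supporting, "mus1")
  # disjoint half-open intervals: [100,200) vs [200,...) do not touch
  disj <- list(gr("chr1", 200, 300, factor = "CEBPA", species = "mus1"))
  expect_false(S4Vectors::mcols(annotate_conservation(rat, disj))$conserved)
  # same peak in five species: conserved with 5 supporters
  five <- lapply(paste0("sp", 1:5), function(s)
    gr("chr1", 100, 200, factor = "CEBPA", species = s))
  ann5 <- annotate_conservation(rat, five)
  expect_equal(length(strsplit(S4Vectors::mcols(ann5)$supporting, ",")[[1]]), 5)
  expect_error(annotate_conservation(rat,
    list(gr("chr1", 100, 200, factor = "FOXA1", species = "m"))), "mismatch")
})

test_that("annotation is invariant under species order and interval permutation", {
  set.seed(3)
  rat <- gr("chr1", seq(0, 9000, 1000), seq(400, 9400, 1000), factor = "F")
  o1 <- gr("chr1", c(350, 5100), c(600, 5300), factor = "F", species = "a")
  o2 <- gr("chr1", 8000, 8200, factor = "F", species = "b")
  c12 <- S4Vectors::mcols(annotate_conservation(rat, list(o1, o2)))$conserved
  c21 <- S4Vectors::mcols(annotate_conservation(rat, list(o2, o1)))$conserved
  expect_equal(c12, c21)
  perm <- sample(length(rat))
  cp <- S4Vectors::mcols(annotate_conservation(rat[perm], list(o1, o2)))$conserved
  expect_equal(cp, c12[perm])
})

make_annotated <- function(chrom, s, e, conserved, factor = "CEBPA") {
  g <- gr(chrom, s, e, factor = factor)
  S4Vectors::mcols(g)$conserved <- conserved
  S4Vectors::mcols(g)$supporting <- ifelse(conserved, "mus1", "")
  g
}

test_that("CE density and fraction modes agree with direct counting", {
  hvr <- gr("chr1", 0, 30000, type = "HVR")
  pk <- make_annotated("chr1", c(1000, 11000, 21000), c(1400, 11400, 21400),
                       rep(TRUE, 3))
  expect_equal(compute_ce(hvr, pk, "density_per_10kb")$value, 1.0)
  pk6 <- make_annotated("chr1", seq(1000, 26000, 5000), seq(1400, 26400, 5000),
                        rep(c(TRUE, FALSE), 3))
  expect_equal(compute_ce(hvr, pk6, "fraction")$value, 0.5)
  none <- make_annotated("chr1", 500000, 500400, TRUE)
  expect_equal(compute_ce(hvr, none, "density_per_10kb")$value, 0)
  expect_equal(compute_ce(hvr, none, "fraction")$value, 0)
  # peak straddling the HVR boundary counts once
  str1 <- make_annotated("chr1", 29900, 30400, TRUE)
  expect_equal(compute_ce(hvr, str1, "density_per_10kb")$n_conserved, 1)
})

test_that("subset construction follows the criteria and nests", {
  hvrs <- gr("chr1", c(0, 40000, 80000), c(30000, 70000, 110000), type = "HVR")
  mk <- function(s, conserved, factor)
    make_annotated("chr1", s, s + 400, conserved, factor)
  # HVR1: conserved CEBPA + FOXA1; HVR2: CEBPA peak unconserved; HVR3: none
  ce_tabs <- list(
    compute_ce(hvrs, c(mk(1000, TRUE, "CEBPA"), mk(50000, FALSE, "CEBPA")), "fraction"),
    compute_ce(hvrs, mk(2000, TRUE, "FOXA1"), "fraction"),
    compute_ce(hvrs, mk(3000, FALSE, "HNF4A"), "fraction"))
  subs <- build_subsets(hvrs, ce_tabs)
  ids <- subs$ALL
  expect_equal(length(ids), 3)
  expect_equal(subs$W_TFBS, ids[1:2])
  expect_equal(subs[["CE>0"]], ids[1])
  expect_equal(subs[["NTF>=1"]], ids[1])
  expect_equal(subs[["NTF>=2"]], ids[1])   # CEBPA + FOXA1 conserved
  expect_equal(subs[["NTF>=3"]], character(0))
  # nesting invariants
  for (i in 2:5) expect_true(all(subs[[sprintf("CE>%g", c(0.2, 0.4, 0.6, 0.8)[i - 1])]]
                                 %in% subs[["CE>0"]]))
  expect_true(all(subs[["CE>0"]] %in% subs$W_TFBS))
  expect_true(all(subs[["NTF>=3"]] %in% subs[["NTF>=2"]]))
  expect_true(all(subs[["NTF>=2"]] %in% subs[["NTF>=1"]]))
})

test_that("all-conserved peaks force CE>0 subset equal to W_TFBS; empty peaks empty it", {
  hvrs <- gr("chr1", c(0, 40000), c(30000, 70000), type = "HVR")
  all_cons <- compute_ce(hvrs, make_annotated("chr1", c(1000, 41000),
                                              c(1400, 41400), c(TRUE, TRUE)),
                         "fraction")
  subs <- build_subsets(hvrs, list(all_cons))
  expect_equal(subs[["CE>0"]], subs$W_TFBS)
  empty_ce <- compute_ce(hvrs, make_annotated(character(), numeric(), numeric(),
                                              logical()), "fraction")
  subs0 <- build_subsets(hvrs, list(empty_ce))
  expect_equal(subs0$W_TFBS, character(0))
  expect_equal(subs0[["CE>0"]], character(0))
  expect_equal(length(subs0$ALL), 2)
})

test_that("subset nesting holds on simulated data", {
  sim <- shared_sim()
  layout <- read_chrom_sizes(sim$paths$chrom_sizes)
  ssv <- call_ssvs_vs_reference(read_minimal_vcf(sim$paths$vcf[["Q1"]]))
  tr <- smooth_track(count_ssvs_per_window(ssv, layout), 3)
  regs <- call_regions(tr, find_threshold(tr$smooth), layout = layout)
  hvrs <- regs[S4Vectors::mcols(regs)$type == "HVR"]
  ce_tabs <- lapply(names(sim$paths$peaks), function(f) {
    ps <- sim$paths$peaks[[f]]
    rat <- read_bed(ps[["rat"]], extra_names = "name")
    S4Vectors::mcols(rat)$factor <- f
    others <- lapply(setdiff(names(ps), "rat"), function(sp) {
      g <- read_bed(ps[[sp]], extra_names = "name")
      S4Vectors::mcols(g)$factor <- f; S4Vectors::mcols(g)$species <- sp
      g
    })
    compute_ce(hvrs, annotate_conservation(rat, others), "fraction")
  })
  subs <- build_subsets(hvrs, ce_tabs)
  sizes <- lengths(subs)
  expect_true(all(diff(sizes[c("ALL", "W_TFBS", "CE>0", "CE>0.2", "CE>0.4",
                               "CE>0.6", "CE>0.8")]) <= 0))
  expect_true(all(diff(sizes[c("NTF>=1", "NTF>=2", "NTF>=3")]) <= 0))
})

test_that("fraction-mode CE recovers the planted conservation probability", {
  # one factor, many blocks with a single planted probability
  dir <- file.path(tempdir(), "hvrscan_consprob")
  cfg <- simulation_config(seed = 77, n_chromosomes = 3, chrom_length_bp = 5e6,
                           conservation_prob_by_block = 0.7,
                           peaks_per_high_block = 8, background_peaks_per_mb = 0,
                           n_genes = 20, n_promoters = 10, n_gwas_points = 10)
  sim <- suppressWarnings(simulate_dataset(cfg, dir))
  layout <- read_chrom_sizes(sim$paths$chrom_sizes)
  ssv <- call_ssvs_vs_reference(read_minimal_vcf(sim$paths$vcf[["Q1"]]))
  tr <- smooth_track(count_ssvs_per_window(ssv, layout), 3)
  regs <- call_regions(tr, find_threshold(tr$smooth), layout = layout)
  hvrs <- regs[S4Vectors::mcols(regs)$type == "HVR"]
  ps <- sim$paths$peaks[["CEBPA"]]
  rat <- read_bed(ps[["rat"]], extra_names = "name")
  S4Vectors::mcols(rat)$factor <- "CEBPA"
  others <- lapply(setdiff(names(ps), "rat"), function(sp) {
    g <- read_bed(ps[[sp]], extra_names = "name")
    S4Vectors::mcols(g)$factor <- "CEBPA"; S4Vectors::mcols(g)$species <- sp
    g
  })
  ce <- compute_ce(hvrs, annotate_conservation(rat, others), "fraction")
  ce <- ce[ce$n_peaks > 0, ]
  # mean conserved fraction weighted by peak count ~ planted p
  phat <- sum(ce$n_conserved) / sum(ce$n_peaks)
  se <- sqrt(0.7 * 0.3 / sum(ce$n_peaks))
  expect_lt(abs(phat - 0.7), 3 * se)
})

test_that("NSC/SC proportions are computed and flagged when undefined", {
  cons <- data.frame(term = c(rep("missense_variant", 8), rep("stop_gained", 2),
                              rep("synonymous_variant", 30), rep("non_coding", 5)))
  r <- nsc_sc_ratio(cons)
  expect_equal(r$n_nsc, 10)
  expect_equal(r$n_sc, 30)
  expect_equal(r$prop_nsc, 0.25)
  expect_false(r$undefined)
  r0 <- nsc_sc_ratio(data.frame(term = rep("non_coding", 4)))
  expect_true(r0$undefined)
  expect_true(is.na(r0$prop_nsc))
})
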