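# Expression filter, promoter assignment, consequence classifier, orthology,
# Fisher enrichment.

test_that("expression filter is strictly greater than the cutoff", {
  ex <- data.frame(gene_id = c("g1", "g2", "g3"), tissue = "liver",
                   fpkm = c(1.0, 1.01, 0.2))
  expect_equal(expressed_genes(ex), "g2")
  expect_equal(expressed_genes(ex[0, ]), character(0))
  expect_error(expressed_genes(data.frame(gene_id = "g", fpkm = -1)), "negative")
})

test_that("promoter assignment boundaries match exhaustive enumeration", {
  prom <- gr("chr1", 10000, 12000, name = "P1")
  mk_gene <- function(tss, strand)
    data.frame(gene_id = "g", chrom = "chr1", strand = strand, tss = tss)
  # + strand: candidate iff TSS in [10000, 12000) or in [12000, 12000+5000)
  for (tss in c(9999, 10000, 11999, 12000, 16999, 17000, 20000)) {
    got <- nrow(assign_promoters(prom, mk_gene(tss, "+")))
    want <- as.integer((tss >= 10000 && tss < 12000) ||
                       (tss >= 12000 && tss < 17000))
    expect_equal(got, want, info = paste("+", tss))
  }
  # spec worked boundaries: promoter.end + 4999 assigned
  expect_equal(nrow(assign_promoters(prom, mk_gene(12000 + 4999, "+"))), 1)
  expect_equal(nrow(assign_promoters(prom, mk_gene(12000 + 5000, "+"))), 0)
  # - strand: downstream lies before the promoter start
  for (tss in c(4998, 4999, 5000, 9999, 10000, 11999, 12000)) {
    got <- nrow(assign_promoters(prom, mk_gene(tss, "-")))
    want <- as.integer((tss >= 10000 && tss < 12000) ||
                       (tss < 10000 && tss >= 5000))
    expect_equal(got, want, info = paste("-", tss))
  }
  expect_equal(nrow(assign_promoters(prom, mk_gene(10000 - 5000, "-"))), 1)
  expect_equal(nrow(assign_promoters(prom, mk_gene(10000 - 5001, "-"))), 0)
  # a + strand gene downstream-of-start is NOT assigned when stranded
  expect_equal(nrow(assign_promoters(prom, mk_gene(6000, "+"))), 0)
  expect_equal(nrow(assign_promoters(prom, mk_gene(6000, "+"), stranded = FALSE)), 1)
})

test_that("one-to-one rule drops every ambiguous pair", {
  proms <- gr("chr1", c(10000, 40000), c(12000, 42000), name = c("P1", "P2"))
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      strand = "+", tss = c(12100, 12200, 40100))
  out <- assign_promoters(proms, genes)
  expect_equal(out$promoter_id, "P2")          # P1 near two TSSs: all dropped
  expect_equal(out$gene_id, "gC")
  # one gene near two promoters is dropped too
  proms2 <- gr("chr1", c(10000, 13000), c(12000, 15000), name = c("P1", "P2"))
  genes2 <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+", tss = 14000)
  expect_equal(nrow(assign_promoters(proms2, genes2)), 0)
})

test_that("promoter assignment is strand-symmetric under coordinate reflection", {
  L <- 1e6
  set.seed(13)
  ps <- sample(0:900000, 15)
  proms <- gr("chr1", ps, ps + 1500, name = sprintf("P%02d", 1:15))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                      strand = sample(c("+", "-"), 20, TRUE),
                      tss = sample(0:999000, 20))
  fwd <- assign_promoters(proms, genes)
  # reflect: x -> L-1-x; intervals [s,e) -> [L-e, L-s); strands flip
  r_proms <- gr("chr1", L - (ps + 1500), L - ps, name = sprintf("P%02d", 1:15))
  r_genes <- transform(genes, tss = L - 1 - tss,
                       strand = ifelse(strand == "+", "-", "+"))
  rev <- assign_promoters(r_proms, r_genes)
  expect_setequal(paste(fwd$promoter_id, fwd$gene_id),
                  paste(rev$promoter_id, rev$gene_id))
})

test_that("codon consequences agree with Biostrings on all 576 substitutions", {
  skip_if_not_installed("Biostrings")
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (codon in names(code)) {
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(codon, pos, pos))) {
        new <- codon
        substr(new, pos, pos) <- alt
        aa_old <- code[[codon]]; aa_new <- code[[new]]
        want <- if (aa_old != "*" && aa_new == "*") "stop_gained"
                else if (aa_old == "*" && aa_new != "*") "stop_lost"
                else if (aa_old == aa_new) "synonymous_variant"
                else "missense_variant"
        expect_equal(codon_consequence(codon, pos, alt), want,
                     info = paste(codon, pos, alt))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 576)
})

test_that("worked codon examples classify as expected", {
  expect_equal(codon_consequence("TAC", 3, "A"), "stop_gained")   # TAC->TAA
  expect_equal(codon_consequence("CTT", 3, "C"), "synonymous_variant")
  expect_equal(codon_consequence("TAA", 3, "C"), "stop_lost")   # TAA->TAC
  expect_equal(codon_consequence("TAA", 1, "G"), "stop_lost")   # TAA->GAA
  expect_equal(codon_consequence("TAA", 3, "G"), "synonymous_variant")  # stop->stop
})

test_that("genomic classification handles strand, splicing and introns", {
  # + strand gene, CDS = ATG TAC GGG TAA split over two exons
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 100)
  genes$exons <- list(cbind(start = c(100, 500), end = c(106, 506)))
  genes$cds <- list(cbind(start = c(100, 500), end = c(106, 506)))
  genes$cds_seq <- "ATGTACGGGTAA"
  # genomic pos 506 (1-based) = CDS offset 11 -> codon 4 (TAA) pos 3;
  # alt G gives TAG, stop to stop: synonymous
  expect_equal(classify_consequence(ssv_df("chr1", 506, "G"), genes)$term,
               "synonymous_variant")
  # pos 106 (1-based) is CDS offset 5: codon 2 (TAC) pos 3; C->A gives TAA
  out <- classify_consequence(ssv_df("chr1", 106, "A"), genes)
  expect_equal(out$term, "stop_gained")
  expect_equal(out$gene_id, "g1")
  # intronic position
  expect_equal(classify_consequence(ssv_df("chr1", 300, "A"), genes)$term,
               "non_coding")
  # - strand gene over genomic [200, 212), cds_seq in translation order:
  # translation starts at 0-based 211; genomic 0-based 209 is CDS offset 2,
  # codon 1 (ATG) pos 3; genomic alt T reads A on the transcript: ATG->ATA
  gm <- data.frame(gene_id = "g2", chrom = "chr1", strand = "-", tss = 211)
  gm$exons <- list(cbind(start = 200, end = 212))
  gm$cds <- list(cbind(start = 200, end = 212))
  gm$cds_seq <- "ATGTACGGGTAA"
  expect_equal(classify_consequence(ssv_df("chr1", 210, "T"), gm)$term,
               "missense_variant")
  # genomic alt C reads G, equal to the transcript base: no consequence
  expect_equal(classify_consequence(ssv_df("chr1", 210, "C"), gm)$term,
               "non_coding")
})

test_that("most severe consequence across transcripts is retained", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      tss = c(100, 100))
  genes$exons <- list(cbind(start = 100, end = 112), cbind(start = 100, end = 112))
  genes$cds <- list(cbind(start = 100, end = 112), cbind(start = 100, end = 112))
  genes$cds_seq <- c("ATGCTTGGGTAA", "ATGTATGGGTAA")
  # CDS offset 5, codon 2 pos 3, alt A: g1 CTT->CTA synonymous (Leu),
  # g2 TAT->TAA stop_gained; the stop gain wins
  out <- classify_consequence(ssv_df("chr1", 106, "A"), genes)
  expect_equal(out$term, "stop_gained")
  expect_equal(out$gene_id, "g2")
})

test_that("orthologue filter keeps one2one classes and drops the rest", {
  orth <- data.frame(rat_id = c("r1", "r2", "r3", "r4", "r4"),
                     human_id = c("h1", "h2", "h3", "h4a", "h4b"),
                     class = c("one2one", "apparently_one2one", "other",
                               "one2one", "one2one"))
  out <- orthologue_filter(c("r1", "r2", "r3", "r4", "r5"), orth)
  expect_setequal(as.character(out), c("h1", "h2"))   # r3 class other, r4 ambiguous
  expect_equal(attr(out, "n_dropped"), 3)
})

test_that("Fisher enrichment reproduces the hypergeometric oracle and worked numbers", {
  r <- fisher_enrichment_2x2(2, 3, 4, 6)
  expect_equal(r$p_two_sided, oracle_fisher_two_sided(2, 3, 4, 6))
  # sample odds ratio ad/bc
  expect_equal(r$odds_ratio, (2 * 6) / (3 * 4))
  # proportional table: OR 1, p 1
  r1 <- fisher_enrichment_2x2(10, 90, 30, 270)
  expect_equal(r1$odds_ratio, 1)
  expect_equal(r1$p_two_sided, 1)
  # invariance under transposing the 2x2 table
  a <- fisher_enrichment_2x2(5, 11, 7, 41)
  b <- fisher_enrichment_2x2(5, 7, 11, 41)
  expect_equal(a$p_two_sided, b$p_two_sided)
  expect_true(r$p_two_sided >= 0 && r$p_two_sided <= 1)
  # degenerate margins flagged
  expect_true(fisher_enrichment_2x2(3, 0, 2, 5)$or_degenerate)
})

test_that("disease enrichment builds the 2x2 from gene sets", {
  bg <- sprintf("h%03d", 1:100)
  cand <- bg[1:20]
  dmap <- data.frame(disease_id = "obesity", human_id = bg[c(1:8, 60:70)])
  r <- disease_enrichment(cand, bg, dmap, "obesity")
  expect_equal(r$a, 8); expect_equal(r$b, 12)
  expect_equal(r$c, 11); expect_equal(r$d, 69)
  expect_equal(r$a + r$b + r$c + r$d, 100)
  expect_equal(r$p_two_sided, oracle_fisher_two_sided(8, 12, 11, 69))
  expect_error(disease_enrichment(c("x"), bg, dmap, "obesity"), "subset")
  expect_error(disease_enrichment(cand, character(), dmap, "obesity"), "empty")
})

test_that("candidate gene selection restricts to subset HVRs and expression", {
  genes <- data.frame(gene_id = c("gIn", "gOut"), chrom = "chr1", strand = "+",
                      tss = c(1000, 200000))
  genes$exons <- list(cbind(start = 1000, end = 1012),
                      cbind(start = 200000, end = 200012))
  genes$cds <- genes$exons
  genes$cds_seq <- c("ATGTACGGGTAA", "ATGTACGGGTAA")
  proms <- gr("chr1", c(500, 199500), c(900, 199900), name = c("P1", "P2"))
  assigns <- assign_promoters(proms, genes)
  expect_equal(nrow(assigns), 2)
  hvr_subset <- gr("chr1", 0, 30000, type = "HVR")
  # NSC-SSV inside subset for gIn (TAC->TAA at pos 1006/0-based 1005);
  # same consequence for gOut but outside the subset
  ssvs <- ssv_df("chr1", c(601, 1006, 200006), c("G", "A", "A"))
  out <- select_candidate_genes(hvr_subset, ssvs, genes, proms, assigns,
                                expressed = c("gIn", "gOut"))
  expect_equal(out$nsc$gene_id, "gIn")
  expect_equal(out$nsc$n_nsc_ssvs, 1)
  expect_equal(out$promoter$gene_id, "gIn")    # SSV at 601 in P1
  expect_equal(out$promoter$n_ssvs, 1)
  # expression filter removes the gene from both routes
  out2 <- select_candidate_genes(hvr_subset, ssvs, genes, proms, assigns,
                                 expressed = character(0))
  expect_equal(nrow(out2$nsc), 0)
  expect_equal(nrow(out2$promoter), 0)
})
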