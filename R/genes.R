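# Standard genetic code, written out so consequence calls do not depend on
# Biostrings (which the test suite uses as the independent oracle).
.CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.SEVERITY <- c(non_coding = 1, synonymous_variant = 2, missense_variant = 3,
               stop_gained = 4, stop_lost = 4)

#' Consequence of a single-base substitution within one codon
#'
#' Stop gain/loss are ranked above missense and checked first; a stop codon
#' replaced by another stop is synonymous.
#'
#' @param codon reference codon (3 bases, translation orientation)
#' @param pos_in_codon 1, 2 or 3
#' @param alt_base substituted base (translation orientation)
#' @return one of "synonymous_variant", "missense_variant", "stop_gained",
#'   "stop_lost"
#' @export
codon_consequence <- function(codon, pos_in_codon, alt_base) {
  codon <- toupper(codon)
  new <- codon
  substr(new, pos_in_codon, pos_in_codon) <- toupper(alt_base)
  aa_old <- .CODON_TABLE[[codon]]
  aa_new <- .CODON_TABLE[[new]]
  if (aa_old != "*" && aa_new == "*") return("stop_gained")
  if (aa_old == "*" && aa_new != "*") return("stop_lost")
  if (aa_old == aa_new) return("synonymous_variant")
  "missense_variant"
}

#' Classify coding consequences of SSVs against gene models
#'
#' A minimal SNV consequence classifier over the standard genetic code. For
#' each SSV and each transcript whose CDS contains it, the novel allele is
#' substituted at the transcript-oriented CDS position, the affected codon is
#' re-translated, and the call is one of synonymous/missense/stop gained/stop
#' lost; SSVs outside every CDS are `non_coding`. The most severe term across
#' transcripts (and across novel alleles) is retained per SSV, with severity
#' stop_gained = stop_lost > missense > synonymous > non_coding.
#'
#' Gene models must carry `cds` interval matrices (0-based half-open, genomic
#' order) and `cds_seq`, the spliced CDS in translation order (see
#' [read_gene_models()]).
#'
#' @param ssvs an `ssv_set` (positions 1-based; `alleles` column holds the
#'   novel alleles)
#' @param genes gene-model data.frame
#' @return data.frame (chrom, pos, term, gene_id); `gene_id` is the gene of
#'   the most severe call, NA for non-coding
#' @export
classify_consequence <- function(ssvs, genes) {
  n <- nrow(ssvs)
  term <- rep("non_coding", n)
  gene <- rep(NA_character_, n)
  if (!n) return(data.frame(chrom = character(), pos = numeric(),
                            term = character(), gene_id = character()))
  for (g in seq_len(nrow(genes))) {
    cds <- genes$cds[[g]]
    if (!nrow(cds)) next
    on_chrom <- which(ssvs$chrom == genes$chrom[g])
    if (!length(on_chrom)) next
    p0 <- ssvs$pos[on_chrom] - 1          # 0-based
    inside <- rep(FALSE, length(on_chrom))
    off <- numeric(length(on_chrom))
    cum <- 0
    for (e in seq_len(nrow(cds))) {
      hit <- p0 >= cds[e, 1] & p0 < cds[e, 2]
      off[hit] <- cum + (p0[hit] - cds[e, 1])
      inside <- inside | hit
      cum <- cum + cds[e, 2] - cds[e, 1]
    }
    if (!any(inside)) next
    total <- cum
    seqv <- strsplit(genes$cds_seq[g], "")[[1]]
    if (length(seqv) != total)
      stop("cds_seq length disagrees with cds intervals for ", genes$gene_id[g])
    for (j in which(inside)) {
      i <- on_chrom[j]
      cds_off <- if (genes$strand[g] == "+") off[j] else total - 1 - off[j]
      ci <- cds_off %/% 3
      cp <- cds_off %% 3 + 1
      codon <- paste(seqv[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
      for (a in strsplit(ssvs$alleles[i], ",")[[1]]) {
        ta <- if (genes$strand[g] == "+") a else .COMPLEMENT[[a]]
        if (substr(codon, cp, cp) == ta) next   # allele equals transcript ref
        tm <- codon_consequence(codon, cp, ta)
        if (.SEVERITY[[tm]] > .SEVERITY[[term[i]]]) {
          term[i] <- tm
          gene[i] <- genes$gene_id[g]
        }
      }
    }
  }
  data.frame(chrom = ssvs$chrom, pos = ssvs$pos, term = term, gene_id = gene,
             stringsAsFactors = FALSE)
}

#' Genes expressed in a tissue
#'
#' FPKM strictly greater than `fpkm_min` (a gene at exactly the cutoff is not
#' expressed). When a gene has several rows (strains/replicates) it is
#' expressed if any row passes.
#'
#' @param expression data.frame with gene_id and fpkm columns
#' @param fpkm_min expression cutoff (default 1.0)
#' @param tissue optional tissue filter (matches a `tissue` column if present)
#' @return character vector of gene ids
#' @export
expressed_genes <- function(expression, fpkm_min = 1.0, tissue = NULL) {
  if (!nrow(expression)) return(character())
  if (!is.null(tissue) && "tissue" %in% names(expression))
    expression <- expression[expression$tissue == tissue, , drop = FALSE]
  if (any(expression$fpkm < 0)) stop("negative FPKM")
  unique(expression$gene_id[expression$fpkm > fpkm_min])
}

#' One-to-one promoter-gene assignment
#'
#' A gene is a candidate for a promoter when its TSS overlaps the promoter
#' interval or lies within `max_downstream` bp downstream of the promoter's
#' 3' end in the gene's orientation (for a + strand gene: past the promoter
#' end; for a - strand gene: before the promoter start). Candidate pairs
#' involving a promoter near several TSSs, or a gene near several promoters,
#' are all discarded: only one-to-one assignments are retained.
#'
#' @param promoters GRanges with a `name` metadata column (promoter ids)
#' @param genes gene-model data.frame (gene_id, chrom, strand, tss 0-based)
#' @param max_downstream maximum downstream distance in bp (default 5 kb)
#' @param stranded FALSE treats downstream as either side (both flanks)
#' @return data.frame (promoter_id, gene_id, distance_class)
#' @export
assign_promoters <- function(promoters, genes, max_downstream = 5000,
                             stranded = TRUE) {
  if (any(GenomicRanges::width(promoters) < 1)) stop("zero-length promoter")
  pch <- as.character(GenomicRanges::seqnames(promoters))
  ps <- .start0(promoters); pe <- .end0(promoters)
  pid <- S4Vectors::mcols(promoters)$name
  if (is.null(pid)) pid <- paste0("prom", seq_along(promoters))
  pairs <- list()
  for (g in seq_len(nrow(genes))) {
    i <- which(pch == genes$chrom[g])
    if (!length(i)) next
    tss <- genes$tss[g]
    overlap <- tss >= ps[i] & tss < pe[i]
    down_plus <- tss >= pe[i] & tss < pe[i] + max_downstream
    down_minus <- tss < ps[i] & tss >= ps[i] - max_downstream
    down <- if (!stranded) down_plus | down_minus
            else if (genes$strand[g] == "+") down_plus else down_minus
    hit <- which(overlap | down)
    for (h in hit) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        promoter_id = pid[i[h]], gene_id = genes$gene_id[g],
        distance_class = if (overlap[h]) "overlap" else "downstream",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs))
    return(data.frame(promoter_id = character(), gene_id = character(),
                      distance_class = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, pairs)
  ok <- !(df$promoter_id %in% df$promoter_id[duplicated(df$promoter_id)]) &
        !(df$gene_id %in% df$gene_id[duplicated(df$gene_id)])
  df[ok, , drop = FALSE]
}

#' Candidate genes of an HVR subset
#'
#' Two routes into the candidate list, both restricted to expressed genes:
#' genes with at least one non-synonymous coding SSV (missense, stop
#' gained/lost most-severe) located inside a subset HVR, and genes whose
#' one-to-one promoter contains at least one SSV inside a subset HVR.
#'
#' @param subset_hvrs GRanges of the HVR subset
#' @param ssvs an `ssv_set`
#' @param genes gene-model data.frame
#' @param promoters GRanges of promoters (with `name` column)
#' @param assignments data.frame from [assign_promoters()]
#' @param expressed character vector from [expressed_genes()]
#' @param consequences optional precomputed [classify_consequence()] output
#'   for `ssvs` (computed when NULL)
#' @return list with data.frames `nsc` (gene_id, n_nsc_ssvs) and `promoter`
#'   (gene_id, promoter_id, n_ssvs), plus `consequences` for the in-subset
#'   SSVs
#' @export
select_candidate_genes <- function(subset_hvrs, ssvs, genes, promoters,
                                   assignments, expressed,
                                   consequences = NULL) {
  in_subset <- IRanges::overlapsAny(ssvs_to_granges(ssvs), subset_hvrs)
  sub_ssvs <- ssvs[in_subset, , drop = FALSE]
  attr(sub_ssvs, "label") <- attr(ssvs, "label")

  if (is.null(consequences)) {
    cons <- classify_consequence(sub_ssvs, genes)
  } else {
    key <- paste(consequences$chrom, consequences$pos)
    cons <- consequences[key %in% paste(sub_ssvs$chrom, sub_ssvs$pos), ,
                         drop = FALSE]
  }
  nsc <- cons[cons$term %in% c("missense_variant", "stop_gained", "stop_lost") &
              !is.na(cons$gene_id) & cons$gene_id %in% expressed, , drop = FALSE]
  nsc_tab <- if (nrow(nsc)) {
    ag <- stats::aggregate(list(n_nsc_ssvs = nsc$pos), list(gene_id = nsc$gene_id),
                           length)
    ag[order(-ag$n_nsc_ssvs, ag$gene_id), , drop = FALSE]
  } else data.frame(gene_id = character(), n_nsc_ssvs = integer())

  pid <- S4Vectors::mcols(promoters)$name
  if (is.null(pid)) pid <- paste0("prom", seq_along(promoters))
  keep_p <- pid %in% assignments$promoter_id
  prom_hits <- GenomicRanges::countOverlaps(promoters[keep_p],
                                            ssvs_to_granges(sub_ssvs))
  prom_tab <- data.frame(promoter_id = pid[keep_p], n_ssvs = prom_hits,
                         stringsAsFactors = FALSE)
  prom_tab <- merge(prom_tab, assignments[, c("promoter_id", "gene_id")],
                    by = "promoter_id")
  prom_tab <- prom_tab[prom_tab$n_ssvs > 0 & prom_tab$gene_id %in% expressed, ,
                       drop = FALSE]
  prom_tab <- prom_tab[order(-prom_tab$n_ssvs, prom_tab$gene_id),
                       c("gene_id", "promoter_id", "n_ssvs"), drop = FALSE]
  rownames(nsc_tab) <- rownames(prom_tab) <- NULL
  list(nsc = nsc_tab, promoter = prom_tab, consequences = cons)
}

#' Restrict a rat gene set to its one-to-one human orthologues
#'
#' Keeps orthology rows of class `one2one` or `apparently_one2one`; rat genes
#' with no row, another class, or ambiguous (multiple-row) mappings are
#' dropped and counted.
#'
#' @param rat_genes character vector of rat gene ids
#' @param orthology data.frame (rat_id, human_id, class)
#' @return character vector of human gene ids (attribute `n_dropped`)
#' @export
orthologue_filter <- function(rat_genes, orthology) {
  ok <- orthology[orthology$class %in% c("one2one", "apparently_one2one"), ,
                  drop = FALSE]
  amb <- unique(c(ok$rat_id[duplicated(ok$rat_id)],
                  ok$human_id[duplicated(ok$human_id)]))
  ok <- ok[!(ok$rat_id %in% amb) & !(ok$human_id %in% amb), , drop = FALSE]
  hits <- ok$human_id[match(rat_genes, ok$rat_id)]
  out <- unique(hits[!is.na(hits)])
  structure(out, n_dropped = sum(is.na(hits)))
}

#' Disease enrichment of a candidate gene set (Fisher's exact test)
#'
#' 2x2 table: candidates in/not in the disease gene set versus the rest of
#' the background. Reports the sample odds ratio `ad/bc` (Inf or 0 flagged)
#' and both the two-sided exact p (default reading) and the one-sided
#' enrichment p.
#'
#' @param candidates character vector, must be a subset of `background`
#' @param background character vector of background gene ids
#' @param disease_map data.frame (disease_id, human_id)
#' @param disease_id disease to test
#' @return one-row data.frame (a, b, c, d, odds_ratio, or_degenerate,
#'   p_two_sided, p_enrichment)
#' @export
disease_enrichment <- function(candidates, background, disease_map, disease_id) {
  if (!length(background)) stop("empty background")
  if (!all(candidates %in% background))
    stop("candidates must be a subset of the background")
  dg <- unique(disease_map$human_id[disease_map$disease_id == disease_id])
  a <- sum(candidates %in% dg)
  b <- length(candidates) - a
  rest <- setdiff(background, candidates)
  c_ <- sum(rest %in% dg)
  d <- length(rest) - c_
  fisher_enrichment_2x2(a, b, c_, d, disease_id = disease_id)
}

#' @rdname disease_enrichment
#' @param a,b,c_,d the 2x2 counts (candidate/disease, candidate/other,
#'   other/disease, other/other)
#' @export
fisher_enrichment_2x2 <- function(a, b, c_, d, disease_id = NA_character_) {
  m <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
  orat <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NaN
  data.frame(disease_id = disease_id, a = a, b = b, c = c_, d = d,
             odds_ratio = orat, or_degenerate = !is.finite(orat),
             p_two_sided = stats::fisher.test(m)$p.value,
             p_enrichment = stats::fisher.test(m, alternative = "greater")$p.value,
             stringsAsFactors = FALSE)
}

#' Generic term enrichment over a gene-to-term table
#'
#' Replaces external annotation services: Fisher enrichment of every term of
#' a user-supplied gene-to-term map in a candidate set versus a background.
#'
#' @param candidates,background character vectors of gene ids
#' @param term_map data.frame (term, gene_id)
#' @return data.frame, one row per term, columns as [fisher_enrichment_2x2()]
#' @export
term_enrichment <- function(candidates, background, term_map) {
  do.call(rbind, lapply(unique(term_map$term), function(tm) {
    disease_enrichment(candidates, background,
                       data.frame(disease_id = tm,
                                  human_id = term_map$gene_id[term_map$term == tm]),
                       tm)
  }))
}
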