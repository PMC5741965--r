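#' Configuration for the synthetic mosaic-genome generator
#'
#' The defaults describe the stated world the pipeline's acceptance suite
#' runs on: a 5 x 10 Mb genome tiled in 10 kb windows; planted high blocks
#' with a Poisson mean of 15 SSVs per window against a background of 0.5
#' (the bimodal structure of real inbred-strain comparisons); three query
#' strains and one control strain sharing blocks identical-by-descent; three
#' transcription factors with block-specific conservation probabilities;
#' about 2% of the genome planted unmappable; and a disease map with a
#' planted odds-ratio-2.5 enrichment in the genes overlapping blocks private
#' to the first query strain.
#'
#' @param seed integer seed; the same seed yields a byte-identical bundle
#' @param n_chromosomes,chrom_length_bp,window_bp genome shape
#' @param mean_high_windows,mean_low_windows mean block / gap lengths in
#'   windows (high blocks have a floor of `min_high_windows` so a planted
#'   block always survives the 3-window run rule with margin)
#' @param min_high_windows,min_low_windows length floors in windows
#' @param n_high_blocks_per_chrom optional exact block count per chromosome
#'   (NULL = emergent from the length distribution)
#' @param lambda_high,lambda_low expected SSVs per window inside / outside
#'   planted blocks
#' @param het_fraction fraction of variants emitted heterozygous
#' @param block_membership_prob probability a strain carries a candidate block
#' @param n_tf number of transcription factors (max 3)
#' @param n_species number of comparison species
#' @param peaks_per_high_block mean rat peaks per factor per block
#' @param conservation_prob_by_block per-block conservation probabilities,
#'   recycled over candidate blocks
#' @param background_peaks_per_mb rat peak rate outside blocks (conserved
#'   with probability 0.5)
#' @param unmappable_fraction fraction of windows planted unmappable
#' @param n_genes,n_promoters gene-model sizes
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM parameters
#' @param de_fraction fraction of genes planted differentially expressed
#' @param de_in_block_fraction fraction of the DE set drawn from genes
#'   overlapping the strain's private blocks (plants the DE-in-HVR signal)
#' @param n_gwas_points number of GWAS orthologue points
#' @param gwas_high_fraction fraction of GWAS points planted inside blocks
#' @param disease_gene_fraction_background background disease-gene rate
#' @param disease_planted_or planted enrichment odds ratio
#' @return a validated `simulation_config` (list)
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 5,
                              chrom_length_bp = 1e7,
                              window_bp = 10000,
                              mean_high_windows = 10,
                              mean_low_windows = 90,
                              min_high_windows = 5,
                              min_low_windows = 20,
                              n_high_blocks_per_chrom = NULL,
                              lambda_high = 15,
                              lambda_low = 0.5,
                              het_fraction = 0.05,
                              block_membership_prob = 0.6,
                              n_tf = 3,
                              n_species = 2,
                              peaks_per_high_block = 5,
                              conservation_prob_by_block = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              background_peaks_per_mb = 1,
                              unmappable_fraction = 0.02,
                              n_genes = 400,
                              n_promoters = 300,
                              fpkm_meanlog = 0.7,
                              fpkm_sdlog = 1.5,
                              de_fraction = 0.1,
                              de_in_block_fraction = 0.5,
                              n_gwas_points = 200,
                              gwas_high_fraction = 0.5,
                              disease_gene_fraction_background = 0.11,
                              disease_planted_or = 2.5) {
  cfg <- as.list(environment())
  probs <- c(het_fraction, block_membership_prob, conservation_prob_by_block,
             unmappable_fraction, de_fraction, de_in_block_fraction,
             gwas_high_fraction, disease_gene_fraction_background)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  lens <- c(n_chromosomes, chrom_length_bp, window_bp, mean_high_windows,
            mean_low_windows, min_high_windows, min_low_windows, n_tf,
            n_species, n_genes, n_promoters, n_gwas_points)
  if (any(lens <= 0)) stop("all lengths and counts must be positive")
  if (lambda_high < 0 || lambda_low < 0) stop("rates must be non-negative")
  if (lambda_high <= lambda_low && lambda_high > 0)
    warning("lambda_high <= lambda_low: bimodality of window counts is not guaranteed")
  if (disease_planted_or <= 0) stop("odds ratio must be positive")
  if (n_tf > 3) stop("at most 3 factors (CEBPA, FOXA1, HNF4A)")
  structure(cfg, class = "simulation_config")
}

.SIM_STRAINS <- c("Q1", "Q2", "Q3", "CTL")
.SIM_FACTORS <- c("CEBPA", "FOXA1", "HNF4A")

#' Generate a synthetic dataset bundle
#'
#' Writes the full input bundle for the pipeline under `outdir`: minimal VCFs
#' for three query strains and one control strain (positions drawn per window
#' from Poisson rates, block variants shared identically by every member
#' strain), chrom.sizes, rat and comparison-species peak BEDs per factor,
#' gene and promoter tables, expression with planted DE flags, GWAS points,
#' per-window MAPQ/coverage statistics, orthology and disease maps, and a
#' `ground_truth.json` describing exactly what was planted.
#'
#' @param config a [simulation_config()]
#' @param outdir output directory (created if needed)
#' @return invisibly, a list with `paths`, `ground_truth`, and `config`
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  w <- config$window_bp
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  layout <- genome_layout(stats::setNames(rep(config$chrom_length_bp,
                                              config$n_chromosomes), chroms))
  nwin <- ceiling(config$chrom_length_bp / w)
  strains <- .SIM_STRAINS
  factors <- .SIM_FACTORS[seq_len(config$n_tf)]
  species <- paste0("mus", seq_len(config$n_species))

  ## -- candidate high blocks (window-aligned, shared pool) ------------------
  blocks <- .sim_blocks(config, chroms, nwin)
  nb <- nrow(blocks)
  blocks$prob <- rep_len(config$conservation_prob_by_block, nb)

  ## -- per-strain membership ------------------------------------------------
  member <- matrix(stats::runif(nb * length(strains)) < config$block_membership_prob,
                   nb, length(strains), dimnames = list(blocks$block_id, strains))

  ## -- variants -------------------------------------------------------------
  block_vars <- .sim_block_variants(config, blocks, w)
  vcf_paths <- character(0)
  strain_dir <- file.path(outdir, "strains")
  dir.create(strain_dir, showWarnings = FALSE)
  for (s in strains) {
    own <- blocks[member[, s], , drop = FALSE]
    bg <- .sim_background_variants(config, chroms, nwin, own, w)
    vv <- rbind(do.call(rbind, block_vars[member[, s]]), bg)
    if (is.null(vv)) vv <- bg
    vv <- vv[!duplicated(paste(vv$chrom, vv$pos)), , drop = FALSE]
    vv <- vv[order(vv$chrom, vv$pos), , drop = FALSE]
    p <- file.path(strain_dir, paste0(s, ".vcf"))
    write_minimal_vcf(vv, p, sample = s, layout = layout)
    vcf_paths[s] <- p
  }

  ## -- TF peaks -------------------------------------------------------------
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  peak_truth <- list()
  peak_paths <- list()
  for (f in factors) {
    pk <- .sim_peaks(config, blocks, chroms, f)
    peak_truth[[f]] <- pk
    rat_gr <- .granges(pk$chrom, pk$start, pk$end, name = pk$peak_id)
    rp <- file.path(outdir, "peaks", paste0(f, "_rat.bed"))
    write_bed(rat_gr, rp)
    peak_paths[[f]] <- c(rat = rp)
    for (sp in species) {
      has <- vapply(strsplit(pk$supporting, ",", fixed = TRUE),
                    function(x) sp %in% x, logical(1))
      op <- file.path(outdir, "peaks", paste0(f, "_", sp, ".bed"))
      write_bed(.granges(pk$chrom[has], pk$start[has], pk$end[has],
                         name = pk$peak_id[has]), op)
      peak_paths[[f]][sp] <- op
    }
  }

  ## -- unmappable stretches + per-window mapping stats ----------------------
  um <- .sim_unmappable(config, blocks, chroms, nwin)
  stats_df <- .sim_mapstats(config, um, chroms, nwin)
  .write_tsv(stats_df, file.path(outdir, "mapstats.tsv"))
  write_bed(.granges(um$chrom, um$win_from * w, (um$win_to + 1) * w),
            file.path(outdir, "unmappable_truth.bed"))

  ## -- gene models, promoters, expression -----------------------------------
  genes <- .sim_genes(config, chroms)
  write_gene_models(genes, file.path(outdir, "genes.tsv"))
  prom <- .sim_promoters(config, genes)
  write_bed(.granges(prom$chrom, prom$start, prom$end, name = prom$promoter_id),
            file.path(outdir, "promoters.bed"))

  private_q1 <- blocks[member[, "Q1"] & !member[, "CTL"], , drop = FALSE]
  de_sets <- list()
  expr <- list()
  for (s in c("Q1", "Q2", "Q3")) {
    priv <- blocks[member[, s] & !member[, "CTL"], , drop = FALSE]
    de <- .sim_de_set(config, genes, priv)
    de_sets[[s]] <- de
    expr[[s]] <- data.frame(gene_id = genes$gene_id, tissue = "liver",
                            strain = s,
                            fpkm = round(stats::rlnorm(nrow(genes),
                                                       config$fpkm_meanlog,
                                                       config$fpkm_sdlog), 4),
                            de_flag = as.integer(genes$gene_id %in% de),
                            stringsAsFactors = FALSE)
  }
  .write_tsv(do.call(rbind, expr), file.path(outdir, "expression.tsv"))

  ## -- GWAS points ----------------------------------------------------------
  gwas <- .sim_gwas(config, blocks, chroms)
  write_bed(.granges(gwas$chrom, gwas$pos, gwas$pos + 1, name = gwas$id),
            file.path(outdir, "gwas.bed"))

  ## -- orthology + disease map ----------------------------------------------
  orth <- data.frame(rat_id = genes$gene_id,
                     human_id = sprintf("HG%05d", seq_len(nrow(genes))),
                     class = sample(c("one2one", "apparently_one2one", "other"),
                                    nrow(genes), replace = TRUE,
                                    prob = c(0.85, 0.05, 0.10)),
                     stringsAsFactors = FALSE)
  .write_tsv(orth, file.path(outdir, "orthology.tsv"))

  planted_rat <- .genes_overlapping_blocks(genes, private_q1)
  p0 <- config$disease_gene_fraction_background
  odds1 <- config$disease_planted_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  in_planted <- genes$gene_id %in% planted_rat
  has_disease <- stats::runif(nrow(genes)) < ifelse(in_planted, p1, p0)
  ctrl_disease <- stats::runif(nrow(genes)) < p0
  h1 <- orth$human_id[has_disease]
  h2 <- orth$human_id[ctrl_disease]
  dm <- data.frame(disease_id = c(rep("obesity", length(h1)),
                                  rep("heart_disease", length(h2))),
                   human_id = c(h1, h2), stringsAsFactors = FALSE)
  .write_tsv(dm, file.path(outdir, "disease_map.tsv"))

  write_chrom_sizes(layout, file.path(outdir, "chrom.sizes"))

  ## -- ground truth ---------------------------------------------------------
  gt <- list(
    candidate_blocks = blocks[, c("block_id", "chrom", "start", "end", "prob")],
    membership = as.data.frame(member),
    strain_blocks = lapply(stats::setNames(strains, strains), function(s)
      blocks[member[, s], c("block_id", "chrom", "start", "end")]),
    unmappable = data.frame(chrom = um$chrom, start = um$win_from * w,
                            end = (um$win_to + 1) * w),
    peaks = lapply(peak_truth, function(pk)
      pk[, c("peak_id", "chrom", "start", "end", "conserved", "block_id")]),
    de_sets = de_sets,
    disease_planted_genes = planted_rat,
    disease_member_genes = genes$gene_id[has_disease],
    seed = config$seed)
  jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  paths <- list(chrom_sizes = file.path(outdir, "chrom.sizes"),
                vcf = vcf_paths, peaks = peak_paths,
                mapstats = file.path(outdir, "mapstats.tsv"),
                unmappable_truth = file.path(outdir, "unmappable_truth.bed"),
                genes = file.path(outdir, "genes.tsv"),
                promoters = file.path(outdir, "promoters.bed"),
                expression = file.path(outdir, "expression.tsv"),
                gwas = file.path(outdir, "gwas.bed"),
                orthology = file.path(outdir, "orthology.tsv"),
                disease_map = file.path(outdir, "disease_map.tsv"),
                ground_truth = file.path(outdir, "ground_truth.json"))
  invisible(list(paths = paths, ground_truth = gt, config = config,
                 layout = layout))
}

# window-aligned candidate blocks; coordinates in bp (0-based half-open)
.sim_blocks <- function(config, chroms, nwin) {
  w <- config$window_bp
  out <- list()
  for (ch in chroms) {
    if (!is.null(config$n_high_blocks_per_chrom)) {
      nb <- config$n_high_blocks_per_chrom
      hl <- config$min_high_windows +
        stats::rgeom(nb, 1 / (config$mean_high_windows - config$min_high_windows + 1))
      slack <- nwin - sum(hl) - (nb + 1) * config$min_low_windows
      if (slack < 0) stop("blocks do not fit the chromosome")
      extra <- if (slack > 0) as.vector(stats::rmultinom(1, slack, rep(1, nb + 1))) else rep(0, nb + 1)
      gaps <- config$min_low_windows + extra
      pos <- cumsum(gaps[seq_len(nb)] + c(0, hl[-nb]))
      starts <- pos
      lens <- hl
    } else {
      starts <- integer(0); lens <- integer(0)
      cur <- 0
      repeat {
        gap <- config$min_low_windows +
          stats::rgeom(1, 1 / (config$mean_low_windows - config$min_low_windows + 1))
        hl <- config$min_high_windows +
          stats::rgeom(1, 1 / (config$mean_high_windows - config$min_high_windows + 1))
        if (cur + gap + hl + config$min_low_windows > nwin) break
        starts <- c(starts, cur + gap)
        lens <- c(lens, hl)
        cur <- cur + gap + hl
      }
    }
    if (length(starts))
      out[[ch]] <- data.frame(chrom = ch, win_from = starts,
                              win_to = starts + lens - 1L,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    stop("no high block fits the chromosome; shorten min/mean block and gap ",
         "lengths or lengthen the chromosomes")
  df$start <- df$win_from * w
  df$end <- (df$win_to + 1L) * w
  df$block_id <- sprintf("B%03d", seq_len(nrow(df)))
  rownames(df) <- df$block_id
  df
}

.sim_variants_in_windows <- function(config, chrom, win_idx, lambda, w) {
  counts <- stats::rpois(length(win_idx), lambda)
  tot <- sum(counts)
  if (!tot) return(NULL)
  win_rep <- rep(win_idx, counts)
  offs <- unlist(lapply(counts[counts > 0], function(n)
    sample.int(w, n, replace = FALSE)))
  pos <- win_rep * w + offs
  # reference base is a pure function of position so independently drawn
  # variants at one site always agree on REF (a pseudo-reference genome)
  bases <- c("A", "C", "G", "T")
  ref <- bases[(pos %% 4) + 1]
  alt_off <- 1 + floor(stats::runif(tot) * 3)       # 1..3 away from ref
  alt <- bases[((pos %% 4) + alt_off) %% 4 + 1]
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             zygosity = ifelse(stats::runif(tot) < config$het_fraction,
                               "het", "hom"),
             stringsAsFactors = FALSE)
}

# one variant table per candidate block, shared by all member strains
.sim_block_variants <- function(config, blocks, w) {
  lapply(seq_len(nrow(blocks)), function(b)
    .sim_variants_in_windows(config, blocks$chrom[b],
                             seq(blocks$win_from[b], blocks$win_to[b]),
                             config$lambda_high, w))
}

.sim_background_variants <- function(config, chroms, nwin, own_blocks, w) {
  out <- list()
  for (ch in chroms) {
    in_block <- rep(FALSE, nwin)
    bb <- own_blocks[own_blocks$chrom == ch, , drop = FALSE]
    for (b in seq_len(nrow(bb)))
      in_block[(bb$win_from[b]:bb$win_to[b]) + 1L] <- TRUE
    out[[ch]] <- .sim_variants_in_windows(config, ch, which(!in_block) - 1L,
                                          config$lambda_low, w)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) data.frame(chrom = character(), pos = numeric(),
                              ref = character(), alt = character(),
                              zygosity = character()) else df
}

.sim_peaks <- function(config, blocks, chroms, f) {
  species <- paste0("mus", seq_len(config$n_species))
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    n <- stats::rpois(1, config$peaks_per_high_block)
    if (!n) next
    width <- round(stats::runif(n, 200, 600))
    start <- blocks$start[b] +
      floor(stats::runif(n) * (blocks$end[b] - blocks$start[b] - width))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = blocks$chrom[b], start = start, end = start + width,
      block_id = blocks$block_id[b],
      conserved = stats::runif(n) < blocks$prob[b],
      stringsAsFactors = FALSE)
  }
  # background peaks outside candidate blocks, conserved at 0.5
  total_mb <- config$n_chromosomes * config$chrom_length_bp / 1e6
  nbg <- stats::rpois(1, config$background_peaks_per_mb * total_mb)
  if (nbg) {
    got <- 0; tries <- 0
    bg <- list()
    while (got < nbg && tries < nbg * 20) {
      tries <- tries + 1
      ch <- sample(chroms, 1)
      width <- round(stats::runif(1, 200, 600))
      start <- floor(stats::runif(1) * (config$chrom_length_bp - width))
      bb <- blocks[blocks$chrom == ch, , drop = FALSE]
      if (any(start < bb$end & start + width > bb$start)) next
      got <- got + 1
      bg[[got]] <- data.frame(chrom = ch, start = start, end = start + width,
                              block_id = NA_character_,
                              conserved = stats::runif(1) < 0.5,
                              stringsAsFactors = FALSE)
    }
    rows <- c(rows, bg)
  }
  pk <- do.call(rbind, rows)
  pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
  pk$peak_id <- sprintf("%s_pk%05d", f, seq_len(nrow(pk)))
  pk$supporting <- ""
  cons <- which(pk$conserved)
  if (length(cons)) {
    pk$supporting[cons] <- vapply(cons, function(i) {
      k <- sample.int(config$n_species, 1)
      paste(sort(sample(species, k)), collapse = ",")
    }, character(1))
  }
  rownames(pk) <- NULL
  pk
}

.sim_unmappable <- function(config, blocks, chroms, nwin) {
  target <- round(config$unmappable_fraction * length(chroms) * nwin)
  taken <- lapply(stats::setNames(chroms, chroms), function(ch) rep(FALSE, nwin))
  for (ch in chroms) {
    bb <- blocks[blocks$chrom == ch, , drop = FALSE]
    for (b in seq_len(nrow(bb)))
      taken[[ch]][(bb$win_from[b]:bb$win_to[b]) + 1L] <- TRUE   # keep off blocks
  }
  placed <- list(); got <- 0; tries <- 0
  used <- lapply(taken, identity)
  while (got < target && tries < 200 + target * 30) {
    tries <- tries + 1
    ch <- sample(chroms, 1)
    len <- sample(3:6, 1)
    s <- sample.int(nwin - len + 1, 1) - 1L
    idx <- (s:(s + len - 1)) + 1L
    if (any(used[[ch]][idx])) next
    used[[ch]][idx] <- TRUE
    placed[[length(placed) + 1L]] <- data.frame(chrom = ch, win_from = s,
                                                win_to = s + len - 1L,
                                                stringsAsFactors = FALSE)
    got <- got + len
  }
  df <- do.call(rbind, placed)
  if (is.null(df)) df <- data.frame(chrom = character(), win_from = integer(),
                                    win_to = integer())
  df[order(df$chrom, df$win_from), , drop = FALSE]
}

.sim_mapstats <- function(config, um, chroms, nwin) {
  df <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, window_index = seq_len(nwin) - 1L,
               mean_mapq = round(pmin(60, stats::rnorm(nwin, 58, 1.5)), 2),
               mean_coverage = round(pmax(1, stats::rnorm(nwin, 30, 5)), 2),
               stringsAsFactors = FALSE)))
  for (r in seq_len(nrow(um))) {
    idx <- which(df$chrom == um$chrom[r] &
                 df$window_index >= um$win_from[r] &
                 df$window_index <= um$win_to[r])
    kind <- sample(c("mapq", "cov", "both"), 1)
    if (kind %in% c("mapq", "both"))
      df$mean_mapq[idx] <- round(pmax(0, pmin(30, stats::rnorm(length(idx), 15, 5))), 2)
    if (kind %in% c("cov", "both"))
      df$mean_coverage[idx] <- round(pmax(100, stats::rnorm(length(idx), 150, 25)), 2)
  }
  df
}

.sim_genes <- function(config, chroms) {
  n <- config$n_genes
  non_stop <- setdiff(names(.CODON_TABLE), c("TAA", "TAG", "TGA"))
  rows <- list()
  for (g in seq_len(n)) {
    ch <- sample(chroms, 1)
    strand <- sample(c("+", "-"), 1)
    n_codon <- sample(100:400, 1)
    cds_seq <- paste0(paste(sample(non_stop, n_codon, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1))
    L <- nchar(cds_seq)
    n_ex <- sample(1:3, 1)
    cuts <- if (n_ex > 1) sort(sample(seq(10, L - 10), n_ex - 1)) else integer(0)
    piece <- diff(c(0, cuts, L))
    introns <- if (n_ex > 1) sample(200:2000, n_ex - 1, replace = TRUE) else integer(0)
    span <- L + sum(introns)
    gstart <- sample.int(config$chrom_length_bp - span - 20000, 1) + 10000
    ex_start <- gstart + cumsum(c(0, piece[-n_ex] + introns))
    ex_end <- ex_start + piece
    cds <- cbind(start = ex_start, end = ex_end)
    tss <- if (strand == "+") gstart else gstart + span - 1
    rows[[g]] <- list(gene_id = sprintf("G%04d", g), chrom = ch,
                      strand = strand, tss = tss,
                      exons = cds, cds = cds, cds_seq = cds_seq,
                      gstart = gstart, gend = gstart + span)
  }
  df <- data.frame(gene_id = vapply(rows, `[[`, character(1), "gene_id"),
                   chrom = vapply(rows, `[[`, character(1), "chrom"),
                   strand = vapply(rows, `[[`, character(1), "strand"),
                   tss = vapply(rows, `[[`, numeric(1), "tss"),
                   stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  df$cds <- lapply(rows, `[[`, "cds")
  df$cds_seq <- vapply(rows, `[[`, character(1), "cds_seq")
  df$gstart <- vapply(rows, `[[`, numeric(1), "gstart")
  df$gend <- vapply(rows, `[[`, numeric(1), "gend")
  df
}

.sim_promoters <- function(config, genes) {
  idx <- sample(nrow(genes), min(config$n_promoters, nrow(genes)))
  rows <- list()
  for (k in seq_along(idx)) {
    g <- idx[k]
    plen <- sample(500:2000, 1)
    gap <- sample(-400:4000, 1)      # negative gap: promoter overlaps the TSS
    tss <- genes$tss[g]
    if (genes$strand[g] == "+") {
      end <- tss - gap
      start <- end - plen
    } else {
      start <- tss + 1 + gap
      end <- start + plen
    }
    if (start < 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = genes$chrom[g], start = start, end = end,
      promoter_id = sprintf("P%04d", k), gene_idx = g,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.genes_overlapping_blocks <- function(genes, blocks) {
  if (!nrow(blocks)) return(character())
  hit <- vapply(seq_len(nrow(genes)), function(g) {
    bb <- blocks[blocks$chrom == genes$chrom[g], , drop = FALSE]
    any(genes$gstart[g] < bb$end & genes$gend[g] > bb$start)
  }, logical(1))
  genes$gene_id[hit]
}

.sim_de_set <- function(config, genes, private_blocks) {
  n_de <- round(config$de_fraction * nrow(genes))
  in_block <- .genes_overlapping_blocks(genes, private_blocks)
  n_in <- min(length(in_block), round(config$de_in_block_fraction * n_de))
  de <- sample(in_block, n_in)
  pool <- setdiff(genes$gene_id, de)
  c(de, sample(pool, n_de - n_in))
}

.sim_gwas <- function(config, blocks, chroms) {
  n <- config$n_gwas_points
  n_in <- round(config$gwas_high_fraction * n)
  pos <- numeric(0); ch <- character(0)
  if (n_in && nrow(blocks)) {
    bi <- sample(nrow(blocks), n_in, replace = TRUE,
                 prob = blocks$end - blocks$start)
    ch <- blocks$chrom[bi]
    pos <- blocks$start[bi] +
      floor(stats::runif(n_in) * (blocks$end[bi] - blocks$start[bi]))
  }
  n_out <- n - length(pos)
  ch <- c(ch, sample(chroms, n_out, replace = TRUE))
  pos <- c(pos, floor(stats::runif(n_out) * config$chrom_length_bp))
  o <- order(ch, pos)
  data.frame(chrom = ch[o], pos = pos[o], id = sprintf("rs%06d", seq_len(n)),
             stringsAsFactors = FALSE)
}
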