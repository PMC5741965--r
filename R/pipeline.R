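#' Build a pipeline configuration
#'
#' Bundles input paths and the analysis parameters. Defaults are the
#' method's stated constants: 10 kb windows, triangular smoothing with k = 3,
#' valley threshold with fallback 3, 3-window minimum runs, MAPQ <= 30 /
#' coverage >= 100 unmappability, 1 Mb cluster gap, 10,000 permutations,
#' FPKM > 1 expression, 5 kb promoter-downstream rule.
#'
#' @param paths named list of input paths as produced by [simulate_dataset()]
#'   (`chrom_sizes`, `vcf` named by strain, `peaks` nested factor -> species,
#'   `mapstats`, `genes`, `promoters`, `expression`, `gwas`, `orthology`,
#'   `disease_map`)
#' @param outdir output directory
#' @param control name of the control strain in `paths$vcf` (default "CTL")
#' @param queries query strain names (default: every other strain)
#' @param window_bp,k,min_run,mapq_max,cov_min,max_gap,fpkm_min,
#'   promoter_max_downstream numeric parameters (see module docs)
#' @param threshold_override fallback/forced HVR threshold
#' @param threshold_auto FALSE forces the override
#' @param n_permutations permutations per enrichment test
#' @param seed master seed for the stochastic stages
#' @param ce_mode CE reading, "density_per_10kb" or "fraction"
#' @param ce_thresholds,ntf_levels subset grids
#' @param candidate_subset subset used for candidate-gene selection
#' @param permute_subsets subsets to run permutation tests on
#' @param disease_ids diseases to test
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(paths, outdir,
                            control = "CTL", queries = NULL,
                            window_bp = 10000, k = 3,
                            threshold_override = 3, threshold_auto = TRUE,
                            min_run = 3, mapq_max = 30, cov_min = 100,
                            max_gap = 1e6, n_permutations = 10000, seed = 1,
                            ce_mode = "density_per_10kb",
                            ce_thresholds = c(0, 0.2, 0.4, 0.6, 0.8),
                            ntf_levels = 1:3,
                            candidate_subset = "NTF>=3",
                            permute_subsets = c("ALL", "NTF>=3"),
                            fpkm_min = 1.0,
                            promoter_max_downstream = 5000,
                            disease_ids = NULL) {
  if (is.null(queries)) queries <- setdiff(names(paths$vcf), control)
  cfg <- as.list(environment())
  num <- c(window_bp, k, min_run, mapq_max, cov_min, max_gap, n_permutations,
           promoter_max_downstream)
  if (any(num <= 0)) stop("numeric parameters must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks that every referenced path exists, that interval records stay
#' within the chromosome bounds of the layout, that VCF contigs are known,
#' and that interval files are sorted (unsorted input is a warning: readers
#' sort). Returns a data.frame of issues with severity "error" or "warning";
#' `strict = TRUE` stops on any error.
#'
#' @param config a [pipeline_config()]
#' @param strict stop on errors (default TRUE)
#' @return data.frame (severity, stage, message), invisibly when clean
#' @export
validate_inputs <- function(config, strict = TRUE) {
  issues <- list()
  add <- function(sev, stage, msg)
    issues[[length(issues) + 1L]] <<- data.frame(severity = sev, stage = stage,
                                                 message = msg,
                                                 stringsAsFactors = FALSE)
  flat <- c(config$paths$chrom_sizes, unlist(config$paths$vcf),
            unlist(config$paths$peaks), config$paths$mapstats,
            config$paths$genes, config$paths$promoters,
            config$paths$expression, config$paths$gwas,
            config$paths$orthology, config$paths$disease_map)
  missing <- flat[!file.exists(flat)]
  for (m in missing) add("error", "paths", paste("missing input file:", m))
  if (length(missing)) {
    df <- do.call(rbind, issues)
    if (strict) stop("input validation failed:\n",
                     paste(df$message, collapse = "\n"))
    return(df)
  }
  layout <- read_chrom_sizes(config$paths$chrom_sizes)
  for (s in names(config$paths$vcf)) {
    v <- read_minimal_vcf(config$paths$vcf[[s]])
    unknown <- setdiff(unique(v$chrom), names(layout))
    if (length(unknown))
      add("error", "vcf", paste0(s, ": contig(s) absent from layout: ",
                                 paste(unknown, collapse = ",")))
    else if (nrow(v) && any(v$pos > unclass(layout)[v$chrom] | v$pos < 1))
      add("error", "vcf", paste0(s, ": position beyond chromosome end"))
    if (nrow(v) && !identical(order(v$chrom, v$pos), seq_len(nrow(v))))
      add("warning", "vcf", paste0(s, ": records not sorted"))
  }
  for (f in names(config$paths$peaks)) {
    for (sp in names(config$paths$peaks[[f]])) {
      gr <- read_bed(config$paths$peaks[[f]][[sp]])
      ch <- as.character(GenomicRanges::seqnames(gr))
      unknown <- setdiff(unique(ch), names(layout))
      if (length(unknown))
        add("error", "peaks", paste0(f, "/", sp, ": unknown contig ",
                                     paste(unknown, collapse = ",")))
      else if (length(gr) && any(.end0(gr) > unclass(layout)[ch]))
        add("error", "peaks", paste0(f, "/", sp, ": record beyond chromosome end"))
      if (length(gr) > 1 && is.unsorted(order(ch, .start0(gr))))
        add("warning", "peaks", paste0(f, "/", sp, ": not sorted; will auto-sort"))
    }
  }
  df <- if (length(issues)) do.call(rbind, issues)
        else data.frame(severity = character(), stage = character(),
                        message = character())
  if (strict && any(df$severity == "error"))
    stop("input validation failed:\n",
         paste(df$message[df$severity == "error"], collapse = "\n"))
  if (any(df$severity == "warning"))
    for (m in df$message[df$severity == "warning"]) warning(m, call. = FALSE)
  invisible(df)
}

#' Run the full analysis
#'
#' SSV calling (each query versus the control on top of the reference) ->
#' window counts -> triangular smoothing -> valley threshold (from the
#' query-versus-reference track) -> unmappable masking -> HVR/LVR calling ->
#' conservation annotation and CE scoring -> HVR subsets -> permutation
#' enrichment tests per subset and element class -> candidate genes on the
#' selected subset -> orthologue mapping and disease Fisher tests. All
#' tables are written under `config$outdir` together with a machine-readable
#' `report.json`; reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, the report list
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_inputs(config, strict = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  layout <- read_chrom_sizes(config$paths$chrom_sizes)
  log <- list()
  say <- function(stage, ...) {
    log[[length(log) + 1L]] <<- paste0("[", stage, "] ", paste0(...))
    message(log[[length(log)]])
  }

  control <- read_minimal_vcf(config$paths$vcf[[config$control]])
  say("ssv", "control strain ", config$control, ": ", nrow(control), " variant records")

  stats_df <- read_window_stats(config$paths$mapstats)
  unmap <- detect_unmappable(stats_df, layout, config$window_bp,
                             config$mapq_max, config$cov_min, config$min_run)
  say("unmappable", length(unmap), " UNMAP regions")

  expr <- .read_tsv(config$paths$expression)
  genes <- read_gene_models(config$paths$genes)
  promoters <- read_bed(config$paths$promoters, extra_names = "name")
  gwas <- read_bed(config$paths$gwas, extra_names = "name")
  orthology <- .read_tsv(config$paths$orthology)
  disease_map <- .read_tsv(config$paths$disease_map)
  disease_ids <- config$disease_ids %||% unique(disease_map$disease_id)
  gene_bodies <- .granges(genes$chrom,
                          vapply(genes$exons, function(m) min(m[, 1]), numeric(1)),
                          vapply(genes$exons, function(m) max(m[, 2]), numeric(1)),
                          name = genes$gene_id)

  peaks <- list()
  for (f in names(config$paths$peaks)) {
    sp <- names(config$paths$peaks[[f]])
    rat <- read_bed(config$paths$peaks[[f]][["rat"]], extra_names = "name")
    S4Vectors::mcols(rat)$factor <- f
    others <- lapply(setdiff(sp, "rat"), function(s1) {
      g <- read_bed(config$paths$peaks[[f]][[s1]], extra_names = "name")
      S4Vectors::mcols(g)$factor <- f
      S4Vectors::mcols(g)$species <- s1
      g
    })
    peaks[[f]] <- annotate_conservation(rat, others)
    say("conserve", f, ": ", sum(S4Vectors::mcols(peaks[[f]])$conserved), "/",
        length(peaks[[f]]), " rat peaks conserved")
  }

  report <- list(config = config[setdiff(names(config), c("paths", "outdir"))],
                 comparisons = list())
  for (q in config$queries) {
    query <- read_minimal_vcf(config$paths$vcf[[q]])
    ssv_ref <- call_ssvs_vs_reference(query, label = paste0(q, "vsREF"))
    ssv <- call_ssvs_vs_control(query, control,
                                label = paste0(q, "vs", config$control))
    say("ssv", q, ": ", nrow(ssv_ref), " SSVs vs reference, ", nrow(ssv),
        " vs control")

    ref_track <- smooth_track(count_ssvs_per_window(ssv_ref, layout,
                                                    config$window_bp), config$k)
    t <- if (config$threshold_auto)
      find_threshold(ref_track$smooth, override = config$threshold_override)
    else config$threshold_override
    say("segment", q, ": threshold ", t)

    track <- smooth_track(count_ssvs_per_window(ssv, layout, config$window_bp),
                          config$k)
    regions <- call_regions(track, t, config$min_run, unmap, layout)
    hvrs <- regions[S4Vectors::mcols(regions)$type == "HVR"]
    summ <- summarize_comparison(ssv, regions, layout)
    say("segment", q, ": ", summ$n_hvrs, " HVRs covering ", summ$hvr_bp, " bp (",
        summ$pct_genome_hvr, "% of genome), ", summ$pct_ssvs_in_hvrs,
        "% of SSVs inside")

    ce_tables <- lapply(peaks, function(pk) compute_ce(hvrs, pk, config$ce_mode))
    subsets <- build_subsets(hvrs, ce_tables, config$ce_thresholds,
                             config$ntf_levels)
    ids <- .hvr_ids(hvrs)

    expressed <- expressed_genes(expr[expr$strain == q, , drop = FALSE],
                                 config$fpkm_min, tissue = "liver")
    de_ids <- unique(expr$gene_id[expr$strain == q & expr$de_flag == 1])
    de_bodies <- gene_bodies[S4Vectors::mcols(gene_bodies)$name %in% de_ids]

    elements <- list(genes = list(gr = gene_bodies, mode = "n_elements_overlapping"),
                     de_genes = list(gr = de_bodies, mode = "n_elements_overlapping"),
                     gwas = list(gr = gwas, mode = "n_points_in"))
    for (f in names(peaks))
      elements[[paste0("peaks_", f)]] <- list(gr = peaks[[f]],
                                              mode = "n_elements_overlapping")
    perms <- list()
    for (sn in intersect(config$permute_subsets, names(subsets))) {
      sub_gr <- hvrs[ids %in% subsets[[sn]]]
      if (!length(sub_gr)) next
      for (en in names(elements)) {
        res <- permutation_test(sub_gr, elements[[en]]$gr, layout,
                                mode = elements[[en]]$mode,
                                N = config$n_permutations,
                                max_gap = config$max_gap,
                                seed = config$seed + 7919L)
        perms[[paste(sn, en, sep = "|")]] <-
          list(subset = sn, element = en, observed = res$observed,
               mean_null = res$mean_null, p_value = res$p_value, N = res$N)
        say("permute", q, " ", sn, " x ", en, ": OV=", res$observed,
            " mean(EV)=", round(res$mean_null, 3), " p=",
            signif(res$p_value, 3))
      }
    }

    assignments <- assign_promoters(promoters, genes,
                                    config$promoter_max_downstream)
    sub_gr <- hvrs[ids %in% (subsets[[config$candidate_subset]] %||% character())]
    cand <- select_candidate_genes(sub_gr, ssv, genes, promoters, assignments,
                                   expressed)
    nsc_counts <- nsc_sc_ratio(cand$consequences)
    say("annotate", q, ": ", nrow(cand$nsc), " genes with NSC-SSVs, ",
        nrow(cand$promoter), " genes via promoter SSVs (subset ",
        config$candidate_subset, ")")

    disease <- list()
    routes <- list(nsc = list(cand = cand$nsc$gene_id, bg = expressed),
                   promoter = list(cand = cand$promoter$gene_id,
                                   bg = intersect(assignments$gene_id, expressed)))
    for (rt in names(routes)) {
      cand_h <- orthologue_filter(routes[[rt]]$cand, orthology)
      bg_h <- orthologue_filter(routes[[rt]]$bg, orthology)
      cand_h <- intersect(cand_h, bg_h)
      for (d in disease_ids) {
        de_res <- disease_enrichment(cand_h, bg_h, disease_map, d)
        de_res$route <- rt
        disease[[paste(rt, d, sep = "|")]] <- de_res
        say("enrich", q, " ", rt, " x ", d, ": ", de_res$a, "/",
            de_res$a + de_res$b, " vs ", de_res$c, "/", de_res$c + de_res$d,
            " p=", signif(de_res$p_two_sided, 3))
      }
    }

    cmp_dir <- file.path(config$outdir, q)
    dir.create(cmp_dir, showWarnings = FALSE)
    write_ssv_bed(ssv, file.path(cmp_dir, "ssv.bed"))
    .write_tsv(track, file.path(cmp_dir, "windows.tsv"))
    write_bed(regions, file.path(cmp_dir, "regions.bed"))
    .write_tsv(summ, file.path(cmp_dir, "summary.tsv"))
    .write_tsv(do.call(rbind, ce_tables), file.path(cmp_dir, "ce.tsv"))
    .write_tsv(data.frame(subset = rep(names(subsets), lengths(subsets)),
                          hvr_id = unlist(subsets, use.names = FALSE)),
               file.path(cmp_dir, "subsets.tsv"))
    .write_tsv(cand$nsc, file.path(cmp_dir, "candidates_nsc.tsv"))
    .write_tsv(cand$promoter, file.path(cmp_dir, "candidates_promoter.tsv"))
    if (length(disease))
      .write_tsv(do.call(rbind, disease), file.path(cmp_dir, "disease.tsv"))

    report$comparisons[[q]] <- list(
      threshold = t, summary = as.list(summ),
      subset_sizes = lapply(subsets, length),
      nsc_sc = as.list(nsc_counts),
      permutations = perms,
      disease = lapply(disease, as.list),
      n_candidates = list(nsc = nrow(cand$nsc), promoter = nrow(cand$promoter)))
  }
  report$log <- unlist(log)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
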