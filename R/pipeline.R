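# Orchestration of the full analysis: ERE prediction and gene grouping,
# threshold calibration, TFBS scanning, per-group over-representation,
# network construction and TF ranking, and the positional statistics.
# Every stage writes its outputs before the next begins and the log mirrors
# the narrative counts (genes, promoters, hits, enriched matrices, edges,
# retained TFs).

#' Assemble a pipeline configuration
#'
#' @param pwm_library Path to the PWM library file.
#' @param pwm_format `"jaspar"` or `"transfac"`.
#' @param target_fasta,background_fasta Promoter FASTA paths.
#' @param gene_table Gene table TSV path.
#' @param matrix_tf_map Matrix-to-TF map TSV path.
#' @param out_dir Output directory.
#' @param annotation Optional annotation TSV (`gene_id`, `term`) for
#'   per-group term fractions.
#' @param threshold_profile Optional pre-computed threshold profile TSV;
#'   when `NULL`, cutoffs are calibrated on the background at
#'   `target_fp_per_kb`.
#' @param tss_offset TSS offset within promoter sequences; default 1000.
#' @param pseudocount PWM pseudocount; default 0.01.
#' @param target_fp_per_kb Calibration target; default 0.5.
#' @param ere_max_mismatch ERE mismatch tolerance; default 2.
#' @param ori_pseudocount,ori_threshold ORI parameters; defaults 1 and 2.
#' @param percentile Retention percentile for TF ranking; default 80.
#' @param bin_width Distance histogram bin width; default 50.
#' @param grid_points Density grid size; default 512.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when the inputs are generated).
#' @return A `pipeline_config` object (validated list).
#' @export
pipeline_config <- function(pwm_library, target_fasta, background_fasta,
                            gene_table, matrix_tf_map, out_dir,
                            pwm_format = "jaspar",
                            annotation = NULL,
                            threshold_profile = NULL,
                            tss_offset = 1000L, pseudocount = 0.01,
                            target_fp_per_kb = 0.5,
                            ere_max_mismatch = 2L,
                            ori_pseudocount = 1, ori_threshold = 2,
                            percentile = 80, bin_width = 50L,
                            grid_points = 512L, seed = 1L) {
  cfg <- list(pwm_library = pwm_library, pwm_format = pwm_format,
              target_fasta = target_fasta,
              background_fasta = background_fasta,
              gene_table = gene_table, matrix_tf_map = matrix_tf_map,
              annotation = annotation,
              threshold_profile = threshold_profile,
              tss_offset = as.integer(tss_offset),
              pseudocount = pseudocount,
              target_fp_per_kb = target_fp_per_kb,
              ere_max_mismatch = as.integer(ere_max_mismatch),
              ori_pseudocount = ori_pseudocount,
              ori_threshold = ori_threshold,
              percentile = percentile, bin_width = as.integer(bin_width),
              grid_points = as.integer(grid_points),
              out_dir = out_dir, seed = as.integer(seed))
  required <- c("pwm_library", "target_fasta", "background_fasta",
                "gene_table", "matrix_tf_map", "out_dir")
  for (f in required)
    if (is.null(cfg[[f]]) || !nzchar(cfg[[f]]))
      stop("pipeline config is missing required field '", f, "'")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Generate a synthetic cohort and run the full pipeline on it
#'
#' Convenience wrapper: writes the cohort of a [cohort_spec()] to
#' `workdir/cohort`, assembles a [pipeline_config()] with the given
#' overrides, and calls [run_full()] with outputs under `workdir/out`.
#'
#' @param spec A [cohort_spec()].
#' @param workdir Working directory; default a fresh temporary directory.
#' @param ... Arguments forwarded to [pipeline_config()] (e.g.
#'   `ori_threshold`, `percentile`).
#' @return The [run_full()] result bundle, with the cohort attached as
#'   `$cohort`.
#' @export
run_synthetic_cohort <- function(spec, workdir = tempfile("erenet"), ...) {
  cohort <- generate_cohort(spec, dir = file.path(workdir, "cohort"))
  cfg <- pipeline_config(
    pwm_library = cohort$paths[["pwm_library"]],
    target_fasta = cohort$paths[["targets"]],
    background_fasta = cohort$paths[["background"]],
    gene_table = cohort$paths[["genes"]],
    matrix_tf_map = cohort$paths[["matrix_tf_map"]],
    out_dir = file.path(workdir, "out"),
    tss_offset = spec$tss_offset,
    seed = spec$seed, ...)
  res <- run_full(cfg)
  res$cohort <- cohort
  res
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis
#'
#' Stages: (1) load inputs; (2) predict EREs on target promoters, flag
#' genes, partition into the four groups and the experimental union;
#' (3) calibrate (or read) per-matrix cutoffs; (4) scan target and
#' background promoters for TFBSs; (5) compute ORI, edges and TF rankings
#' for the full target set, each group, and the experimental union, all
#' against the common background; (6) TFBS-to-ERE distance statistics on
#' ERE-bearing promoters of the experimental union and the TSS positional
#' density over all target hits; (7) per-group annotation-term fractions
#' when an annotation table is supplied. Deterministic given the config and
#' input files: re-running writes byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the result bundle: `genes`, `groups`,
#'   `experimental_union`, `profile`, `target_hits`, `background_hits`,
#'   `ere_hits`, `ori` (named list per gene set), `edges`, `rankings`,
#'   `distances`, `distance_summary`, `density`, `term_fractions`,
#'   `counts`, `paths`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)  # truncate
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- character()

  # 1. inputs
  inp <- stage("load_inputs", {
    pwms <- read_pwm_library(config$pwm_library, config$pwm_format,
                             config$pseudocount)
    targets <- read_promoters(config$target_fasta, config$tss_offset)
    background <- read_promoters(config$background_fasta, config$tss_offset)
    genes <- read_gene_table(config$gene_table, promoters = targets)
    map <- read_matrix_tf_map(config$matrix_tf_map)
    list(pwms = pwms, targets = targets, background = background,
         genes = genes, map = map)
  })
  logf("seed: %d", config$seed)
  logf("inputs: %d matrices, %d target promoters, %d background promoters, %d genes",
       length(inp$pwms), nrow(inp$targets), nrow(inp$background),
       nrow(inp$genes))

  # 2. EREs and grouping
  grp <- stage("ere_and_grouping", {
    ere_hits <- scan_ere_set(inp$targets, config$ere_max_mismatch)
    genes <- flag_ere_genes(inp$genes, ere_hits)
    genes <- assign_groups(genes)
    groups <- partition_genes(genes)
    list(ere_hits = ere_hits, genes = genes, groups = groups,
         union13 = experimental_union(groups))
  })
  paths["groups"] <- write_tsv_groups <- file.path(config$out_dir, "groups.tsv")
  write_groups_tsv(grp$genes, write_tsv_groups)
  paths["ere_bed"] <- file.path(config$out_dir, "ere_sites.bed")
  ere_for_bed <- grp$ere_hits
  ere_for_bed$score <- ere_for_bed$mismatches
  write_sites_bed(ere_for_bed, paths["ere_bed"], shift = config$tss_offset)
  sizes <- vapply(grp$groups, length, integer(1L))
  logf("ere: %d hits on %d promoters; groups (1,2,3,4) = (%s); experimental union %d genes",
       nrow(grp$ere_hits), length(unique(grp$ere_hits$promoter_id)),
       paste(sizes, collapse = ","), length(grp$union13))

  # 3. thresholds
  profile <- stage("thresholds", {
    if (!is.null(config$threshold_profile))
      read_threshold_profile(config$threshold_profile)
    else
      calibrate_profile(inp$pwms, inp$background, config$target_fp_per_kb)
  })
  paths["thresholds"] <- file.path(config$out_dir, "thresholds.tsv")
  write_threshold_profile(profile, paths["thresholds"])
  logf("thresholds: %s (median matrix cutoff %.3f)",
       if (is.null(config$threshold_profile)) "calibrated on background"
       else "read from file",
       stats::median(profile$matrix_cutoff))

  # 4. scanning
  hits <- stage("tfbs_scan", {
    list(target = scan_promoters(inp$pwms, inp$targets, profile),
         background = scan_promoters(inp$pwms, inp$background, profile))
  })
  paths["target_bed"] <- file.path(config$out_dir, "tfbs_target.bed")
  paths["background_bed"] <- file.path(config$out_dir, "tfbs_background.bed")
  write_sites_bed(hits$target, paths["target_bed"], shift = config$tss_offset)
  write_sites_bed(hits$background, paths["background_bed"],
                  shift = config$tss_offset)
  n_tfs_hit <- length(unique(unlist(inp$map[unique(hits$target$matrix_id)])))
  logf("scan: %d target TFBSs (%d matrices, %d TFs), %d background TFBSs",
       nrow(hits$target), length(unique(hits$target$matrix_id)), n_tfs_hit,
       nrow(hits$background))

  # 5. enrichment, network, ranking per gene set
  gene_sets <- c(list(full = inp$genes$gene_id), grp$groups,
                 list(experimental = grp$union13))
  names(gene_sets) <- c("full", paste0("group", 1:4), "experimental")
  enr <- stage("enrichment_network", {
    lapply(gene_sets, function(ids) {
      if (!length(ids))
        return(list(ori = NULL, edges = NULL, ranking = NULL))
      sub_genes <- inp$genes[inp$genes$gene_id %in% ids, , drop = FALSE]
      proms <- unlist(split_ids(sub_genes$promoter_ids))
      sub_prom <- inp$targets[inp$targets$promoter_id %in% proms, ,
                              drop = FALSE]
      sub_hits <- hits$target[hits$target$promoter_id %in% proms, ,
                              drop = FALSE]
      ori <- compute_ori(sub_hits, sub_prom, hits$background,
                         inp$background, config$ori_pseudocount,
                         config$ori_threshold)
      edges <- build_network(ori, sub_hits, inp$map, sub_genes)
      ranking <- if (nrow(edges)) rank_tfs(edges, config$percentile)
                 else NULL
      list(ori = ori, edges = edges, ranking = ranking)
    })
  })
  for (nm in names(enr)) {
    if (is.null(enr[[nm]]$ori)) next
    paths[paste0("ori_", nm)] <-
      write_tsv(enr[[nm]]$ori, file.path(config$out_dir,
                                         paste0("ori_", nm, ".tsv")))
    paths[paste0("edges_", nm)] <-
      write_tsv(enr[[nm]]$edges, file.path(config$out_dir,
                                           paste0("edges_", nm, ".tsv")))
    if (!is.null(enr[[nm]]$ranking))
      paths[paste0("ranking_", nm)] <-
        write_tsv(enr[[nm]]$ranking,
                  file.path(config$out_dir,
                            paste0("ranking_", nm, ".tsv")))
    logf("set %s: %d enriched matrices, %d edges, %d TFs ranked, %d retained",
         nm, sum(enr[[nm]]$ori$enriched), nrow(enr[[nm]]$edges),
         if (is.null(enr[[nm]]$ranking)) 0L else nrow(enr[[nm]]$ranking),
         if (is.null(enr[[nm]]$ranking)) 0L
         else sum(enr[[nm]]$ranking$retained))
  }

  # 6. positional statistics: distances on ERE-bearing promoters of the
  # experimentally controlled genes, density over all target hits
  stats_out <- stage("site_statistics", {
    exp_genes <- inp$genes[inp$genes$gene_id %in% grp$union13, ,
                           drop = FALSE]
    exp_proms <- unlist(split_ids(exp_genes$promoter_ids))
    exp_hits <- hits$target[hits$target$promoter_id %in% exp_proms, ,
                            drop = FALSE]
    exp_eres <- grp$ere_hits[grp$ere_hits$promoter_id %in% exp_proms, ,
                             drop = FALSE]
    recs <- tfbs_ere_distances(exp_hits, exp_eres)
    dsum <- distance_summary(recs, config$bin_width)
    dens <- if (nrow(hits$target) >= 2L) {
      # grid spans the promoter extent, e.g. [-1000, +200]
      tss_positional_density(
        hits$target, config$grid_points,
        window = c(-config$tss_offset,
                   max(nchar(inp$targets$sequence)) - config$tss_offset))
    } else NULL
    list(records = recs, summary = dsum, density = dens)
  })
  paths["distances"] <- write_tsv(stats_out$records,
                                  file.path(config$out_dir, "distances.tsv"))
  paths["distance_histogram"] <-
    write_tsv(stats_out$summary$histogram,
              file.path(config$out_dir, "distance_histogram.tsv"))
  paths["per_matrix_min"] <-
    write_tsv(stats_out$summary$per_matrix_min,
              file.path(config$out_dir, "distance_per_matrix_min.tsv"))
  if (!is.null(stats_out$density))
    paths["density"] <- write_tsv(stats_out$density,
                                  file.path(config$out_dir,
                                            "tss_density.tsv"))
  logf("distances: %d records on ERE-bearing promoters; %d matrices with a fully overlapping site",
       nrow(stats_out$records),
       sum(stats_out$summary$per_matrix_min$complete_overlap))

  # 7. term fractions
  tf_frac <- NULL
  if (!is.null(config$annotation)) {
    tf_frac <- stage("term_fractions", {
      ann <- utils::read.delim(config$annotation, stringsAsFactors = FALSE)
      out <- lapply(names(grp$groups), function(g) {
        ids <- grp$groups[[g]]
        if (!length(ids)) return(NULL)
        cbind(group = g, term_fractions(ids, ann))
      })
      do.call(rbind, c(out, list(make.row.names = FALSE)))
    })
    paths["term_fractions"] <-
      write_tsv(tf_frac, file.path(config$out_dir, "term_fractions.tsv"))
  }

  counts <- list(genes = nrow(inp$genes),
                 target_promoters = nrow(inp$targets),
                 background_promoters = nrow(inp$background),
                 ere_hits = nrow(grp$ere_hits),
                 group_sizes = sizes,
                 experimental_union = length(grp$union13),
                 target_tfbs = nrow(hits$target),
                 enriched_full = sum(enr$full$ori$enriched),
                 retained_full = if (is.null(enr$full$ranking)) 0L
                                 else sum(enr$full$ranking$retained))
  logf("summary: genes=%d promoters=%d tfbs=%d enriched=%d retained=%d",
       counts$genes, counts$target_promoters, counts$target_tfbs,
       counts$enriched_full, counts$retained_full)

  invisible(list(genes = grp$genes, groups = grp$groups,
                 experimental_union = grp$union13, profile = profile,
                 target_hits = hits$target,
                 background_hits = hits$background,
                 ere_hits = grp$ere_hits,
                 ori = lapply(enr, `[[`, "ori"),
                 edges = lapply(enr, `[[`, "edges"),
                 rankings = lapply(enr, `[[`, "ranking"),
                 distances = stats_out$records,
                 distance_summary = stats_out$summary,
                 density = stats_out$density,
                 term_fractions = tf_frac,
                 counts = counts, paths = paths))
}
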