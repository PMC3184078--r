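# Seeded synthetic cohorts: background promoters drawn i.i.d. from a base
# composition, target promoters with motif consensi planted at controlled
# rates and enrichment ratios, planted degenerate EREs, Bernoulli evidence
# flags, and a truth ledger recording every planted site and flag.

#' Specify a synthetic cohort
#'
#' Collects every knob of the generator into a validated spec. Seeded runs
#' are bit-reproducible.
#'
#' @param n_target_genes Number of target genes (one promoter each).
#' @param n_background_promoters Number of background promoters.
#' @param matrices Data.frame describing the motif panel, with columns
#'   `matrix_id`, `tf_id`, `consensus` (DNA string), `background_rate_per_kb`
#'   (expected planted sites per kb of background sequence),
#'   `target_enrichment_ratio` (planting-rate multiplier in carrier target
#'   promoters) and `fraction_of_targets_carrying` (share of target
#'   promoters planted at the enriched rate; the rest receive none).
#' @param promoter_length Promoter length in nt; default 1200.
#' @param tss_offset TSS offset within each promoter; default 1000.
#' @param base_composition Probabilities for A,C,G,T; must sum to 1.
#' @param ere_fraction_of_targets Fraction of target genes receiving a
#'   planted ERE.
#' @param evidence_rate_given_ere,evidence_rate_given_no_ere Bernoulli rates
#'   of the experimental-evidence flag conditional on ERE-carrier status.
#' @param seed Integer RNG seed.
#' @param site_mutation_prob Probability that a planted motif site carries
#'   one mutated position (so thresholded scanning is exercised, not just
#'   exact matching); default 0.1.
#' @param ere_mutation_prob Probability that a planted ERE carries one
#'   mutated half-site base; default 0.5.
#' @param deterministic If `TRUE`, carrier and evidence counts are hit
#'   exactly (rounded expectations) instead of drawn Bernoulli, and
#'   ERE-negative target promoters are resampled until they contain no ERE
#'   match at `ere_scrub_max_mismatch`, so the downstream four-group
#'   partition is exact by construction.
#' @param ere_scrub_max_mismatch Mismatch tolerance used by the
#'   deterministic-mode scrub; default 2 (the pipeline's default ERE
#'   tolerance).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_target_genes, n_background_promoters, matrices,
                        promoter_length = 1200L, tss_offset = 1000L,
                        base_composition = c(0.25, 0.25, 0.25, 0.25),
                        ere_fraction_of_targets = 0.2,
                        evidence_rate_given_ere = 0.5,
                        evidence_rate_given_no_ere = 0.25,
                        seed = 1L,
                        site_mutation_prob = 0.1,
                        ere_mutation_prob = 0.5,
                        deterministic = FALSE,
                        ere_scrub_max_mismatch = 2L) {
  matrices <- as.data.frame(matrices, stringsAsFactors = FALSE)
  need <- c("matrix_id", "tf_id", "consensus", "background_rate_per_kb",
            "target_enrichment_ratio", "fraction_of_targets_carrying")
  if (nrow(matrices) && !all(need %in% names(matrices)))
    stop("matrices must have columns ", paste(need, collapse = ", "))
  spec <- structure(
    list(n_target_genes = as.integer(n_target_genes),
         n_background_promoters = as.integer(n_background_promoters),
         promoter_length = as.integer(promoter_length),
         tss_offset = as.integer(tss_offset),
         base_composition = as.numeric(base_composition),
         matrices = matrices,
         ere_fraction_of_targets = ere_fraction_of_targets,
         evidence_rate_given_ere = evidence_rate_given_ere,
         evidence_rate_given_no_ere = evidence_rate_given_no_ere,
         seed = as.integer(seed),
         site_mutation_prob = site_mutation_prob,
         ere_mutation_prob = ere_mutation_prob,
         deterministic = isTRUE(deterministic),
         ere_scrub_max_mismatch = as.integer(ere_scrub_max_mismatch)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_target_genes < 1L || n_background_promoters < 1L)
      stop("need at least one target gene and one background promoter")
    if (length(base_composition) != 4L ||
        abs(sum(base_composition) - 1) > 1e-9 || any(base_composition < 0))
      stop("base_composition must be 4 non-negative probabilities summing to 1")
    if (tss_offset < 0L || tss_offset > promoter_length)
      stop("tss_offset outside the promoter")
    rates <- c(ere_fraction_of_targets, evidence_rate_given_ere,
               evidence_rate_given_no_ere, site_mutation_prob,
               ere_mutation_prob)
    if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
    if (nrow(matrices)) {
      if (any(matrices$background_rate_per_kb < 0) ||
          any(matrices$target_enrichment_ratio < 0) ||
          any(matrices$fraction_of_targets_carrying < 0) ||
          any(matrices$fraction_of_targets_carrying > 1))
        stop("matrix rates/ratios out of range")
      if (any(grepl("[^ACGT]", matrices$consensus)))
        stop("consensus sequences must be over A,C,G,T")
      if (anyDuplicated(matrices$matrix_id))
        stop("duplicate matrix ids in the panel")
    }
  })
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec:", x$n_target_genes, "target genes,",
      x$n_background_promoters, "background promoters of",
      x$promoter_length, "nt;", nrow(x$matrices), "matrices; seed",
      x$seed, if (x$deterministic) "(deterministic mode)" else "", "\n")
  invisible(x)
}

# Fixed motif panel for the reference-shaped cohort: 10-mers free of the
# ERE half-sites GGTCA/TGACC, pairwise distinct (also under reverse
# complement), without homopolymer runs longer than 3. The background
# planting rate (0.4 sites/kb) is chosen below the default calibration
# allowance (0.5 false positives/kb) so that the planted background signal
# never forces a matrix cutoff above the consensus score.
PANEL_CONSENSI <- c(
  "TGGACGGATC", "AGCAGAGCAC", "CTTGACTGTA", "TATACAGACG", "GGCGTTAGGG",
  "TGCTCGTGTG", "CCATACTGGG", "CGACCTGACT", "TATGTATACG", "TGACTAGCAG",
  "GCCTCGTATT", "CATGGGCCTC", "CAGTCCACAA", "TGTTAAAGAA", "AGATTCTCGG",
  "TCTTTCACGA", "CGTAACCAGG", "TAAGACTCTC", "TGATGGTCGT", "TGCTCTTAGA",
  "GTAAGTCGAA", "AATGAAGTGT", "GATTTGCGTC", "CGCCGGCCTT", "ACAGCACCTA",
  "TGGCAGACAA", "TCAGGTCCTC", "CGCGATTAAT", "CCCAGATCTC", "GAACTATTAG",
  "TGAAGAATCT", "TTCTACTTAC", "ACGCAATAGG")

#' Reference-shaped cohort spec
#'
#' A cohort mirroring the structure of the study conditions: 323 target
#' genes of which 65 carry a planted ERE (11 of them with the evidence
#' flag) and 258 do not (66 with the flag), so the four-group partition is
#' (11, 54, 66, 192) and the experimental union has 77 genes. The
#' background is 200 promoters of 1200 nt (a desk-scale stand-in for a
#' genome-wide background set). The motif panel has 33 matrices, one TF
#' each: 5 strongly enriched (0.4 sites/kb background, 4x in 80% of
#' targets), 20 moderately enriched (6x in 50%) and 8 null (1x everywhere),
#' giving an enriched TF list long enough that the 80th-percentile
#' retention rule keeps roughly the top fifth.
#'
#' @param seed Integer RNG seed for the generated cohort.
#' @param deterministic Exact group sizes by construction (default `TRUE`);
#'   see [cohort_spec()].
#' @param n_background Number of background promoters; default 200.
#' @return A [cohort_spec()].
#' @export
paper_shape_spec <- function(seed = 1L, deterministic = TRUE,
                             n_background = 200L) {
  kind <- rep(c("strong", "medium", "null"), c(5L, 20L, 8L))
  panel <- data.frame(
    matrix_id = sprintf("M%03d", seq_along(PANEL_CONSENSI)),
    tf_id = sprintf("TF%03d", seq_along(PANEL_CONSENSI)),
    consensus = PANEL_CONSENSI,
    background_rate_per_kb = 0.4,
    target_enrichment_ratio = c(strong = 4, medium = 6, null = 1)[kind],
    fraction_of_targets_carrying = c(strong = 0.8, medium = 0.5,
                                     null = 1)[kind],
    kind = kind,
    stringsAsFactors = FALSE)
  cohort_spec(n_target_genes = 323L,
              n_background_promoters = as.integer(n_background),
              matrices = panel,
              ere_fraction_of_targets = 65 / 323,
              evidence_rate_given_ere = 11 / 65,
              evidence_rate_given_no_ere = 66 / 258,
              seed = seed,
              deterministic = deterministic)
}

revcomp_string <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

random_bases <- function(n, probs) sample(DNA_BASES, n, replace = TRUE,
                                          prob = probs)

mutate_one <- function(chars, positions) {
  i <- if (length(positions) == 1L) positions else sample(positions, 1L)
  chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  chars
}

# Sample a non-overlapping start for a site of length w given an occupancy
# mask; falls back to an arbitrary position if the promoter is too crowded
# (bounded retries keep generation total).
sample_site_start <- function(occ, w) {
  len <- length(occ)
  for (try in 1:100) {
    pos <- sample.int(len - w + 1L, 1L)
    if (!any(occ[pos:(pos + w - 1L)])) return(pos)
  }
  sample.int(len - w + 1L, 1L)
}

# Build one promoter sequence: random background plus planted motif sites.
# plan: data.frame(matrix_id, consensus, rate_per_kb). Sites are planted at
# non-overlapping positions (so a planted rate means surviving sites, not
# sites later overwritten by other plantings). Returns the char vector, an
# occupancy mask, and parallel site vectors (promoter-local 0-based starts).
build_promoter_seq <- function(len, probs, plan, site_mutation_prob) {
  chars <- random_bases(len, probs)
  occ <- logical(len)
  s_mat <- character(0); s_pos <- integer(0)
  s_strand <- character(0); s_mut <- logical(0)
  if (nrow(plan)) for (r in seq_len(nrow(plan))) {
    motif <- strsplit(plan$consensus[r], "", fixed = TRUE)[[1L]]
    k <- stats::rpois(1L, plan$rate_per_kb[r] * len / 1000)
    if (!k) next
    if ((sum(occ) + k * length(motif)) > len)
      stop("planted sites for matrix ", plan$matrix_id[r],
           " exceed sequence capacity (", k, " x ", length(motif),
           " nt in ", len, " nt)")
    for (j in seq_len(k)) {
      pos <- sample_site_start(occ, length(motif))
      strand <- if (stats::runif(1L) < 0.5) "+" else "-"
      ins <- if (strand == "+") motif
             else rev(chartr("ACGT", "TGCA", motif))
      mutated <- stats::runif(1L) < site_mutation_prob
      if (mutated) ins <- mutate_one(ins, seq_along(ins))
      span <- pos:(pos + length(ins) - 1L)
      chars[span] <- ins
      occ[span] <- TRUE
      s_mat <- c(s_mat, plan$matrix_id[r])
      s_pos <- c(s_pos, pos - 1L)
      s_strand <- c(s_strand, strand)
      s_mut <- c(s_mut, mutated)
    }
  }
  list(chars = chars, occ = occ, site_matrix = s_mat, site_pos = s_pos,
       site_strand = s_strand, site_mut = s_mut)
}

# Plant one degenerate ERE (consensus with at most one mutated half-site
# base, random spacer) at a position clear of planted motif sites when
# possible. Returns updated chars plus the planted position and mismatch
# count.
plant_ere <- function(chars, occ, probs, ere_mutation_prob) {
  site <- c(strsplit(ERE_HALF_LEFT, "")[[1L]], random_bases(3L, probs),
            strsplit(ERE_HALF_RIGHT, "")[[1L]])
  mm <- 0L
  if (stats::runif(1L) < ere_mutation_prob) {
    site <- mutate_one(site, c(1:5, 9:13))
    mm <- 1L
  }
  pos <- sample_site_start(occ, 13L)
  chars[pos:(pos + 12L)] <- site
  list(chars = chars, position = pos - 1L, mismatches = mm)
}

#' Generate a synthetic cohort
#'
#' Draws every promoter, plants motif sites and EREs, assigns evidence
#' flags, and (optionally) writes the cohort to disk in the package's
#' standard formats: a JASPAR-format PWM library, target and background
#' FASTA, gene table TSV, matrix-to-TF map TSV, truth ledger TSV and the
#' spec as YAML.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory, or `NULL` to keep the cohort in memory
#'   only.
#' @return List with elements `pwms` (list of [`PWMatrix`][pwmatrix]),
#'   `targets` and `background` (promoter data.frames), `genes` (gene
#'   table), `matrix_tf_map` (named list), `truth` (ledger data.frame with
#'   columns `entity`, `id`, `promoter_id`, `position`, `attribute`),
#'   `spec`, and `paths` (named file paths when `dir` is given).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  len <- spec$promoter_length
  probs <- spec$base_composition
  panel <- spec$matrices
  nt <- spec$n_target_genes
  nb <- spec$n_background_promoters

  gene_ids <- sprintf("G%04d", seq_len(nt))
  target_prom_ids <- sprintf("P%04d", seq_len(nt))
  bg_prom_ids <- sprintf("B%04d", seq_len(nb))

  # ERE carrier and evidence assignment
  n_carrier <- round(spec$ere_fraction_of_targets * nt)
  carrier <- logical(nt)
  if (spec$deterministic) {
    carrier[sample.int(nt, n_carrier)] <- TRUE
    evidence <- logical(nt)
    ci <- which(carrier); ni <- which(!carrier)
    n_ev_c <- round(spec$evidence_rate_given_ere * length(ci))
    n_ev_n <- round(spec$evidence_rate_given_no_ere * length(ni))
    evidence[sample(ci, n_ev_c)] <- TRUE
    evidence[sample(ni, n_ev_n)] <- TRUE
  } else {
    carrier <- stats::runif(nt) < spec$ere_fraction_of_targets
    evidence <- stats::runif(nt) <
      ifelse(carrier, spec$evidence_rate_given_ere,
             spec$evidence_rate_given_no_ere)
  }

  # per-matrix carrier subsets among targets
  mat_carriers <- lapply(seq_len(nrow(panel)), function(r) {
    frac <- panel$fraction_of_targets_carrying[r]
    if (spec$deterministic) {
      idx <- sample.int(nt, round(frac * nt))
    } else {
      idx <- which(stats::runif(nt) < frac)
    }
    sort(idx)
  })

  # truth ledger accumulated as parallel vectors (one data.frame at the end)
  led <- new.env(parent = emptyenv())
  led$entity <- led$id <- led$promoter_id <- led$attribute <- list()
  led$position <- list()
  note <- function(entity, id, promoter_id, position, attribute) {
    k <- length(led$entity) + 1L
    led$entity[[k]] <- entity; led$id[[k]] <- id
    led$promoter_id[[k]] <- promoter_id; led$position[[k]] <- position
    led$attribute[[k]] <- attribute
  }
  note_sites <- function(b, prom_id) {
    if (length(b$site_matrix))
      note(rep("tfbs_site", length(b$site_matrix)), b$site_matrix,
           rep(prom_id, length(b$site_matrix)), b$site_pos,
           paste0(b$site_strand, ifelse(b$site_mut, ",mutated", "")))
  }

  bg_plan <- data.frame(matrix_id = panel$matrix_id,
                        consensus = panel$consensus,
                        rate_per_kb = panel$background_rate_per_kb,
                        stringsAsFactors = FALSE)

  # background promoters
  bg_seqs <- character(nb)
  for (i in seq_len(nb)) {
    b <- build_promoter_seq(len, probs, bg_plan, spec$site_mutation_prob)
    bg_seqs[i] <- paste(b$chars, collapse = "")
    note_sites(b, bg_prom_ids[i])
  }

  # per-target planting plans from the per-matrix carrier subsets
  carrier_mat <- matrix(FALSE, nt, nrow(panel))
  for (r in seq_len(nrow(panel))) carrier_mat[mat_carriers[[r]], r] <- TRUE

  # target promoters
  tg_seqs <- character(nt)
  for (i in seq_len(nt)) {
    rows <- which(carrier_mat[i, ])
    plan <- data.frame(
      matrix_id = panel$matrix_id[rows],
      consensus = panel$consensus[rows],
      rate_per_kb = panel$background_rate_per_kb[rows] *
        panel$target_enrichment_ratio[rows],
      stringsAsFactors = FALSE)
    repeat {
      b <- build_promoter_seq(len, probs, plan, spec$site_mutation_prob)
      if (carrier[i]) {
        e <- plant_ere(b$chars, b$occ, probs, spec$ere_mutation_prob)
        b$chars <- e$chars
        break
      } else if (spec$deterministic) {
        # reject sequences with an accidental ERE so ERE-negative genes
        # stay negative at the pipeline's mismatch tolerance
        s <- match(b$chars, DNA_BASES)
        acc <- ere_mismatch_positions(s, spec$ere_scrub_max_mismatch)
        e <- NULL
        if (!length(acc$pos)) break
      } else {
        e <- NULL
        break
      }
    }
    tg_seqs[i] <- paste(b$chars, collapse = "")
    note_sites(b, target_prom_ids[i])
    if (carrier[i])
      note("ere_site", "ERE", target_prom_ids[i], e$position,
           paste0("mismatches=", e$mismatches))
    note("gene", gene_ids[i], target_prom_ids[i], NA_integer_,
         paste0("ere_carrier=", as.integer(carrier[i]),
                ",evidence=", as.integer(evidence[i])))
  }

  targets <- data.frame(promoter_id = target_prom_ids, gene_id = gene_ids,
                        sequence = tg_seqs, tss_offset = spec$tss_offset,
                        stringsAsFactors = FALSE)
  background <- data.frame(promoter_id = bg_prom_ids,
                           gene_id = NA_character_, sequence = bg_seqs,
                           tss_offset = spec$tss_offset,
                           stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = gene_ids, promoter_ids = target_prom_ids,
                      evidence = evidence, ere_predicted = NA,
                      group = NA_integer_, stringsAsFactors = FALSE)
  pwms <- lapply(seq_len(nrow(panel)), function(r)
    consensus_pwm(panel$matrix_id[r], panel$consensus[r],
                  tf_ids = panel$tf_id[r]))
  names(pwms) <- panel$matrix_id
  map <- as.list(panel$tf_id)
  names(map) <- panel$matrix_id
  truth <- data.frame(entity = unlist(led$entity),
                      id = unlist(led$id),
                      promoter_id = unlist(led$promoter_id),
                      position = unlist(led$position),
                      attribute = unlist(led$attribute),
                      stringsAsFactors = FALSE)

  out <- list(pwms = pwms, targets = targets, background = background,
              genes = genes, matrix_tf_map = map, truth = truth,
              spec = spec, paths = NULL)
  if (!is.null(dir)) out$paths <- write_cohort(out, dir)
  out
}

#' One-hot PWM from a consensus string
#'
#' Builds a [`PWMatrix`][pwmatrix] whose counts put weight `scale` on the
#' consensus base at every position.
#'
#' @param matrix_id Matrix identifier.
#' @param consensus DNA string over A,C,G,T, length at least 5.
#' @param tf_ids TF ids associated with the matrix.
#' @param scale Count given to the consensus base; default 12.
#' @param pseudocount Passed to [pwmatrix()].
#' @export
consensus_pwm <- function(matrix_id, consensus, tf_ids = character(),
                          scale = 12, pseudocount = 0.01) {
  s <- encode_dna(consensus, "consensus")
  counts <- matrix(0, length(s), 4L)
  counts[cbind(seq_along(s), s)] <- scale
  pwmatrix(matrix_id, counts, tf_ids = tf_ids, pseudocount = pseudocount)
}

#' Write a PWM library in JASPAR PFM format
#'
#' @param pwms List of [`PWMatrix`][pwmatrix] objects.
#' @param path Output path.
#' @export
write_pwm_library_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$matrix_id, " ",
                      paste(p$tf_ids, collapse = ";")), con)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(p$counts[, b], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Write a cohort to disk
#'
#' @param cohort Cohort list from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pwm_library = file.path(dir, "pwm_library.jaspar"),
             targets = file.path(dir, "targets.fa"),
             background = file.path(dir, "background.fa"),
             genes = file.path(dir, "genes.tsv"),
             matrix_tf_map = file.path(dir, "matrix_tf_map.tsv"),
             truth = file.path(dir, "truth.tsv"),
             spec = file.path(dir, "cohort_spec.yaml"))
  write_pwm_library_jaspar(cohort$pwms, paths["pwm_library"])
  write_promoters(cohort$targets, paths["targets"])
  write_promoters(cohort$background, paths["background"])
  utils::write.table(
    data.frame(gene_id = cohort$genes$gene_id,
               promoter_ids = cohort$genes$promoter_ids,
               evidence = as.integer(cohort$genes$evidence)),
    paths["genes"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(matrix_id = names(cohort$matrix_tf_map),
               tf_ids = vapply(cohort$matrix_tf_map, paste,
                               character(1L), collapse = ",")),
    paths["matrix_tf_map"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  write_cohort_spec(cohort$spec, paths["spec"])
  paths
}

#' Read / write a cohort spec as YAML
#'
#' The round trip is lossless: `read_cohort_spec(write_cohort_spec(s))`
#' reproduces `s`.
#'
#' @param spec A [cohort_spec()].
#' @param path YAML path.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$matrices <- as.list(x$matrices)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  mats <- as.data.frame(x$matrices, stringsAsFactors = FALSE)
  cohort_spec(n_target_genes = x$n_target_genes,
              n_background_promoters = x$n_background_promoters,
              matrices = mats,
              promoter_length = x$promoter_length,
              tss_offset = x$tss_offset,
              base_composition = x$base_composition,
              ere_fraction_of_targets = x$ere_fraction_of_targets,
              evidence_rate_given_ere = x$evidence_rate_given_ere,
              evidence_rate_given_no_ere = x$evidence_rate_given_no_ere,
              seed = x$seed,
              site_mutation_prob = x$site_mutation_prob,
              ere_mutation_prob = x$ere_mutation_prob,
              deterministic = x$deterministic,
              ere_scrub_max_mismatch = x$ere_scrub_max_mismatch)
}
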