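no_matrix_spec <- function(seed, n_targets = 20L, n_bg = 10L, ...) {
  cohort_spec(n_target_genes = n_targets, n_background_promoters = n_bg,
              matrices = data.frame(), seed = seed, ...)
}

test_that("seeded generation is bit-reproducible", {
  a <- generate_cohort(no_matrix_spec(7, n_targets = 5L, n_bg = 10L))
  b <- generate_cohort(no_matrix_spec(7, n_targets = 5L, n_bg = 10L))
  expect_identical(a$background$sequence, b$background$sequence)
  expect_identical(a$targets$sequence, b$targets$sequence)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(no_matrix_spec(8, n_targets = 5L, n_bg = 10L))
  expect_false(identical(a$background$sequence, c2$background$sequence))
  expect_equal(nchar(a$background$sequence), rep(1200L, 10L))
})

test_that("planting at high rate in all targets shows up in the truth ledger", {
  panel <- data.frame(matrix_id = "M1", tf_id = "TF1",
                      consensus = "TGGACGGATC",
                      background_rate_per_kb = 0,
                      target_enrichment_ratio = 1,
                      fraction_of_targets_carrying = 1,
                      stringsAsFactors = FALSE)
  # rate 0 background x ratio 1 plants nothing; use a background rate with
  # ratio boosting targets instead
  panel$background_rate_per_kb <- 5
  panel$fraction_of_targets_carrying <- 1
  spec <- cohort_spec(20L, 10L, panel, seed = 3)
  co <- generate_cohort(spec)
  planted <- co$truth[co$truth$entity == "tfbs_site" &
                        co$truth$id == "M1" &
                        grepl("^P", co$truth$promoter_id), ]
  expect_gte(nrow(planted), 20L)
  # the consensus really sits at the recorded positions (unmutated sites)
  clean <- planted[!grepl("mutated", planted$attribute), ]
  i <- which.max(clean$position)
  seqc <- co$targets$sequence[co$targets$promoter_id == clean$promoter_id[i]]
  insert <- substr(seqc, clean$position[i] + 1, clean$position[i] + 10)
  expect_true(insert == "TGGACGGATC" || insert == rc("TGGACGGATC"))
})

test_that("planting beyond sequence capacity errors", {
  panel <- data.frame(matrix_id = "M1", tf_id = "TF1",
                      consensus = "TGGACGGATC",
                      background_rate_per_kb = 500,
                      target_enrichment_ratio = 1,
                      fraction_of_targets_carrying = 1,
                      stringsAsFactors = FALSE)
  spec <- cohort_spec(2L, 2L, panel, promoter_length = 300L,
                      tss_offset = 100L, seed = 1)
  expect_error(generate_cohort(spec), "capacity")
})

test_that("ERE carrier counts equal an independent recount of the ledger", {
  spec <- no_matrix_spec(11, n_targets = 100L, n_bg = 5L,
                         ere_fraction_of_targets = 0.2,
                         deterministic = FALSE)
  co <- generate_cohort(spec)
  ledger_carriers <- unique(co$truth$promoter_id[co$truth$entity == "ere_site"])
  flag_carriers <- co$truth$promoter_id[co$truth$entity == "gene" &
                                  grepl("ere_carrier=1", co$truth$attribute)]
  expect_setequal(ledger_carriers, flag_carriers)
  # every recorded ERE is findable at the planted position within 1 mismatch
  eres <- co$truth[co$truth$entity == "ere_site", ]
  for (r in seq_len(nrow(eres))) {
    p <- co$targets[co$targets$promoter_id == eres$promoter_id[r], ]
    hits <- scan_ere(p, max_mismatch = 1)
    expect_true((eres$position[r] - p$tss_offset[1]) %in% hits$start)
  }
})

test_that("the reference-shaped cohort partitions exactly in deterministic mode", {
  co <- generate_cohort(paper_shape_spec(seed = 19))
  genes <- flag_ere_genes(co$genes, scan_ere_set(co$targets, 2))
  groups <- partition_genes(genes)
  expect_equal(lengths(groups),
               c("1" = 11L, "2" = 54L, "3" = 66L, "4" = 192L))
  expect_length(experimental_union(groups), 77L)
})

test_that("stochastic mode hits the group-1 size in expectation", {
  sizes <- vapply(1:50, function(s) {
    co <- generate_cohort(no_matrix_spec(
      s, n_targets = 323L, n_bg = 1L,
      ere_fraction_of_targets = 65 / 323,
      evidence_rate_given_ere = 11 / 65,
      evidence_rate_given_no_ere = 66 / 258,
      deterministic = FALSE))
    carrier <- co$truth$promoter_id[co$truth$entity == "gene" &
                                grepl("ere_carrier=1", co$truth$attribute)]
    genes <- co$genes
    genes$ere_predicted <- genes$promoter_ids %in% carrier
    length(partition_genes(genes)[["1"]])
  }, numeric(1))
  expect_lt(abs(mean(sizes) - 11), 2)
})

test_that("cohort specs round-trip through YAML losslessly", {
  spec <- paper_shape_spec(seed = 5)
  f <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, f)
  back <- read_cohort_spec(f)
  expect_equal(back, spec, tolerance = 1e-12)
})

test_that("written cohorts reload into the same objects", {
  d <- tempfile("cohort")
  spec <- cohort_spec(6L, 10L, data.frame(
    matrix_id = c("M1", "M2"), tf_id = c("T1", "T2"),
    consensus = c("TGGACGGATC", "AGCAGAGCAC"),
    background_rate_per_kb = 1, target_enrichment_ratio = 4,
    fraction_of_targets_carrying = 0.5, stringsAsFactors = FALSE),
    seed = 23)
  co <- generate_cohort(spec, dir = d)
  expect_true(all(file.exists(co$paths)))
  targets <- read_promoters(co$paths[["targets"]], spec$tss_offset)
  expect_equal(targets, co$targets, ignore_attr = TRUE)
  pwms <- read_pwm_library(co$paths[["pwm_library"]], "jaspar")
  expect_equal(names(pwms), c("M1", "M2"))
  expect_equal(pwms$M1$freqs, co$pwms$M1$freqs, tolerance = 1e-12)
  genes <- read_gene_table(co$paths[["genes"]], promoters = targets)
  expect_equal(genes$evidence, co$genes$evidence)
})

test_that("the empirical ORI of a planted matrix tracks the planted ratios as the cohort grows", {
  run_one <- function(n_t, n_b, seed) {
    panel <- data.frame(matrix_id = "M1", tf_id = "T1",
                        consensus = "TGGACGGATC",
                        background_rate_per_kb = 1,
                        target_enrichment_ratio = 4,
                        fraction_of_targets_carrying = 1,
                        stringsAsFactors = FALSE)
    spec <- cohort_spec(n_t, n_b, panel, seed = seed,
                        ere_fraction_of_targets = 0)
    co <- generate_cohort(spec)
    # consensus-only cutoffs so the measured densities are the planted ones
    prof <- data.frame(matrix_id = "M1", core_cutoff = 0.99,
                       matrix_cutoff = 0.999)
    th <- scan_promoters(co$pwms, co$targets, prof)
    bh <- scan_promoters(co$pwms, co$background, prof)
    compute_ori(th, co$targets, bh, co$background)$ori
  }
  # planted densities: 4/kb in targets vs 1/kb in background, thinned by
  # the 10% per-site mutation rate that pushes a site below the consensus
  # cutoff; expected coverages from the Poisson planting model (1.2 kb)
  lam_t <- 4 * 1.2 * 0.9
  lam_b <- 1 * 1.2 * 0.9
  predicted <- 4 * (1 - exp(-lam_t)) / (1 - exp(-lam_b))
  small <- run_one(40L, 30L, seed = 41)
  large <- run_one(160L, 120L, seed = 42)
  expect_lt(abs(large - predicted) / predicted, 0.2)
  # the two-point check: growing the cohort 4x moves the estimate no
  # further from the planted value
  expect_lte(abs(large - predicted), abs(small - predicted) + 0.2 * predicted)
})
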