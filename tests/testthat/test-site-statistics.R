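mk_tfbs <- function(promoter_id, start, end, matrix_id = "M1") {
  data.frame(matrix_id = matrix_id, promoter_id = promoter_id,
             start = as.integer(start), end = as.integer(end),
             strand = "+", mss = 0.9, css = 0.9, stringsAsFactors = FALSE)
}

mk_ere <- function(promoter_id, start) {
  data.frame(promoter_id = promoter_id, start = as.integer(start),
             end = as.integer(start) + 13L, strand = "+", mismatches = 0L,
             stringsAsFactors = FALSE)
}

test_that("interval gaps and containment behave as defined", {
  tf <- mk_tfbs("P1", 10, 20)
  ere <- mk_ere("P1", 40)  # [40, 53)
  rec <- tfbs_ere_distances(tf, ere)
  expect_equal(rec$distance, 20L)
  expect_false(rec$complete_overlap)
  inside <- tfbs_ere_distances(mk_tfbs("P1", 45, 50), mk_ere("P1", 40))
  expect_equal(inside$distance, 0L)
  expect_true(inside$complete_overlap)
  # intersection without containment: distance 0 but not complete overlap
  straddle <- tfbs_ere_distances(mk_tfbs("P1", 35, 45), mk_ere("P1", 40))
  expect_equal(straddle$distance, 0L)
  expect_false(straddle$complete_overlap)
  # promoters without an ERE contribute nothing
  none <- tfbs_ere_distances(mk_tfbs("P2", 0, 10), mk_ere("P1", 40))
  expect_equal(nrow(none), 0L)
})

test_that("each TFBS pairs with its closest ERE (all-pairs oracle), ties to the smaller start", {
  set.seed(31)
  for (rep in 1:4) {
    proms <- paste0("P", 1:3)
    tf <- do.call(rbind, lapply(1:25, function(i) {
      s <- sample(0:500, 1)
      mk_tfbs(sample(proms, 1), s, s + sample(6:15, 1),
              matrix_id = paste0("M", sample(1:4, 1)))
    }))
    ere <- do.call(rbind, lapply(1:6, function(i)
      mk_ere(sample(proms, 1), sample(0:500, 1))))
    recs <- tfbs_ere_distances(tf, ere)
    for (r in seq_len(nrow(recs))) {
      e_p <- ere[ere$promoter_id == recs$promoter_id[r], ]
      gaps <- vapply(seq_len(nrow(e_p)), function(k)
        oracle_gap(recs$tfbs_start[r], recs$tfbs_end[r],
                   e_p$start[k], e_p$end[k]), integer(1))
      expect_equal(recs$distance[r], min(gaps))
      winners <- e_p$start[gaps == min(gaps)]
      expect_equal(recs$ere_start[r], min(winners))
    }
    # per-promoter pairwise gap multiset is symmetric in the two roles
    for (p in unique(recs$promoter_id)) {
      tf_p <- tf[tf$promoter_id == p, ]
      e_p <- ere[ere$promoter_id == p, ]
      g1 <- sort(as.vector(outer(seq_len(nrow(tf_p)), seq_len(nrow(e_p)),
        Vectorize(function(i, k) oracle_gap(tf_p$start[i], tf_p$end[i],
                                            e_p$start[k], e_p$end[k])))))
      g2 <- sort(as.vector(outer(seq_len(nrow(e_p)), seq_len(nrow(tf_p)),
        Vectorize(function(k, i) oracle_gap(e_p$start[k], e_p$end[k],
                                            tf_p$start[i], tf_p$end[i])))))
      expect_equal(g1, g2)
    }
  }
})

test_that("distance histograms bin, accumulate and conserve counts", {
  recs <- data.frame(matrix_id = c("M1", "M1", "M2", "M3"),
                     promoter_id = "P1", tfbs_start = 0L, tfbs_end = 1L,
                     ere_start = 0L, ere_end = 1L,
                     distance = c(0L, 0L, 20L, 95L),
                     complete_overlap = c(TRUE, TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  s <- distance_summary(recs, bin_width = 50L)
  expect_equal(s$histogram$count[1], 3L)  # [0, 50)
  expect_equal(s$histogram$count[2], 1L)  # [50, 100)
  expect_equal(tail(s$histogram$cumulative, 1), 4L)
  expect_true(all(diff(s$histogram$cumulative) >= 0))
  expect_equal(sum(s$histogram$count), nrow(recs))
  expect_equal(s$per_matrix_min$min_distance,
               c(0L, 20L, 95L))
  expect_equal(s$per_matrix_min$complete_overlap, c(TRUE, FALSE, FALSE))
  empty <- distance_summary(recs[0, ])
  expect_equal(nrow(empty$histogram), 0L)
  # random recount oracle
  set.seed(32)
  rr <- recs[sample(1:4, 40, TRUE), ]
  rr$distance <- sample(0:300, 40, TRUE)
  s2 <- distance_summary(rr, 50L)
  want <- as.integer(table(cut(rr$distance,
                               c(s2$histogram$bin_start,
                                 max(s2$histogram$bin_end)),
                               right = FALSE)))
  expect_equal(s2$histogram$count, want)
})

test_that("the TSS density integrates to 1, is symmetric, and matches direct kernel sums", {
  # point mass: argmax at the grid point nearest the hits
  h <- mk_tfbs("P1", rep(-105, 3), rep(-95, 3))
  d <- tss_positional_density(h, grid_points = 512, bandwidth = 30)
  expect_equal(d$position[which.max(d$density)],
               d$position[which.min(abs(d$position + 100))])
  expect_equal(sum(diff(d$position) *
                     (head(d$density, -1) + tail(d$density, -1)) / 2),
               1, tolerance = 1e-3)
  # symmetry about -400
  mids <- c(-500, -450, -400, -350, -300)
  hs <- mk_tfbs("P1", mids - 5, mids + 5)
  ds <- tss_positional_density(hs, grid_points = 481, bandwidth = 25,
                               window = c(-640, -160))
  expect_equal(ds$density, rev(ds$density), tolerance = 1e-9)
  # seeded sample vs direct kernel-sum evaluation at probe points, and
  # against the R density estimator as an independent cross-check
  set.seed(33)
  mids2 <- round(runif(200, -900, 100))
  h2 <- mk_tfbs("P1", mids2 - 5, mids2 + 5)
  bw <- 40
  d2 <- tss_positional_density(h2, grid_points = 512, bandwidth = bw)
  probes <- sample(seq_len(512), 10)
  for (i in probes) {
    direct <- mean(dnorm(d2$position[i], mean = mids2, sd = bw))
    expect_equal(d2$density[i], direct, tolerance = 1e-12)
  }
  ref <- stats::density(mids2, bw = bw, n = 512, from = -1000, to = 200)
  expect_equal(d2$density, ref$y, tolerance = 1e-3)
  expect_error(tss_positional_density(h2[1, ]), "at least 2")
})

test_that("term fractions count annotated genes over the group size", {
  genes11 <- sprintf("G%02d", 1:11)
  ann <- data.frame(gene_id = c(genes11[1:5], "G01", "G20"),
                    term = c(rep("kinase activity", 5),
                             "nucleotide binding", "kinase activity"),
                    stringsAsFactors = FALSE)
  tf <- term_fractions(genes11, ann)
  ka <- tf[tf$term == "kinase activity", ]
  expect_equal(ka$n_genes, 5L)       # G20 is outside the group
  expect_equal(ka$fraction, 0.45)
  expect_equal(ka$percent, 45)
  expect_equal(tf$percent[tf$term == "nucleotide binding"], 9)
  none <- term_fractions(genes11, ann[ann$term == "absent", ])
  expect_equal(nrow(none), 0L)
  all_ann <- term_fractions(genes11,
                            data.frame(gene_id = genes11, term = "t"))
  expect_equal(all_ann$percent, 100)
  expect_error(term_fractions(character(0), ann), "empty")
})
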