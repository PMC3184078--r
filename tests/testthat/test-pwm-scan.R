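one_hot <- function(id, consensus, pseudocount = 0) {
  s <- match(strsplit(consensus, "")[[1L]], BASES)
  counts <- matrix(0, length(s), 4)
  counts[cbind(seq_along(s), s)] <- 10
  pwmatrix(id, counts, pseudocount = pseudocount)
}

test_that("information vector hits its limits and hand-computed values", {
  m <- one_hot("M", "AAAAA")
  expect_equal(m$info, rep(log(4), 5))
  expect_equal(information_vector(matrix(0.25, 1, 4)), 0)
  expect_equal(information_vector(matrix(c(0.5, 0.5, 0, 0), 1, 4)), log(2))
  expect_error(information_vector(matrix(c(-0.1, 0.5, 0.3, 0.3), 1, 4)),
               "negative")
})

test_that("mss is 1 on consensus, 0 on anti-consensus, ordered as the formula says", {
  counts <- matrix(c(0.7, 0.1, 0.1, 0.1), 5, 4, byrow = TRUE) * 20
  m <- pwmatrix("M", counts, pseudocount = 0)
  expect_equal(mss_score(m, "AAAAA"), 1)
  # all min-frequency bases -> 0 (ties on C/G/T; any is minimal)
  expect_equal(mss_score(m, "CCCCC"), 0)
  expect_lt(mss_score(m, "AAAAC"), mss_score(m, "AAAAA"))
  # brute-force over all 4^5 windows: equality with the direct evaluation,
  # and range [0,1]
  wins <- apply(expand.grid(rep(list(BASES), 5)), 1, paste, collapse = "")
  got <- vapply(wins, function(w) mss_score(m, w), numeric(1))
  want <- vapply(wins, function(w) oracle_mss(m, w), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
  expect_error(mss_score(m, "AAAA"), "length")
})

test_that("fully uniform matrix scores 1 everywhere (Max = Min convention)", {
  m <- pwmatrix("U", matrix(5, 6, 4), pseudocount = 0)
  expect_equal(mss_score(m, "ACGTAC"), 1)
  expect_equal(core_window(m), 0L)  # tie-break at the smallest start
})

test_that("core window maximizes summed information, ties to smallest start", {
  counts <- matrix(1, 10, 4)
  counts[4:8, ] <- 0.01
  counts[cbind(4:8, c(1, 2, 3, 4, 1))] <- 10
  m <- pwmatrix("M", counts, pseudocount = 0)
  expect_equal(core_window(m), 3L)
  set.seed(42)
  for (i in 1:10) {
    r <- rand_pwm(paste0("R", i), 12)
    expect_equal(core_window(r), oracle_core_start(r))
  }
})

test_that("scanning finds a planted consensus site and counts windows without thresholds", {
  m <- one_hot("M", "ACGTA")
  p <- prom(paste0(strrep("C", 40), "ACGTA", strrep("G", 55)))
  prof <- data.frame(matrix_id = "M", core_cutoff = 0.9, matrix_cutoff = 0.9)
  hits <- scan_promoter(m, p, prof)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 40L)
  expect_equal(hits$end, 45L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mss, 1)
  prof0 <- data.frame(matrix_id = "M", core_cutoff = 0, matrix_cutoff = 0)
  expect_equal(nrow(scan_promoter(m, p, prof0)), 2L * (100L - 5L + 1L))
})

test_that("scan output equals the brute-force window oracle on random instances", {
  set.seed(101)
  for (i in 1:6) {
    L <- sample(6:10, 1)
    m <- rand_pwm(paste0("M", i), L)
    seqc <- rand_seq(sample(80:200, 1))
    if (i %% 2 == 0) {  # inject Ns to exercise window skipping
      pos <- sample(nchar(seqc), 3)
      for (q in pos) substr(seqc, q, q) <- "N"
    }
    p <- prom(seqc, tss_offset = 50L)
    cc <- stats::runif(1, 0.5, 0.8)
    mc <- stats::runif(1, 0.6, 0.9)
    prof <- data.frame(matrix_id = m$matrix_id, core_cutoff = cc,
                       matrix_cutoff = mc)
    got <- scan_promoter(m, p, prof)
    want <- oracle_scan(m, p, cc, mc)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("vectorized promoter-set scan equals per-promoter scanning", {
  set.seed(202)
  pwms <- lapply(1:3, function(i) rand_pwm(paste0("M", i), 7 + i))
  proms <- do.call(rbind, lapply(1:5, function(i)
    prom(rand_seq(150), promoter_id = paste0("P", i),
         gene_id = paste0("G", i), tss_offset = 100L)))
  prof <- data.frame(matrix_id = paste0("M", 1:3), core_cutoff = 0.6,
                     matrix_cutoff = 0.75)
  got <- scan_promoters(pwms, proms, prof)
  want <- do.call(rbind, lapply(pwms, function(m)
    do.call(rbind, lapply(1:5, function(i)
      scan_promoter(m, proms[i, ], prof)))))
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("strand symmetry: scanning the reverse complement mirrors the hit set", {
  set.seed(303)
  m <- rand_pwm("M", 8)
  seqc <- rand_seq(160)
  p <- prom(seqc, tss_offset = 0L)
  p_rc <- prom(rc(seqc), tss_offset = 0L)
  prof <- data.frame(matrix_id = "M", core_cutoff = 0.6,
                     matrix_cutoff = 0.75)
  fwd <- scan_promoter(m, p, prof)
  rev <- scan_promoter(m, p_rc, prof)
  n <- nchar(seqc)
  mirrored <- data.frame(start = n - rev$end, end = n - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         mss = rev$mss, css = rev$css)
  ord <- function(d) d[order(d$start, d$strand), ]
  expect_equal(ord(fwd[c("start", "end", "strand", "mss", "css")]),
               ord(mirrored), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("raising cutoffs never adds hits and all scores stay in [0,1]", {
  set.seed(404)
  m <- rand_pwm("M", 9)
  p <- prom(rand_seq(300))
  cuts <- seq(0, 1, by = 0.25)
  prev <- Inf
  for (ct in cuts) {
    prof <- data.frame(matrix_id = "M", core_cutoff = ct * 0.9,
                       matrix_cutoff = ct)
    h <- scan_promoter(m, p, prof)
    expect_true(all(h$mss >= 0 & h$mss <= 1 & h$css >= 0 & h$css <= 1))
    expect_lte(nrow(h), prev)
    prev <- nrow(h)
  }
})

test_that("background calibration matches an independent quantile computation", {
  set.seed(505)
  bg <- do.call(rbind, lapply(1:12, function(i)
    prom(rand_seq(1000), promoter_id = paste0("B", i))))
  m <- one_hot("M8", "ACGTACGT", pseudocount = 0.01)
  # boundary: a target large enough to admit every window
  cut_all <- calibrate_min_fp(m, bg, target_fp_per_kb = 1e9)
  scores <- oracle_background_scores(m, bg)
  expect_equal(unname(cut_all["matrix_cutoff"]), min(scores),
               tolerance = 1e-12)
  # boundary: zero tolerated false positives -> cutoff just above the max
  cut0 <- calibrate_min_fp(m, bg, target_fp_per_kb = 0)
  expect_gt(cut0["matrix_cutoff"], max(scores))
  # 0.1/kb on 12 kb allows one background hit; the cutoff is the smallest
  # score level whose tail count stays within that allowance (just above
  # the maximum when even the top score level is too populous)
  cut <- calibrate_min_fp(m, bg, target_fp_per_kb = 0.1)
  k <- floor(0.1 * 12)
  u <- sort(unique(scores), decreasing = TRUE)
  cnt <- vapply(u, function(v) sum(scores >= v), integer(1))
  want <- if (any(cnt <= k)) min(u[cnt <= k]) else max(scores) + 1e-9
  expect_equal(unname(cut["matrix_cutoff"]), want, tolerance = 1e-9)
  expect_lte(sum(scores >= cut["matrix_cutoff"]), k)
  # monotone: larger tolerated density, never a larger cutoff
  cuts <- vapply(c(0, 0.1, 0.5, 2, 10),
                 function(t) calibrate_min_fp(m, bg, t)["matrix_cutoff"],
                 numeric(1))
  expect_true(all(diff(cuts) <= 1e-12))
})
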