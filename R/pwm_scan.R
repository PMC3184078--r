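# Match-style promoter scanning: both strands, matrix + core similarity
# scores, per-matrix cutoffs, and background-quantile threshold calibration
# standing in for vendor minFP profiles.

profile_cutoffs <- function(profile, matrix_id) {
  i <- match(matrix_id, profile$matrix_id)
  if (is.na(i))
    stop("threshold profile has no entry for matrix ", matrix_id)
  c(core = profile$core_cutoff[i], matrix = profile$matrix_cutoff[i])
}

empty_hits <- function() {
  data.frame(matrix_id = character(), promoter_id = character(),
             start = integer(), end = integer(), strand = character(),
             mss = numeric(), css = numeric(), stringsAsFactors = FALSE)
}

# Scan one context with one matrix on both strands. Returns window starts
# (1-based within the sequence), strand, mss, css for windows passing both
# cutoffs. Windows containing N never score.
scan_encoded <- function(pwm, ctx, core_cutoff, matrix_cutoff) {
  fwd <- strand_hits(pwm$freqs, pwm$info, pwm$core_start, ctx,
                     core_cutoff, matrix_cutoff)
  rcp <- revcomp_pwm_parts(pwm$freqs, pwm$info, pwm$core_start)
  rev <- strand_hits(rcp$freqs, rcp$info, rcp$core_start, ctx,
                     core_cutoff, matrix_cutoff)
  data.frame(window = c(fwd$window, rev$window),
             strand = rep(c("+", "-"),
                          c(length(fwd$window), length(rev$window))),
             mss = c(fwd$mss, rev$mss),
             css = c(fwd$css, rev$css),
             stringsAsFactors = FALSE)
}

#' Scan a promoter with one PWM
#'
#' Slides the matrix over both strands of the promoter (the minus strand
#' scores the reverse complement of each window; reported coordinates stay
#' on the forward strand) and emits every window whose core similarity score
#' reaches the core cutoff and whose matrix similarity score reaches the
#' matrix cutoff. Windows containing N are skipped. Hits are sorted by start
#' then strand (`+` before `-`). Coordinates are 0-based half-open,
#' promoter-relative (TSS at 0).
#'
#' @param pwm A [`PWMatrix`][pwmatrix].
#' @param promoter One promoter: a one-row data.frame (or list) with
#'   `promoter_id`, `sequence` and `tss_offset`.
#' @param profile Threshold profile data.frame (`matrix_id`, `core_cutoff`,
#'   `matrix_cutoff`) containing this matrix.
#' @return Data.frame of site hits: `matrix_id`, `promoter_id`, `start`,
#'   `end`, `strand`, `mss`, `css`.
#' @export
scan_promoter <- function(pwm, promoter, profile) {
  cut <- profile_cutoffs(profile, pwm$matrix_id)
  s <- encode_dna(promoter$sequence[[1L]], promoter$promoter_id[[1L]])
  hits <- scan_encoded(pwm, make_scan_context(s), cut["core"], cut["matrix"])
  L <- nrow(pwm$freqs)
  out <- data.frame(matrix_id = rep(pwm$matrix_id, nrow(hits)),
                    promoter_id = rep(promoter$promoter_id[[1L]], nrow(hits)),
                    start = hits$window - 1L - as.integer(promoter$tss_offset[[1L]]),
                    end = hits$window - 1L - as.integer(promoter$tss_offset[[1L]]) + L,
                    strand = hits$strand,
                    mss = hits$mss, css = hits$css,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Concatenate all promoter sequences with N spacers so one vectorized pass
# per matrix scans the whole set; windows spanning a junction contain N and
# are dropped, so results equal per-promoter scanning.
concat_promoters <- function(promoters, gap = 30L) {
  n <- nrow(promoters)
  lens <- nchar(promoters$sequence)
  starts <- cumsum(c(1L, lens[-n] + gap))
  joined <- paste(promoters$sequence,
                  collapse = strrep("N", gap))
  list(s = encode_dna(joined, "promoter set"), starts = starts, lens = lens)
}

#' Scan a promoter set with a PWM library
#'
#' Vectorized equivalent of calling [scan_promoter()] for every matrix and
#' promoter; output rows are ordered by matrix, then promoter (input order),
#' then start, then strand.
#'
#' @param pwms List of [`PWMatrix`][pwmatrix] objects.
#' @param promoters Promoter data.frame ([read_promoters()]).
#' @param profile Threshold profile covering all matrices.
#' @return Data.frame of site hits (see [scan_promoter()]).
#' @export
scan_promoters <- function(pwms, promoters, profile) {
  if (inherits(pwms, "PWMatrix")) pwms <- list(pwms)
  maxL <- max(vapply(pwms, function(p) nrow(p$freqs), integer(1L)))
  cp <- concat_promoters(promoters, gap = maxL + 5L)
  ctx <- make_scan_context(cp$s)
  res <- lapply(pwms, function(pwm) {
    cut <- profile_cutoffs(profile, pwm$matrix_id)
    hits <- scan_encoded(pwm, ctx, cut["core"], cut["matrix"])
    if (!nrow(hits)) return(empty_hits())
    # map concatenated window starts back to promoter + local offset
    idx <- findInterval(hits$window, cp$starts)
    local <- hits$window - cp$starts[idx]  # 0-based within promoter
    L <- nrow(pwm$freqs)
    out <- data.frame(matrix_id = rep(pwm$matrix_id, nrow(hits)),
                      promoter_id = promoters$promoter_id[idx],
                      start = local - as.integer(promoters$tss_offset[idx]),
                      end = local - as.integer(promoters$tss_offset[idx]) + L,
                      strand = hits$strand,
                      mss = hits$mss, css = hits$css,
                      stringsAsFactors = FALSE)
    out[order(idx, out$start, out$strand), , drop = FALSE]
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Calibrate per-matrix cutoffs from background promoters
#'
#' Emulates a minFP-style threshold: the matrix cutoff is the smallest
#' observed background score `s` such that the density of background windows
#' scoring at least `s` does not exceed `target_fp_per_kb` hits per kb of
#' background sequence (both strands' hits counted against sequence length).
#' With a target of 0 the cutoff is placed just above the maximum background
#' score. The core cutoff is a fixed fraction of the matrix cutoff
#' (default 0.9, capped at 1). Larger targets never yield larger cutoffs.
#'
#' @param pwm A [`PWMatrix`][pwmatrix].
#' @param background Background promoter data.frame; total sequence length
#'   must be at least 10 kb.
#' @param target_fp_per_kb Tolerated background hit density; default 0.5/kb.
#' @param core_fraction Core cutoff as a fraction of the matrix cutoff.
#' @return Named numeric vector `c(core_cutoff, matrix_cutoff)`.
#' @export
calibrate_min_fp <- function(pwm, background, target_fp_per_kb = 0.5,
                             core_fraction = 0.9, .ctx = NULL) {
  if (is.null(background) || !nrow(background))
    stop("empty background promoter set")
  total_kb <- sum(nchar(background$sequence)) / 1000
  if (total_kb < 10)
    stop("background too small for calibration: ", round(total_kb, 2),
         " kb < 10 kb")
  if (target_fp_per_kb < 0) stop("target_fp_per_kb must be non-negative")
  if (is.null(.ctx)) {
    cp <- concat_promoters(background, gap = nrow(pwm$freqs) + 5L)
    .ctx <- make_scan_context(cp$s)
  }
  rcp <- revcomp_pwm_parts(pwm$freqs, pwm$info, pwm$core_start)
  scores <- c(strand_scores(pwm$freqs, pwm$info, pwm$core_start, .ctx,
                            need_css = FALSE)$mss,
              strand_scores(rcp$freqs, rcp$info, rcp$core_start, .ctx,
                            need_css = FALSE)$mss)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("background yields no scoreable windows")
  k <- floor(target_fp_per_kb * total_kb)  # admissible background hits
  matrix_cutoff <- if (k >= length(scores)) {
    min(scores)
  } else {
    u <- sort(unique(scores), decreasing = TRUE)
    counts <- cumsum(tabulate(match(scores, u), nbins = length(u)))
    ok <- which(counts <= k)
    if (length(ok)) u[max(ok)] else max(scores) + 1e-9
  }
  c(core_cutoff = min(1, core_fraction * matrix_cutoff),
    matrix_cutoff = matrix_cutoff)
}

#' Calibrate a whole threshold profile
#'
#' Runs [calibrate_min_fp()] for every matrix in a library.
#'
#' @inheritParams calibrate_min_fp
#' @param pwms List of [`PWMatrix`][pwmatrix] objects.
#' @return Threshold profile data.frame (`matrix_id`, `core_cutoff`,
#'   `matrix_cutoff`).
#' @export
calibrate_profile <- function(pwms, background, target_fp_per_kb = 0.5,
                              core_fraction = 0.9) {
  maxL <- max(vapply(pwms, function(p) nrow(p$freqs), integer(1L)))
  cp <- concat_promoters(background, gap = maxL + 5L)
  ctx <- make_scan_context(cp$s)
  rows <- lapply(pwms, function(pwm) {
    cut <- calibrate_min_fp(pwm, background, target_fp_per_kb, core_fraction,
                            .ctx = ctx)
    data.frame(matrix_id = pwm$matrix_id,
               core_cutoff = unname(cut["core_cutoff"]),
               matrix_cutoff = unname(cut["matrix_cutoff"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
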