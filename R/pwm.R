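# Alphabet order is fixed A,C,G,T throughout the package.
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A `PWMatrix` bundles a position count (or frequency) matrix with the
#' quantities the Match-style scorer needs: row-normalized frequencies after
#' pseudocount addition, the per-position information vector
#' \eqn{I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))}, and the start of the 5-position
#' core window (the window maximizing \eqn{\sum I(i)}).
#'
#' @param matrix_id Character identifier for the matrix.
#' @param counts Numeric L x 4 matrix of non-negative base counts, columns in
#'   A,C,G,T order. L must be at least 5 so a core window exists.
#' @param tf_ids Character vector of transcription factor identifiers the
#'   matrix is associated with (may be empty; usually filled from a
#'   matrix-to-TF map).
#' @param pseudocount Non-negative number added to every cell before row
#'   normalization. Default 0.01 so consensus matrices stay near-exact.
#' @return An object of class `PWMatrix`: a list with elements `matrix_id`,
#'   `tf_ids`, `counts`, `freqs`, `info`, `core_start` (0-based) and
#'   `pseudocount`.
#' @examples
#' m <- pwmatrix("M1", matrix(c(10, 0, 0, 0), 5, 4, byrow = TRUE))
#' m$info                 # ln(4) at every position
#' m$core_start           # 0
#' @export
pwmatrix <- function(matrix_id, counts, tf_ids = character(), pseudocount = 0.01) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (ncol(counts) != 4L)
    stop("matrix '", matrix_id, "': expected 4 columns (A,C,G,T), got ",
         ncol(counts))
  if (nrow(counts) < 5L)
    stop("matrix '", matrix_id, "': needs at least 5 positions, got ",
         nrow(counts))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("matrix '", matrix_id, "': counts must be finite and non-negative")
  if (pseudocount < 0)
    stop("pseudocount must be non-negative")
  adj <- counts + pseudocount
  rs <- rowSums(adj)
  if (any(rs <= 0))
    stop("matrix '", matrix_id,
         "': row of all zeros cannot be normalized with pseudocount 0 (row ",
         which(rs <= 0)[1L], ")")
  freqs <- adj / rs
  dimnames(freqs) <- list(NULL, DNA_BASES)
  info <- information_vector(freqs)
  structure(
    list(matrix_id = as.character(matrix_id),
         tf_ids = as.character(tf_ids),
         counts = counts,
         freqs = freqs,
         info = info,
         core_start = core_start_from_info(info),
         pseudocount = pseudocount),
    class = "PWMatrix")
}

#' @export
print.PWMatrix <- function(x, ...) {
  cat("PWMatrix", x$matrix_id,
      sprintf("(L = %d, core at %d..%d)", nrow(x$freqs), x$core_start,
              x$core_start + 4L), "\n")
  if (length(x$tf_ids))
    cat("  TFs:", paste(x$tf_ids, collapse = ", "), "\n")
  cat("  consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Per-position information vector of a frequency matrix
#'
#' Computes \eqn{I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))} with the convention
#' \eqn{0 \ln 0 = 0}. `I(i)` is 0 for a uniform row and `ln 4` for a one-hot
#' row; it weights positions in the matrix and core similarity scores.
#'
#' @param freqs Numeric L x 4 matrix whose rows sum to 1.
#' @return Numeric vector of length L, all entries in `[0, ln 4]`.
#' @export
information_vector <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (any(freqs < 0)) stop("negative frequency in matrix rows")
  if (any(abs(rowSums(freqs) - 1) > 1e-6))
    stop("frequency rows must sum to 1")
  x <- freqs * log(4 * freqs)
  x[freqs == 0] <- 0
  rowSums(x)
}

# 0-based start of the 5-position window maximizing the summed information;
# ties broken by the smallest start (which.max takes the first maximum).
core_start_from_info <- function(info) {
  L <- length(info)
  if (L < 5L) stop("matrix shorter than the 5-position core")
  cs <- cumsum(c(0, info))
  wsum <- cs[6:(L + 1L)] - cs[1:(L - 4L)]
  which.max(wsum) - 1L
}

#' Core window start of a PWM
#'
#' The core is the 5 consecutive positions with maximal summed information;
#' ties resolve to the smallest start. Returned 0-based.
#'
#' @param pwm A `PWMatrix`.
#' @return Integer 0-based start index of the core window.
#' @export
core_window <- function(pwm) {
  stopifnot(inherits(pwm, "PWMatrix"))
  pwm$core_start
}

consensus_string <- function(pwm) {
  paste(DNA_BASES[max.col(pwm$freqs, ties.method = "first")], collapse = "")
}

# ---- sequence encoding -----------------------------------------------------

# Encode a DNA string as integers 1..4 (A,C,G,T); N -> NA. Any other
# character is an error. Used by every scanner.
encode_dna <- function(sequence, what = "sequence") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  code <- match(chars, DNA_BASES)
  bad <- is.na(code) & chars != "N"
  if (any(bad))
    stop(what, " contains invalid character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  code
}

COMPLEMENT <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G in A,C,G,T coding

# ---- Match-style scoring ---------------------------------------------------

# Weight matrix used by the Match scheme: w(i,b) = I(i) * f(i,b).
# A window score is sum_i w(i, s_i), normalized to
# (Current - Min) / (Max - Min) with Max/Min the per-position extremes.
pwm_weights <- function(freqs, info, rows = seq_len(nrow(freqs))) {
  w <- info[rows] * freqs[rows, , drop = FALSE]
  list(w = w,
       max = sum(apply(w, 1L, max)),
       min = sum(apply(w, 1L, min)))
}

# Precomputed scan context for an encoded sequence: the encoding with N
# replaced by a sentinel (so vectorized gathers stay in-bounds) and a
# cumulative N count used to invalidate windows that contain N. Built once
# per sequence (or per concatenated promoter set) and shared across
# matrices and strands.
make_scan_context <- function(s) {
  na <- is.na(s)
  s0 <- s
  s0[na] <- 1L
  ctx <- new.env(parent = emptyenv())
  ctx$n <- length(s)
  ctx$s0 <- s0
  ctx$na_cum <- cumsum(na)
  ctx$idx_cache <- list()
  ctx
}

# Flat gather index for windows of length L: S[j, i] = (i-1)*4 + s[j+i-1],
# addressing column i of a transposed 4 x L weight matrix. Depends only on
# the sequence and L, so it is cached on the context and shared by every
# matrix of that length (and both strands).
window_index <- function(ctx, L) {
  key <- as.character(L)
  S <- ctx$idx_cache[[key]]
  if (is.null(S)) {
    m <- ctx$n - L + 1L
    S <- matrix(0L, m, L)
    for (i in seq_len(L))
      S[, i] <- (i - 1L) * 4L + ctx$s0[i:(i + m - 1L)]
    ctx$idx_cache[[key]] <- S
  }
  S
}

# Per-row weight contributions for every window start: an m x L matrix G
# with G[j, i] = w(i, s[j+i-1]). mss is the row sum over all columns, css
# the row sum over the core columns, so one gather pass serves both.
window_contributions <- function(ctx, w) {
  L <- nrow(w)
  m <- ctx$n - L + 1L
  if (m < 1L) return(NULL)
  S <- window_index(ctx, L)
  G <- t(w)[S]
  dim(G) <- dim(S)
  G
}

# Windows of length L starting at j = 1..n-L+1 that contain an N; cached
# on the context per L.
na_windows <- function(ctx, L) {
  m <- ctx$n - L + 1L
  if (m < 1L) return(logical(0))
  key <- paste0("na", L)
  bad <- ctx$idx_cache[[key]]
  if (is.null(bad)) {
    bad <- ctx$na_cum[L:(L + m - 1L)] - c(0, ctx$na_cum)[1:m] > 0
    ctx$idx_cache[[key]] <- bad
  }
  bad
}

normalize_scores <- function(raw, wmin, wmax) {
  if (wmax - wmin <= 0) {
    # fully uninformative block: defined as a perfect score
    out <- rep(1, length(raw))
    out[is.na(raw)] <- NA_real_
    return(out)
  }
  (raw - wmin) / (wmax - wmin)
}

# Matrix and core similarity scores for every window start of a scan
# context, on one strand. Returns list(mss, css), each length n - L + 1;
# windows containing N are NA. css computation can be skipped when only
# matrix scores are needed (threshold calibration).
strand_scores <- function(freqs, info, core_start, ctx, need_css = TRUE) {
  L <- nrow(freqs)
  if (ctx$n < L) return(list(mss = numeric(0), css = numeric(0)))
  full <- pwm_weights(freqs, info)
  bad <- na_windows(ctx, L)
  G <- window_contributions(ctx, full$w)
  mss_raw <- rowSums(G)
  mss_raw[bad] <- NA_real_
  mss <- normalize_scores(mss_raw, full$min, full$max)
  if (!need_css) return(list(mss = mss, css = NULL))
  # the core block starts core_start bases into every full window, i.e. it
  # is the corresponding column slice of the contribution matrix
  core_rows <- (core_start + 1L):(core_start + 5L)
  core <- pwm_weights(freqs, info, core_rows)
  css_raw <- rowSums(G[, core_rows, drop = FALSE])
  css_raw[bad] <- NA_real_
  list(mss = mss, css = normalize_scores(css_raw, core$min, core$max))
}

# Hit detection on one strand: mss is computed for all windows, css only at
# the windows already passing the matrix cutoff.
strand_hits <- function(freqs, info, core_start, ctx, core_cutoff,
                        matrix_cutoff) {
  L <- nrow(freqs)
  none <- list(window = integer(0), mss = numeric(0), css = numeric(0))
  if (ctx$n < L) return(none)
  full <- pwm_weights(freqs, info)
  G <- window_contributions(ctx, full$w)
  mss_raw <- rowSums(G)
  mss_raw[na_windows(ctx, L)] <- NA_real_
  mss <- normalize_scores(mss_raw, full$min, full$max)
  cand <- which(!is.na(mss) & mss >= matrix_cutoff)
  if (!length(cand)) return(none)
  core_rows <- (core_start + 1L):(core_start + 5L)
  core <- pwm_weights(freqs, info, core_rows)
  css <- normalize_scores(rowSums(G[cand, core_rows, drop = FALSE]),
                          core$min, core$max)
  keep <- css >= core_cutoff
  list(window = cand[keep], mss = mss[cand][keep], css = css[keep])
}

# Reverse-complement view of a matrix: rows reversed, A<->T and C<->G
# columns swapped. Scoring the forward sequence with this view equals
# scoring the reverse complement of each window with the original matrix.
revcomp_pwm_parts <- function(freqs, info, core_start) {
  L <- nrow(freqs)
  list(freqs = freqs[L:1, 4:1, drop = FALSE],
       info = rev(info),
       core_start = L - 5L - core_start)
}

#' Matrix similarity score of a single window
#'
#' Scores one L-long window with the Match matrix similarity score
#' \eqn{MSS = (Current - Min)/(Max - Min)} where
#' \eqn{Current = \sum_i I(i) f(i, s_i)} and Max/Min are the per-position
#' information-weighted extremes. A fully uniform (zero-information) matrix
#' scores 1 by definition.
#'
#' @param pwm A `PWMatrix`.
#' @param window Character scalar over A,C,G,T of length equal to the matrix.
#' @return A number in `[0, 1]`.
#' @export
mss_score <- function(pwm, window) {
  stopifnot(inherits(pwm, "PWMatrix"))
  s <- encode_dna(window, "window")
  if (any(is.na(s))) stop("window must be over A,C,G,T (no N)")
  if (length(s) != nrow(pwm$freqs))
    stop("window length ", length(s), " does not match matrix length ",
         nrow(pwm$freqs))
  p <- pwm_weights(pwm$freqs, pwm$info)
  normalize_scores(sum(p$w[cbind(seq_along(s), s)]), p$min, p$max)
}

#' Core similarity score of a single window
#'
#' Same normalized scheme as [mss_score()] restricted to the 5-position core
#' window of the matrix, applied at the corresponding offset of the sequence
#' window.
#'
#' @inheritParams mss_score
#' @return A number in `[0, 1]`.
#' @export
css_score <- function(pwm, window) {
  stopifnot(inherits(pwm, "PWMatrix"))
  s <- encode_dna(window, "window")
  if (length(s) != nrow(pwm$freqs))
    stop("window length ", length(s), " does not match matrix length ",
         nrow(pwm$freqs))
  rows <- (pwm$core_start + 1L):(pwm$core_start + 5L)
  p <- pwm_weights(pwm$freqs, pwm$info, rows)
  normalize_scores(sum(p$w[cbind(seq_len(5L), s[rows])]), p$min, p$max)
}
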