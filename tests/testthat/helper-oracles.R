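# Fixture builders and independent brute-force oracles. The oracles
# re-derive every score from the raw definitions (no shared code with the
# package internals) so they can certify the vectorized implementations.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
}

rc <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

prom <- function(sequence, promoter_id = "P1", gene_id = "G1",
                 tss_offset = 0L) {
  data.frame(promoter_id = promoter_id, gene_id = gene_id,
             sequence = sequence, tss_offset = as.integer(tss_offset),
             stringsAsFactors = FALSE)
}

# Random PWM with a few informative positions, built from Dirichlet-ish
# count draws.
rand_pwm <- function(id, L, pseudocount = 0.01) {
  counts <- matrix(rexp(L * 4), L, 4)
  counts <- counts / rowSums(counts) * 20
  pwmatrix(id, counts, pseudocount = pseudocount)
}

# ---- Match-score oracle (plain double loops over the definitions) -------

oracle_info <- function(freqs) {
  apply(freqs, 1, function(f) {
    x <- f * log(4 * f)
    sum(x[f > 0])
  })
}

oracle_mss_rows <- function(freqs, rows, window_chars) {
  info <- oracle_info(freqs)
  cur <- mx <- mn <- 0
  for (k in seq_along(rows)) {
    i <- rows[k]
    wrow <- info[i] * freqs[i, ]
    b <- match(window_chars[k], BASES)
    cur <- cur + wrow[b]
    mx <- mx + max(wrow)
    mn <- mn + min(wrow)
  }
  if (mx - mn <= 0) return(1)
  unname((cur - mn) / (mx - mn))
}

oracle_mss <- function(pwm, window) {
  chars <- strsplit(window, "")[[1L]]
  oracle_mss_rows(pwm$freqs, seq_len(nrow(pwm$freqs)), chars)
}

oracle_core_start <- function(pwm) {
  info <- oracle_info(pwm$freqs)
  L <- length(info)
  sums <- vapply(0:(L - 5L), function(s) sum(info[(s + 1):(s + 5)]),
                 numeric(1))
  which.max(sums) - 1L
}

oracle_css <- function(pwm, window) {
  s <- oracle_core_start(pwm)
  chars <- strsplit(window, "")[[1L]]
  oracle_mss_rows(pwm$freqs, (s + 1):(s + 5), chars[(s + 1):(s + 5)])
}

# Naive re-scan: every window on both strands, scored character by
# character; windows containing N are skipped.
oracle_scan <- function(pwm, promoter, core_cutoff, matrix_cutoff) {
  seqc <- promoter$sequence[[1L]]
  L <- nrow(pwm$freqs)
  n <- nchar(seqc)
  rows <- list()
  for (j in seq_len(max(0L, n - L + 1L))) {
    win <- substr(seqc, j, j + L - 1L)
    if (grepl("N", win)) next
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rc(win)
      mss <- oracle_mss(pwm, w)
      css <- oracle_css(pwm, w)
      if (mss >= matrix_cutoff && css >= core_cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          matrix_id = pwm$matrix_id,
          promoter_id = promoter$promoter_id[[1L]],
          start = j - 1L - promoter$tss_offset[[1L]],
          end = j - 1L - promoter$tss_offset[[1L]] + L,
          strand = strand, mss = mss, css = css,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(matrix_id = character(), promoter_id = character(),
                         start = integer(), end = integer(),
                         strand = character(), mss = numeric(),
                         css = numeric(), stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

# All background mss values (both strands), oracle-scored.
oracle_background_scores <- function(pwm, background) {
  unlist(lapply(seq_len(nrow(background)), function(i) {
    sc <- oracle_scan(pwm, background[i, ], core_cutoff = 0,
                      matrix_cutoff = 0)
    sc$mss
  }))
}

# ---- ERE oracle: exhaustive 13-mer Hamming distance ----------------------

oracle_ere <- function(promoter, max_mismatch, spacer = 3L) {
  seqc <- promoter$sequence[[1L]]
  n <- nchar(seqc)
  L <- 10L + spacer
  pat <- c(strsplit("GGTCA", "")[[1L]], rep(NA, spacer),
           strsplit("TGACC", "")[[1L]])
  rows <- list()
  for (j in seq_len(max(0L, n - L + 1L))) {
    win <- strsplit(substr(seqc, j, j + L - 1L), "")[[1L]]
    if (any(win == "N")) next
    mm <- sum(win != pat, na.rm = TRUE)
    if (mm <= max_mismatch)
      rows[[length(rows) + 1L]] <- data.frame(
        promoter_id = promoter$promoter_id[[1L]],
        start = j - 1L - promoter$tss_offset[[1L]],
        end = j - 1L - promoter$tss_offset[[1L]] + L,
        strand = "+", mismatches = mm, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(promoter_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# ---- misc oracles --------------------------------------------------------

oracle_gap <- function(a, b, c, d) max(0L, c - b, a - d)

oracle_nearest_rank <- function(x, p) {
  xs <- sort(x)
  xs[max(1L, ceiling(p / 100 * length(xs)))]
}

# Simple gene-table builder: k genes, one promoter each, with given flags.
gene_tab <- function(ere, evidence, ids = NULL) {
  k <- length(ere)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(k))
  data.frame(gene_id = ids, promoter_ids = sprintf("P%03d", seq_len(k)),
             evidence = evidence, ere_predicted = ere, group = NA_integer_,
             stringsAsFactors = FALSE)
}

# Edges giving each TF a prescribed out-degree (distinct gene ids per TF).
edges_with_degrees <- function(tf_ids, degrees) {
  do.call(rbind, lapply(seq_along(tf_ids), function(i)
    data.frame(tf_id = tf_ids[i],
               gene_id = sprintf("%s_g%03d", tf_ids[i],
                                 seq_len(degrees[i])),
               supporting_matrix_ids = "M1", stringsAsFactors = FALSE)))
}
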