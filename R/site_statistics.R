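# Positional statistics over predicted sites: TFBS-to-ERE distances on
# ERE-bearing promoters, a Gaussian-kernel density of sites around the TSS,
# and annotation-term fractions per gene group.

interval_gap <- function(a, b, c, d) pmax(0L, pmax(c - b, a - d))

#' Distance from each TFBS to its closest ERE
#'
#' Only promoters carrying at least one ERE contribute. For every TFBS on
#' such a promoter the closest ERE is found; the distance is the nucleotide
#' gap between the half-open intervals `[a,b)` and `[c,d)`, i.e.
#' `max(0, c - b, a - d)` (0 when they intersect). Ties go to the ERE with
#' the smaller start. `complete_overlap` records containment of one
#' interval in the other.
#'
#' @param tfbs_hits Site hits ([scan_promoters()]).
#' @param ere_hits ERE hits ([scan_ere_set()]).
#' @return Data.frame with one row per TFBS on an ERE-bearing promoter:
#'   `matrix_id`, `promoter_id`, `tfbs_start`, `tfbs_end`, `ere_start`,
#'   `ere_end`, `distance`, `complete_overlap`.
#' @export
tfbs_ere_distances <- function(tfbs_hits, ere_hits) {
  empty <- data.frame(matrix_id = character(), promoter_id = character(),
                      tfbs_start = integer(), tfbs_end = integer(),
                      ere_start = integer(), ere_end = integer(),
                      distance = integer(), complete_overlap = logical(),
                      stringsAsFactors = FALSE)
  keep <- tfbs_hits$promoter_id %in% unique(ere_hits$promoter_id)
  tf <- tfbs_hits[keep, , drop = FALSE]
  if (!nrow(tf)) return(empty)
  rows <- lapply(split(seq_len(nrow(tf)), tf$promoter_id), function(idx) {
    prom <- tf$promoter_id[idx[1L]]
    ere <- ere_hits[ere_hits$promoter_id == prom, , drop = FALSE]
    ere <- ere[order(ere$start), , drop = FALSE]
    best <- t(vapply(idx, function(i) {
      a <- tf$start[i]; b <- tf$end[i]
      gaps <- interval_gap(a, b, ere$start, ere$end)
      j <- which.min(gaps)  # first minimum = smallest ERE start
      contain <- (a >= ere$start[j] && b <= ere$end[j]) ||
        (ere$start[j] >= a && ere$end[j] <= b)
      c(ere$start[j], ere$end[j], gaps[j], as.integer(contain))
    }, numeric(4L)))
    data.frame(matrix_id = tf$matrix_id[idx],
               promoter_id = prom,
               tfbs_start = tf$start[idx], tfbs_end = tf$end[idx],
               ere_start = as.integer(best[, 1L]),
               ere_end = as.integer(best[, 2L]),
               distance = as.integer(best[, 3L]),
               complete_overlap = as.logical(best[, 4L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$promoter_id, out$tfbs_start, out$matrix_id), , drop = FALSE]
}

#' Summarize TFBS-to-ERE distances
#'
#' Bins distances into `[0, w), [w, 2w), ...` (default width 50 nt), with
#' cumulative counts, and tabulates the minimum distance per matrix (a
#' per-TF view when matrices map 1:1 to TFs).
#'
#' @param records Distance records ([tfbs_ere_distances()]).
#' @param bin_width Histogram bin width in nt; default 50.
#' @return List with `histogram` (`bin_start`, `bin_end`, `count`,
#'   `cumulative`) and `per_matrix_min` (`matrix_id`, `min_distance`,
#'   `complete_overlap` = whether any record of the matrix fully overlaps an
#'   ERE).
#' @export
distance_summary <- function(records, bin_width = 50L) {
  if (!nrow(records)) {
    return(list(histogram = data.frame(bin_start = integer(),
                                       bin_end = integer(),
                                       count = integer(),
                                       cumulative = integer()),
                per_matrix_min = data.frame(matrix_id = character(),
                                            min_distance = integer(),
                                            complete_overlap = logical(),
                                            stringsAsFactors = FALSE)))
  }
  nb <- floor(max(records$distance) / bin_width) + 1L
  bin <- records$distance %/% bin_width + 1L
  counts <- tabulate(bin, nbins = nb)
  hist <- data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
                     bin_end = seq_len(nb) * bin_width,
                     count = counts,
                     cumulative = cumsum(counts))
  per <- lapply(split(seq_len(nrow(records)), records$matrix_id),
                function(idx)
                  data.frame(matrix_id = records$matrix_id[idx[1L]],
                             min_distance = min(records$distance[idx]),
                             complete_overlap = any(records$complete_overlap[idx]),
                             stringsAsFactors = FALSE))
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  list(histogram = hist,
       per_matrix_min = per[order(per$matrix_id), , drop = FALSE])
}

#' Gaussian-kernel density of TFBS positions around the TSS
#'
#' Evaluates the Gaussian kernel density of site midpoints on an even grid
#' over the promoter window (default \[-1000, +200\]), by direct kernel
#' summation: \eqn{\hat f(t) = n^{-1} \sum_i \phi_h(t - x_i)}. The
#' bandwidth defaults to Silverman's rule-of-thumb ([stats::bw.nrd0()]);
#' for degenerate samples (zero spread) a 1 nt bandwidth is used.
#'
#' @param hits Site hits with `start`/`end` columns (midpoints are used).
#' @param grid_points Number of grid points; default 512.
#' @param bandwidth Kernel bandwidth in nt, or `NULL` for Silverman's rule.
#' @param window Numeric length-2 grid range; default `c(-1000, 200)`.
#' @return Data.frame with columns `position` and `density`.
#' @export
tss_positional_density <- function(hits, grid_points = 512L,
                                   bandwidth = NULL,
                                   window = c(-1000, 200)) {
  x <- (hits$start + hits$end) / 2
  if (length(x) < 2L) stop("need at least 2 hits for a density estimate")
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd0(x)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  grid <- seq(window[1L], window[2L], length.out = grid_points)
  # direct kernel sum, chunked over hits to bound memory
  dens <- numeric(grid_points)
  chunk <- 5000L
  for (i in seq(1L, length(x), by = chunk)) {
    xi <- x[i:min(i + chunk - 1L, length(x))]
    dens <- dens + rowSums(vapply(
      xi, function(v) stats::dnorm(grid, mean = v, sd = bandwidth),
      numeric(grid_points)))
  }
  data.frame(position = grid, density = dens / length(x))
}

#' Annotation-term fractions within a gene group
#'
#' For each term, the fraction of group genes annotated with it. Genes
#' absent from the annotation count as unannotated for every term.
#'
#' @param group_genes Character vector of gene ids (non-empty).
#' @param annotation Data.frame with columns `gene_id`, `term` (one row per
#'   pair), or a named list gene_id -> character vector of terms.
#' @return Data.frame sorted by decreasing fraction: `term`, `n_genes`,
#'   `fraction` (rounded to 2 decimals), `percent` (rounded to an integer).
#' @export
term_fractions <- function(group_genes, annotation) {
  if (!length(group_genes)) stop("empty gene group")
  if (is.list(annotation) && !is.data.frame(annotation)) {
    annotation <- data.frame(
      gene_id = rep(names(annotation), lengths(annotation)),
      term = unlist(annotation, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  ann <- unique(annotation[annotation$gene_id %in% group_genes, ,
                           drop = FALSE])
  n <- length(unique(group_genes))
  if (!nrow(ann))
    return(data.frame(term = character(), n_genes = integer(),
                      fraction = numeric(), percent = numeric(),
                      stringsAsFactors = FALSE))
  counts <- table(ann$term)
  out <- data.frame(term = names(counts),
                    n_genes = as.integer(counts),
                    fraction = round(as.integer(counts) / n, 2L),
                    percent = round(100 * as.integer(counts) / n),
                    stringsAsFactors = FALSE)
  out[order(-out$n_genes, out$term), , drop = FALSE]
}
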