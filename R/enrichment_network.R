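# Over-representation of matrices in target vs background promoters, the
# TF -> gene network built from enriched matrices, out-degree ranking with
# a percentile retention rule, and TF set algebra between gene groups.

#' Per-matrix over-representation index
#'
#' For every matrix appearing in either hit list, compares hit density and
#' promoter coverage between the target and background promoter sets:
#' \deqn{ORI = \frac{(h_t + p)/kb_t}{(h_b + p)/kb_b} \times
#'             \frac{c_t + \epsilon}{c_b + \epsilon}}
#' where `h` are hit counts, `kb` total promoter lengths in kb, `c` the
#' fractions of promoters carrying at least one hit, `p` a pseudocount on
#' hit counts and `\epsilon` a small coverage regularizer (default
#' `1/n_background_promoters`). A matrix is flagged enriched when its ORI
#' reaches `ori_threshold` (default 2). The index is invariant under a
#' common rescaling of lengths and hit counts (with the pseudocount scaled
#' along) and is robust to a single promoter carrying many sites, because a
#' density spike on one promoter barely moves coverage.
#'
#' @param target_hits,background_hits Site hit data.frames
#'   ([scan_promoters()]).
#' @param target_promoters,background_promoters Promoter data.frames; both
#'   non-empty.
#' @param pseudocount Pseudocount on hit counts; default 1.
#' @param ori_threshold Enrichment threshold on ORI; default 2.
#' @param coverage_eps Coverage regularizer; default
#'   `1/nrow(background_promoters)`.
#' @return Data.frame with one row per matrix: `matrix_id`, `target_hits`,
#'   `background_hits`, `target_len_kb`, `background_len_kb`,
#'   `target_coverage`, `background_coverage`, `ori`, `enriched`; sorted by
#'   decreasing ORI.
#' @export
compute_ori <- function(target_hits, target_promoters,
                        background_hits, background_promoters,
                        pseudocount = 1, ori_threshold = 2,
                        coverage_eps = NULL) {
  if (is.null(target_promoters) || !nrow(target_promoters))
    stop("empty target promoter set")
  if (is.null(background_promoters) || !nrow(background_promoters))
    stop("empty background promoter set")
  if (is.null(coverage_eps)) coverage_eps <- 1 / nrow(background_promoters)
  t_kb <- sum(nchar(target_promoters$sequence)) / 1000
  b_kb <- sum(nchar(background_promoters$sequence)) / 1000
  mats <- sort(unique(c(target_hits$matrix_id, background_hits$matrix_id)))
  side <- function(hits, n_prom, mat) {
    h <- hits[hits$matrix_id == mat, , drop = FALSE]
    c(n = nrow(h), cov = length(unique(h$promoter_id)) / n_prom)
  }
  rows <- lapply(mats, function(mat) {
    tg <- side(target_hits, nrow(target_promoters), mat)
    bg <- side(background_hits, nrow(background_promoters), mat)
    ori <- ((tg["n"] + pseudocount) / t_kb) /
           ((bg["n"] + pseudocount) / b_kb) *
           ((tg["cov"] + coverage_eps) / (bg["cov"] + coverage_eps))
    data.frame(matrix_id = mat,
               target_hits = as.integer(tg["n"]),
               background_hits = as.integer(bg["n"]),
               target_len_kb = t_kb, background_len_kb = b_kb,
               target_coverage = unname(tg["cov"]),
               background_coverage = unname(bg["cov"]),
               ori = unname(ori),
               enriched = unname(ori >= ori_threshold),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(matrix_id = character(), target_hits = integer(),
                      background_hits = integer(), target_len_kb = numeric(),
                      background_len_kb = numeric(),
                      target_coverage = numeric(),
                      background_coverage = numeric(), ori = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$ori, out$matrix_id), , drop = FALSE]
}

#' Build the TF-to-gene network from enriched matrices
#'
#' An edge (TF, gene) exists iff some enriched matrix mapped to the TF has
#' at least one hit on at least one promoter of the gene. Non-enriched
#' matrices contribute nothing.
#'
#' @param ori ORI table ([compute_ori()]); only rows with `enriched == TRUE`
#'   are used.
#' @param target_hits Site hits on the target promoters.
#' @param matrix_tf_map Named list matrix_id -> TF ids
#'   ([read_matrix_tf_map()]). Must cover every enriched matrix.
#' @param genes Gene table; promoters are resolved through its
#'   `promoter_ids` column.
#' @return Data.frame of edges: `tf_id`, `gene_id`,
#'   `supporting_matrix_ids` (comma-separated, sorted), ordered by
#'   `tf_id`, `gene_id`.
#' @export
build_network <- function(ori, target_hits, matrix_tf_map, genes) {
  enriched <- ori$matrix_id[ori$enriched]
  missing <- setdiff(enriched, names(matrix_tf_map))
  if (length(missing))
    stop("enriched matrix id(s) missing from the matrix-TF map: ",
         paste(missing, collapse = ", "))
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      supporting_matrix_ids = character(),
                      stringsAsFactors = FALSE)
  hits <- target_hits[target_hits$matrix_id %in% enriched, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  prom_lists <- split_ids(genes$promoter_ids)
  prom2gene <- data.frame(promoter_id = unlist(prom_lists),
                          gene_id = rep(genes$gene_id, lengths(prom_lists)),
                          stringsAsFactors = FALSE)
  hits$gene_id <- prom2gene$gene_id[match(hits$promoter_id,
                                          prom2gene$promoter_id)]
  hits <- hits[!is.na(hits$gene_id), , drop = FALSE]
  if (!nrow(hits)) return(empty)
  # one row per (matrix, gene), expanded to (tf, gene, matrix)
  mg <- unique(hits[c("matrix_id", "gene_id")])
  tfs <- matrix_tf_map[mg$matrix_id]
  expanded <- data.frame(tf_id = unlist(tfs),
                         gene_id = rep(mg$gene_id, lengths(tfs)),
                         matrix_id = rep(mg$matrix_id, lengths(tfs)),
                         stringsAsFactors = FALSE)
  key <- paste(expanded$tf_id, expanded$gene_id, sep = "\r")
  support <- vapply(split(expanded$matrix_id, key),
                    function(m) paste(sort(unique(m)), collapse = ","),
                    character(1L))
  parts <- strsplit(names(support), "\r", fixed = TRUE)
  out <- data.frame(tf_id = vapply(parts, `[`, character(1L), 1L),
                    gene_id = vapply(parts, `[`, character(1L), 2L),
                    supporting_matrix_ids = unname(support),
                    stringsAsFactors = FALSE)
  out[order(out$tf_id, out$gene_id), , drop = FALSE]
}

# Nearest-rank percentile of a multiset: the value at position
# ceil(p/100 * n) of the ascending sort.
nearest_rank_percentile <- function(x, p) {
  sort(x)[max(1L, ceiling(p / 100 * length(x)))]
}

#' Rank TFs by out-degree with percentile retention
#'
#' The out-degree of a TF is the number of distinct genes it is linked to.
#' TFs are sorted by decreasing out-degree (ties by TF id, ascending) and
#' ranked 1..n. A TF is retained iff its out-degree reaches the
#' nearest-rank `percentile`-th percentile of the out-degree multiset; ties
#' at the threshold are all retained, so the retained set is upward-closed
#' in out-degree.
#'
#' @param edges Edge data.frame ([build_network()]); must be non-empty.
#' @param percentile Retention percentile; default 80.
#' @return Data.frame: `tf_id`, `out_degree`, `rank`, `retained`.
#' @export
rank_tfs <- function(edges, percentile = 80) {
  if (is.null(edges) || !nrow(edges)) stop("empty edge list")
  deg <- vapply(split(edges$gene_id, edges$tf_id),
                function(g) length(unique(g)), integer(1L))
  out <- data.frame(tf_id = names(deg), out_degree = unname(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$out_degree, out$tf_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  cutoff <- nearest_rank_percentile(out$out_degree, percentile)
  out$retained <- out$out_degree >= cutoff
  rownames(out) <- NULL
  out
}

#' Set algebra between two TF sets
#'
#' @param set_a,set_b Character vectors of TF ids.
#' @return List with sorted components `common`, `unique_a`, `unique_b`,
#'   `union`; `|union| = |a| + |b| - |common|`.
#' @export
tf_set_algebra <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  list(common = sort(intersect(a, b)),
       unique_a = sort(setdiff(a, b)),
       unique_b = sort(setdiff(b, a)),
       union = sort(union(a, b)))
}
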