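# Estrogen response element detection by degenerate-palindrome matching.
# The canonical full ERE is the palindrome GGTCA-nnn-TGACC: two 5-bp
# half-sites on opposite strands separated by an unconstrained 3-nt spacer.
# Mismatches are counted over the 10 half-site positions only. Because the
# consensus is its own reverse complement, every site is reported once on
# the + strand.

ERE_HALF_LEFT <- "GGTCA"
ERE_HALF_RIGHT <- "TGACC"

#' Scan a promoter for estrogen response elements
#'
#' Matches the degenerate palindrome `GGTCA-n{spacer}-TGACC` at every
#' position of the promoter, counting mismatches over the 10 half-site
#' positions (the spacer is unconstrained). Windows containing N are
#' skipped. Overlapping hits are all reported.
#'
#' @param promoter One promoter: a one-row data.frame (or list) with
#'   `promoter_id`, `sequence`, `tss_offset`.
#' @param max_mismatch Maximum tolerated half-site mismatches, in 0..4;
#'   default 2.
#' @param spacer Spacer length in nt between half-sites; default 3 (site
#'   length 13).
#' @return Data.frame of hits: `promoter_id`, `start`, `end` (0-based
#'   half-open, promoter-relative), `strand` (always `"+"`), `mismatches`.
#' @export
scan_ere <- function(promoter, max_mismatch = 2L, spacer = 3L) {
  if (max_mismatch < 0 || max_mismatch > 4)
    stop("max_mismatch must be in [0, 4]")
  s <- encode_dna(promoter$sequence[[1L]], promoter$promoter_id[[1L]])
  hits <- ere_mismatch_positions(s, max_mismatch, spacer)
  data.frame(promoter_id = rep(promoter$promoter_id[[1L]], length(hits$pos)),
             start = hits$pos - 1L - as.integer(promoter$tss_offset[[1L]]),
             end = hits$pos - 1L - as.integer(promoter$tss_offset[[1L]]) +
               10L + as.integer(spacer),
             strand = rep("+", length(hits$pos)),
             mismatches = hits$mm,
             stringsAsFactors = FALSE)
}

# Vectorized mismatch counting over an encoded sequence. Returns 1-based
# window starts and mismatch counts for windows passing the threshold;
# windows containing N anywhere (spacer included) are skipped.
ere_mismatch_positions <- function(s, max_mismatch, spacer = 3L) {
  pat <- c(encode_dna(ERE_HALF_LEFT), rep(NA_integer_, spacer),
           encode_dna(ERE_HALF_RIGHT))
  L <- length(pat)
  n <- length(s)
  if (n < L) return(list(pos = integer(0), mm = integer(0)))
  m <- n - L + 1L
  mm <- integer(m)
  bad <- logical(m)
  for (i in seq_len(L)) {
    si <- s[i:(i + m - 1L)]
    na <- is.na(si)
    if (any(na)) bad <- bad | na
    if (!is.na(pat[i])) mm <- mm + as.integer(si != pat[i] | na)
  }
  keep <- which(!bad & mm <= max_mismatch)
  list(pos = keep, mm = mm[keep])
}

#' Scan a promoter set for EREs
#'
#' @inheritParams scan_ere
#' @param promoters Promoter data.frame ([read_promoters()]).
#' @return Data.frame of hits over all promoters, promoter order preserved.
#' @export
scan_ere_set <- function(promoters, max_mismatch = 2L, spacer = 3L) {
  rows <- lapply(seq_len(nrow(promoters)), function(i)
    scan_ere(promoters[i, ], max_mismatch, spacer))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(promoter_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  out
}

#' Flag ERE-bearing genes
#'
#' Sets `ere_predicted` for every gene: `TRUE` iff at least one of its
#' promoters carries at least one ERE hit. A gene with several alternative
#' promoters is ERE-positive if any one of them is.
#'
#' @param genes Gene table ([read_gene_table()]).
#' @param hits ERE hit data.frame ([scan_ere_set()]). Every hit promoter
#'   must belong to some gene.
#' @return The gene table with `ere_predicted` filled in.
#' @export
flag_ere_genes <- function(genes, hits) {
  prom_lists <- split_ids(genes$promoter_ids)
  known <- unlist(prom_lists)
  orphans <- setdiff(unique(hits$promoter_id), known)
  if (length(orphans))
    stop("ERE hits on promoter(s) not in the gene table: ",
         paste(orphans, collapse = ", "))
  hit_proms <- unique(hits$promoter_id)
  genes$ere_predicted <- vapply(prom_lists,
                                function(p) any(p %in% hit_proms),
                                logical(1L))
  genes
}
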