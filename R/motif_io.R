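# Readers and writers for the external formats the pipeline touches:
# PWM libraries (TRANSFAC flat / JASPAR PFM text), promoter FASTA, gene and
# matrix-to-TF tables, threshold profiles, and BED6 site output.

#' Read a PWM library
#'
#' Parses a motif library in either TRANSFAC flat-matrix format (AC/ID
#' header lines, a `P0` column-header row, numbered position rows, `//`
#' terminator) or JASPAR PFM text (`>ID name` header followed by four rows
#' `A [ ... ]` ... `T [ ... ]`, brackets optional). Matrices are returned in
#' file order, normalized with the pseudocount (see [pwmatrix()]).
#'
#' @param path Path to the library file.
#' @param format `"transfac"` or `"jaspar"`.
#' @param pseudocount Non-negative number added to every count before row
#'   normalization; default 0.01.
#' @return A named list of [`PWMatrix`][pwmatrix] objects (names are matrix
#'   ids), in file order.
#' @export
read_pwm_library <- function(path, format = c("transfac", "jaspar"),
                             pseudocount = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("PWM library not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pwms <- switch(format,
                 transfac = parse_transfac(lines, pseudocount),
                 jaspar = parse_jaspar(lines, pseudocount))
  if (!length(pwms)) stop("no matrices found in ", path)
  names(pwms) <- vapply(pwms, function(p) p$matrix_id, character(1L))
  if (anyDuplicated(names(pwms)))
    stop("duplicate matrix ids in ", path, ": ",
         paste(unique(names(pwms)[duplicated(names(pwms))]), collapse = ", "))
  pwms
}

parse_jaspar <- function(lines, pseudocount) {
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no '>' headers: not JASPAR PFM text")
  bounds <- c(headers, length(lines) + 1L)
  lapply(seq_along(headers), function(k) {
    h <- lines[headers[k]]
    matrix_id <- strsplit(sub("^>\\s*", "", h), "\\s+")[[1L]][1L]
    block <- lines[(headers[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    rows <- vector("list", 4L)
    for (ln in block) {
      m <- regmatches(ln, regexec("^\\s*([ACGT])\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1L]]
      if (length(m) != 3L)
        stop("malformed JASPAR row for matrix ", matrix_id, ": '", ln, "'")
      base <- match(m[2L], DNA_BASES)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3L]), "\\s+")[[1L]]))
      if (any(is.na(vals)))
        stop("non-numeric counts for matrix ", matrix_id, " row ", m[2L])
      rows[[base]] <- vals
    }
    if (any(vapply(rows, is.null, logical(1L))))
      stop("matrix ", matrix_id, ": missing one of the A/C/G/T rows")
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("matrix ", matrix_id, ": ragged rows (lengths ",
           paste(lens, collapse = ","), ")")
    counts <- cbind(A = rows[[1L]], C = rows[[2L]], G = rows[[3L]],
                    T = rows[[4L]])
    pwmatrix(matrix_id, counts, pseudocount = pseudocount)
  })
}

parse_transfac <- function(lines, pseudocount) {
  pwms <- list()
  ac <- id <- NA_character_
  rows <- list()
  in_matrix <- FALSE
  flush <- function() {
    mid <- if (!is.na(ac)) ac else id
    if (is.na(mid)) stop("TRANSFAC record without AC or ID line")
    if (!length(rows)) stop("matrix ", mid, ": no position rows")
    counts <- do.call(rbind, rows)
    pwmatrix(mid, counts, pseudocount = pseudocount)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1L, 2L)
    if (tag == "AC") {
      ac <- trimws(sub("^AC\\s*", "", ln))
    } else if (tag == "ID") {
      id <- trimws(sub("^ID\\s*", "", ln))
    } else if (tag == "P0" || tag == "PO") {
      in_matrix <- TRUE
      cols <- strsplit(trimws(sub("^P[0O]\\s*", "", ln)), "\\s+")[[1L]]
      if (!identical(toupper(cols[1:4]), DNA_BASES))
        stop("line ", i, ": TRANSFAC P0 columns must be A C G T, got '",
             ln, "'")
    } else if (tag == "//") {
      if (in_matrix || length(rows)) {
        pwms[[length(pwms) + 1L]] <- flush()
      }
      ac <- id <- NA_character_
      rows <- list()
      in_matrix <- FALSE
    } else if (in_matrix && grepl("^[0-9]", ln)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (length(parts) < 5L || any(is.na(vals)))
        stop("malformed TRANSFAC position row for matrix ",
             if (!is.na(ac)) ac else id, " at line ", i, ": '", ln, "'")
      rows[[length(rows) + 1L]] <- vals
    }
  }
  if (in_matrix || length(rows))
    pwms[[length(pwms) + 1L]] <- flush()
  pwms
}

#' Read promoter sequences from FASTA
#'
#' One record per promoter. Record ids are either `geneID|promoterID` or a
#' plain promoter id (then the gene id is left `NA` and must come from the
#' gene table). Sequences are upper-cased; characters outside A,C,G,T,N are
#' rejected. The TSS sits `tss_offset` bases into each sequence, so sequence
#' index `j` (0-based) maps to promoter-relative coordinate `j - tss_offset`.
#'
#' @param path FASTA file path.
#' @param tss_offset Integer offset of the TSS within each sequence; default
#'   1000, matching a \[-1000, +200\] promoter window.
#' @return A data.frame with columns `promoter_id`, `gene_id`, `sequence`,
#'   `tss_offset`.
#' @export
read_promoters <- function(path, tss_offset = 1000L) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  gene_id <- ifelse(grepl("|", ids, fixed = TRUE),
                    sub("\\|.*$", "", ids), NA_character_)
  promoter_id <- sub("^[^|]*\\|", "", ids)
  if (anyDuplicated(promoter_id))
    stop("duplicate promoter ids in ", path, ": ",
         paste(unique(promoter_id[duplicated(promoter_id)]), collapse = ", "))
  sequence <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("invalid sequence characters in record(s): ",
         paste(promoter_id[bad], collapse = ", "))
  lens <- nchar(sequence)
  if (any(tss_offset < 0 | tss_offset > lens))
    stop("tss_offset ", tss_offset,
         " outside sequence bounds for record(s): ",
         paste(promoter_id[tss_offset > lens], collapse = ", "))
  data.frame(promoter_id = promoter_id, gene_id = gene_id,
             sequence = sequence,
             tss_offset = as.integer(tss_offset),
             stringsAsFactors = FALSE)
}

#' Write promoters to FASTA
#'
#' Inverse of [read_promoters()]; headers are `geneID|promoterID` when the
#' gene id is known, else the bare promoter id.
#'
#' @param promoters Promoter data.frame as returned by [read_promoters()].
#' @param path Output path.
#' @export
write_promoters <- function(promoters, path) {
  ids <- ifelse(is.na(promoters$gene_id), promoters$promoter_id,
                paste0(promoters$gene_id, "|", promoters$promoter_id))
  x <- Biostrings::DNAStringSet(promoters$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read the gene table
#'
#' TSV with columns `gene_id`, `promoter_ids` (comma-separated) and
#' `evidence` (0/1: documented experimental estrogen responsiveness). The
#' derived columns `ere_predicted` and `group` start unset (`NA`) and are
#' filled by [flag_ere_genes()] and [partition_genes()].
#'
#' @param path TSV path.
#' @param promoters Optional promoter data.frame; when given, every promoter
#'   id referenced by a gene must exist in it.
#' @return A data.frame with columns `gene_id`, `promoter_ids`, `evidence`
#'   (logical), `ere_predicted` (logical, `NA`), `group` (integer, `NA`).
#' @export
read_gene_table <- function(path, promoters = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "promoter_ids", "evidence")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  genes <- data.frame(gene_id = tab$gene_id,
                      promoter_ids = tab$promoter_ids,
                      evidence = tab$evidence %in% c("1", "TRUE", "true"),
                      ere_predicted = NA,
                      group = NA_integer_,
                      stringsAsFactors = FALSE)
  if (!is.null(promoters)) {
    known <- promoters$promoter_id
    refd <- unlist(split_ids(genes$promoter_ids))
    orphans <- setdiff(refd, known)
    if (length(orphans))
      stop("gene table references unknown promoter id(s): ",
           paste(orphans, collapse = ", "))
  }
  genes
}

split_ids <- function(x) strsplit(x, ",", fixed = TRUE)

#' Read a matrix-to-TF map
#'
#' TSV with columns `matrix_id` and `tf_ids` (comma-separated TF
#' identifiers, e.g. Entrez-style ids).
#'
#' @param path TSV path.
#' @return A named list mapping each matrix id to a character vector of TF
#'   ids.
#' @export
read_matrix_tf_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("matrix_id", "tf_ids") %in% names(tab)))
    stop("matrix map must have columns matrix_id, tf_ids")
  map <- split_ids(tab$tf_ids)
  names(map) <- tab$matrix_id
  map
}

#' Write site hits as BED6
#'
#' Sites are written 0-based half-open in promoter-relative coordinates
#' shifted by `shift` (default +1000) so that the start column is
#' non-negative for the standard \[-1000, +200\] window. The BED score
#' column carries `round(1000 * score)` where the score is the matrix
#' similarity score for TFBS hits, or is taken from a `score` column when
#' present (the ERE writer stores mismatch counts there directly).
#'
#' @param hits Data.frame with columns `promoter_id`, `start`, `end`,
#'   `strand` and either `mss` or `score`; a name column is taken from
#'   `matrix_id` if present.
#' @param path Output path.
#' @param shift Coordinate shift added to start/end; default 1000.
#' @export
write_sites_bed <- function(hits, path, shift = 1000L) {
  score <- if ("score" %in% names(hits)) hits$score
           else if ("mss" %in% names(hits)) round(1000 * hits$mss)
           else rep(0L, nrow(hits))
  name <- if ("matrix_id" %in% names(hits)) hits$matrix_id
          else rep(".", nrow(hits))
  bed <- data.frame(chrom = hits$promoter_id,
                    start = hits$start + shift,
                    end = hits$end + shift,
                    name = name,
                    score = score,
                    strand = hits$strand,
                    stringsAsFactors = FALSE)
  if (nrow(bed) && any(bed$start < 0))
    stop("negative BED start after +", shift, " shift")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site file written by [write_sites_bed()]
#'
#' @param path BED path.
#' @param shift Shift to subtract from coordinates (default 1000), restoring
#'   promoter-relative positions.
#' @return Data.frame with columns `promoter_id`, `start`, `end`,
#'   `matrix_id`, `score`, `strand`.
#' @export
read_sites_bed <- function(path, shift = 1000L) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  data.frame(promoter_id = bed$chrom,
             start = bed$start - shift,
             end = bed$end - shift,
             matrix_id = bed$name,
             score = bed$score,
             strand = bed$strand,
             stringsAsFactors = FALSE)
}

#' Read / write a threshold profile
#'
#' TSV with columns `matrix_id`, `core_cutoff`, `matrix_cutoff`, the
#' per-matrix cutoffs used by [scan_promoter()].
#'
#' @param path TSV path.
#' @return `read_threshold_profile()`: data.frame with those columns.
#' @export
read_threshold_profile <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("matrix_id", "core_cutoff", "matrix_cutoff")
  if (!all(need %in% names(tab)))
    stop("threshold profile must have columns ", paste(need, collapse = ", "))
  validate_profile(tab)
  tab[need]
}

#' @rdname read_threshold_profile
#' @param profile Data.frame with columns `matrix_id`, `core_cutoff`,
#'   `matrix_cutoff`.
#' @export
write_threshold_profile <- function(profile, path) {
  validate_profile(profile)
  utils::write.table(profile[c("matrix_id", "core_cutoff", "matrix_cutoff")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_profile <- function(profile) {
  # cutoffs live in [0,1]; an epsilon overshoot above 1 is allowed because a
  # zero-false-positive calibration places the cutoff just above the maximum
  # observed background score, which can itself be 1
  bad <- profile$core_cutoff < 0 | profile$core_cutoff > 1 + 1e-6 |
    profile$matrix_cutoff < 0 | profile$matrix_cutoff > 1 + 1e-6
  if (any(bad))
    stop("cutoffs outside [0,1] for matrix id(s): ",
         paste(profile$matrix_id[bad], collapse = ", "))
  invisible(profile)
}
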