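# Four-way gene partition by (ERE predicted, experimental evidence):
#   group 1: ERE & evidence      group 2: ERE & no evidence
#   group 3: no ERE & evidence   group 4: neither

#' Assign group labels to genes
#'
#' Fills the `group` column from the two flags: (TRUE,TRUE) -> 1,
#' (TRUE,FALSE) -> 2, (FALSE,TRUE) -> 3, (FALSE,FALSE) -> 4.
#'
#' @param genes Gene table with `ere_predicted` and `evidence` set for every
#'   gene.
#' @return The gene table with `group` filled in.
#' @export
assign_groups <- function(genes) {
  unset <- is.na(genes$ere_predicted) | is.na(genes$evidence)
  if (any(unset))
    stop("gene(s) with unset ERE or evidence flag: ",
         paste(genes$gene_id[unset], collapse = ", "))
  genes$group <- ifelse(genes$ere_predicted,
                        ifelse(genes$evidence, 1L, 2L),
                        ifelse(genes$evidence, 3L, 4L))
  genes
}

#' Partition genes into the four groups
#'
#' @param genes Gene table with both flags set (see [assign_groups()]).
#' @return Named list `"1".."4"` of sorted gene-id vectors; groups are
#'   disjoint and their union is the input set.
#' @export
partition_genes <- function(genes) {
  genes <- assign_groups(genes)
  out <- lapply(1:4, function(g) sort(genes$gene_id[genes$group == g]))
  names(out) <- as.character(1:4)
  out
}

#' Union of the experimentally estrogen-controlled groups
#'
#' Groups 1 and 3 both carry experimental evidence of estrogen control;
#' their union is the "experimentally controlled" gene set used for the
#' pooled ranking.
#'
#' @param groups Partition as returned by [partition_genes()].
#' @return Sorted vector of gene ids in group 1 or group 3.
#' @export
experimental_union <- function(groups) {
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("groups are not disjoint: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sort(union(groups[["1"]], groups[["3"]]))
}

#' Write the group assignment table
#'
#' TSV with columns `gene_id`, `ere_predicted`, `evidence`, `group`.
#'
#' @param genes Gene table with groups assigned.
#' @param path Output path.
#' @export
write_groups_tsv <- function(genes, path) {
  out <- assign_groups(genes)
  utils::write.table(
    data.frame(gene_id = out$gene_id,
               ere_predicted = as.integer(out$ere_predicted),
               evidence = as.integer(out$evidence),
               group = out$group),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
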