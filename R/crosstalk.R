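subpathway_part_levels <- c("intersection", "A_unique", "B_unique")

new_subpathway_set <- function(parent_a, parent_b, part, genes) {
  out <- tibble(
    subpathway_id = paste(parent_a, parent_b, part, sep = "|"),
    parent_a = parent_a, parent_b = parent_b,
    part = part, genes = genes,
    n_genes = lengths(genes))
  class(out) <- c("subpathway_set", class(out))
  out
}

#' Decompose crosstalking pathway pairs into sub-pathways
#'
#' Two pathways crosstalk when they share at least `min_overlap` genes.
#' Every crosstalking unordered pair (A, B) generates three candidate
#' sub-pathways — the shared part `A n B`, the A-unique part `A - (A n B)`
#' and the B-unique part `B - (A n B)` — of which only those with at least
#' `min_size` genes are retained. The three parts of a pair are pairwise
#' disjoint and their union is `A u B`.
#'
#' Identical gene sets arising from different pairs are kept as distinct
#' entries: the sub-pathway id `"A|B|part"` records provenance, and all
#' downstream feature matrices key on that id.
#'
#' @param selected A [gene_set_collection()] (typically the top-ranked
#'   pathways from [select_top()]).
#' @param min_overlap Minimum shared-gene count for a pair to crosstalk.
#' @param min_size Minimum genes a retained sub-pathway must have.
#' @return A `subpathway_set` tibble with columns `subpathway_id`,
#'   `parent_a`, `parent_b`, `part`, `genes` (list) and `n_genes`, ordered
#'   by pair (collection order) then part (intersection, A_unique,
#'   B_unique). May have zero rows.
#' @export
decompose_crosstalk <- function(selected, min_overlap = 3, min_size = 3) {
  selected <- as_gene_set_collection(selected)
  if (nrow(selected) == 0) {
    abort("Cannot decompose an empty collection.",
          class = "pascrosstalk_input_error")
  }
  sets <- gene_sets(selected)
  ids <- names(sets)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      shared <- intersect(sets[[i]], sets[[j]])
      if (length(shared) < min_overlap) next
      parts <- list(intersection = shared,
                    A_unique = setdiff(sets[[i]], shared),
                    B_unique = setdiff(sets[[j]], shared))
      keep <- lengths(parts) >= min_size
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- new_subpathway_set(
        parent_a = rep(ids[i], sum(keep)),
        parent_b = rep(ids[j], sum(keep)),
        part = names(parts)[keep],
        genes = unname(parts[keep]))
    }
  }
  if (length(rows) == 0) {
    return(new_subpathway_set(character(), character(), character(), list()))
  }
  out <- bind_rows(rows)
  class(out) <- c("subpathway_set", class(out))
  out
}

#' @export
print.subpathway_set <- function(x, ...) {
  cat("# A subpathway_set: ", nrow(x), " sub-pathways from ",
      length(unique(c(x$parent_a, x$parent_b))), " parent pathways\n",
      sep = "")
  NextMethod()
}

#' Filter a subpathway_set by id
#'
#' @param subpaths A `subpathway_set`.
#' @param ids Sub-pathway ids to keep (order preserved from `ids`).
#' @return A `subpathway_set`.
#' @export
subpathways_by_id <- function(subpaths, ids) {
  missing_ids <- setdiff(ids, subpaths$subpathway_id)
  if (length(missing_ids) > 0) {
    abort(paste0("Unknown sub-pathway id(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "pascrosstalk_input_error")
  }
  out <- subpaths[match(ids, subpaths$subpathway_id), ]
  class(out) <- c("subpathway_set", class(out))
  out
}
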