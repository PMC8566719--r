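#' Construct a gene-set collection
#'
#' A gene-set collection is a tibble with one row per pathway (or derived
#' sub-pathway) and columns `pathway_id`, `description` and a list-column
#' `genes` of character vectors. Genes within a set have set semantics:
#' duplicates are collapsed and order is not meaningful.
#'
#' @param pathway_id Character vector of unique set identifiers.
#' @param genes List of character vectors, one per set; each must be
#'   non-empty after duplicate collapse.
#' @param description Optional character vector of free-text descriptions
#'   (defaults to `""`).
#'
#' @return A `gene_set_collection`, a tibble subclass.
#' @export
#' @examples
#' gene_set_collection(c("P1", "P2"), list(c("A", "B", "C"), c("B", "D")))
gene_set_collection <- function(pathway_id, genes, description = NULL) {
  pathway_id <- as.character(pathway_id)
  if (anyDuplicated(pathway_id)) {
    dup <- unique(pathway_id[duplicated(pathway_id)])
    abort(paste0("Duplicate pathway_id: ", paste(dup, collapse = ", ")),
          class = "pascrosstalk_format_error")
  }
  if (is.null(description)) description <- rep("", length(pathway_id))
  genes <- map(genes, function(g) unique(as.character(g)))
  if (length(pathway_id) > 0 && any(lengths(genes) == 0)) {
    abort("Every gene set must be non-empty.",
          class = "pascrosstalk_format_error")
  }
  out <- tibble(pathway_id = pathway_id,
                description = as.character(description),
                genes = genes)
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Test or coerce gene-set collections
#'
#' @param x An object.
#' @return `is_gene_set_collection()` returns a logical scalar;
#'   `as_gene_set_collection()` returns a `gene_set_collection`.
#' @export
is_gene_set_collection <- function(x) inherits(x, "gene_set_collection")

#' @rdname is_gene_set_collection
#' @export
as_gene_set_collection <- function(x) {
  if (is_gene_set_collection(x)) return(x)
  if (inherits(x, "subpathway_set")) {
    return(gene_set_collection(x$subpathway_id, x$genes,
                               paste(x$parent_a, x$parent_b, x$part)))
  }
  if (is.list(x) && !is.data.frame(x)) {
    return(gene_set_collection(names(x), x))
  }
  abort("Cannot coerce this object to a gene_set_collection.")
}

#' Extract gene sets as a named list
#'
#' @param collection A `gene_set_collection`.
#' @return Named list of character vectors.
#' @export
gene_sets <- function(collection) {
  setNames(collection$genes, collection$pathway_id)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format: each line holds a set
#' identifier, a description, then one or more member gene symbols. File
#' order is preserved; duplicate genes within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path), class = "pascrosstalk_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(gene_set_collection(character(), list(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(paste0("Malformed GMT line ", bad[1],
                 ": expected at least 3 tab-separated fields."),
          class = "pascrosstalk_format_error")
  }
  gene_set_collection(
    pathway_id = map_chr(fields, 1),
    description = map_chr(fields, 2),
    genes = map(fields, function(f) f[-(1:2)])
  )
}

#' Write a gene-set collection to GMT
#'
#' Round-trips with [read_gmt()]: identifiers and gene sets are reproduced
#' exactly. Tabs are the field separator, so no identifier, description or
#' gene symbol may contain a tab.
#'
#' @param collection A `gene_set_collection` (or coercible object).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  collection <- as_gene_set_collection(collection)
  all_fields <- c(collection$pathway_id, collection$description,
                  unlist(collection$genes, use.names = FALSE))
  if (any(grepl("\t", all_fields, fixed = TRUE))) {
    abort("GMT fields may not contain tab characters.",
          class = "pascrosstalk_format_error")
  }
  lines <- pmap(list(collection$pathway_id, collection$description,
                     collection$genes),
                function(id, d, g) paste(c(id, d, g), collapse = "\t"))
  lines <- as.character(unlist(lines, use.names = FALSE))
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort(paste0("Cannot write GMT to ", path, ": ",
                                     conditionMessage(e)),
                              class = "pascrosstalk_io_error")
  )
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("# A gene_set_collection: ", nrow(x), " sets\n", sep = "")
  NextMethod()
}
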