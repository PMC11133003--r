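#' Read gene sets from a GMT file
#'
#' Parses the tab-separated GMT dialect: one gene set per line with fields
#' `set id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate gene
#' symbols within a line are collapsed (first occurrence kept); symbols are
#' whitespace-trimmed and matched by exact string identity.
#'
#' @param path path to a GMT file.
#' @return an object of class `gene_set_collection`: a named list of character
#'   vectors of gene symbols with a `description` attribute per set, ordered
#'   as in the file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  descs <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields) | seq_along(fields) == 2]
    if (length(fields) < 3)
      stopf("malformed GMT line %d: fewer than 3 tab-separated fields", i)
    ids[[i]] <- fields[[1]]
    descs[[i]] <- fields[[2]]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(ids))
    stopf("duplicate pathway id(s) in GMT: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  structure(sets, descriptions = stats::setNames(descs, ids),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Build the binary gene-pathway mask
#'
#' Constructs the bi-adjacency mask matrix used to constrain the connections
#' between the gene layer and the pathway layer: entry (i, j) is 1 exactly
#' when gene i belongs to pathway j. Pathways are first restricted to the
#' supplied gene universe; pathways whose restricted size falls outside
#' `[min_size, max_size]` are dropped, and genes annotated to no surviving
#' pathway are removed. Row order follows `genes`, column order follows the
#' collection.
#'
#' @param genes character vector of gene identifiers (the dataset's universe).
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param min_size,max_size inclusive bounds on restricted pathway size.
#' @return an object of class `pathway_mask` with elements `matrix`
#'   (genes x pathways, 0/1), `gene_ids` and `pathway_ids`.
#' @export
build_mask <- function(genes, collection, min_size = 10L, max_size = 500L) {
  genes <- trimws(as.character(genes))
  if (length(genes) == 0) stopf("empty gene universe")
  if (anyDuplicated(genes)) stopf("duplicate gene identifiers in `genes`")
  if (min_size < 1 || min_size > max_size)
    stopf("require 1 <= min_size <= max_size")
  restricted <- lapply(collection, function(g) intersect(trimws(g), genes))
  keep <- vapply(restricted, function(g)
    length(g) >= min_size && length(g) <= max_size, logical(1))
  restricted <- restricted[keep]
  if (length(restricted) == 0)
    stopf("no pathway survives the size filter [%d, %d]; model unbuildable",
          min_size, max_size)
  used_genes <- genes[genes %in% unique(unlist(restricted))]
  m <- matrix(0, nrow = length(used_genes), ncol = length(restricted),
              dimnames = list(used_genes, names(restricted)))
  for (j in seq_along(restricted)) m[restricted[[j]], j] <- 1
  structure(list(matrix = m, gene_ids = used_genes,
                 pathway_ids = names(restricted)),
            class = "pathway_mask")
}

#' @export
print.pathway_mask <- function(x, ...) {
  cat(sprintf("pathway_mask: %d genes x %d pathways, density %.3f\n",
              length(x$gene_ids), length(x$pathway_ids), mean(x$matrix)))
  invisible(x)
}

#' Align an expression dataset to a pathway mask
#'
#' Subsets and reorders the dataset's gene columns to exactly the mask's gene
#' order so that expression columns line up with the mask rows. Idempotent.
#'
#' @param dataset a `spin_dataset`.
#' @param mask a `pathway_mask`.
#' @return the dataset restricted to `mask$gene_ids`, in mask order.
#' @export
align_dataset <- function(dataset, mask) {
  stopifnot(inherits(dataset, "spin_dataset"), inherits(mask, "pathway_mask"))
  missing <- setdiff(mask$gene_ids, dataset$gene_ids)
  if (length(missing) > 0)
    stopf("mask gene(s) absent from dataset: %s", paste(missing, collapse = ", "))
  dataset$expression <- dataset$expression[, mask$gene_ids, drop = FALSE]
  dataset$gene_ids <- mask$gene_ids
  dataset
}
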