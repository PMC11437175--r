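#' Canonical taxonomic rank ladder
#' @export
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Create an annotation set from lineages
#'
#' @param lineages Named list: contig id -> character vector of rank labels
#'   from domain downward (length 0-7; a contiguous prefix of the ladder).
#'   Empty vectors mark unannotated contigs.
#' @param source_name Identity of the classifier that produced the labels.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(lineages, source_name = "unknown") {
  ids <- names(lineages)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("every lineage must be named by its contig id")
  if (anyDuplicated(ids))
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  too_deep <- lengths(lineages) > length(TAX_RANKS)
  if (any(too_deep))
    stop("lineage deeper than ", length(TAX_RANKS), " ranks for contig(s): ",
         paste(ids[too_deep], collapse = ", "))
  lineages <- lapply(lineages, function(x) as.character(x[nzchar(x)]))
  structure(list(lineages = lineages, source_name = source_name),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n <- length(x$lineages)
  cat(sprintf("annotation_set '%s': %d contigs (%d annotated)\n",
              x$source_name, n, sum(lengths(x$lineages) > 0)))
  invisible(x)
}

#' Parse classifier annotations from a lineage TSV
#'
#' Two columns: contig id and a separator-delimited lineage string, deepest
#' rank last, possibly truncated at any rank. An empty second column marks an
#' unannotated contig. Names are disambiguated by full path downstream, so
#' homonymous taxa under different parents stay distinct.
#'
#' @param path Path to the TSV (no header by default).
#' @param sep Label separator within the lineage string (default `";"`).
#' @param header Whether the file has a header row.
#' @param source_name Classifier identity recorded on the set.
#' @return An `annotation_set`.
#' @export
parse_annotations <- function(path, sep = ";", header = FALSE,
                              source_name = basename(path)) {
  if (!file.exists(path)) stop("annotation TSV not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = header,
                          data.table = FALSE, colClasses = "character",
                          fill = TRUE)
  if (ncol(dt) < 1) stop("annotation TSV is empty: ", path)
  if (ncol(dt) == 1) dt[[2]] <- ""
  ids <- as.character(dt[[1]])
  lineage_str <- as.character(dt[[2]])
  lineage_str[is.na(lineage_str)] <- ""
  lineages <- lapply(strsplit(lineage_str, sep, fixed = TRUE), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  deep <- lengths(lineages) > length(TAX_RANKS)
  if (any(deep))
    stop("more than ", length(TAX_RANKS), " rank fields at line(s): ",
         paste(which(deep) + as.integer(header), collapse = ", "))
  names(lineages) <- ids
  annotation_set(lineages, source_name = source_name)
}

#' Write an annotation set as a lineage TSV
#' @param annotations An `annotation_set`.
#' @param path Output path.
#' @param sep Lineage separator.
#' @export
write_annotations <- function(annotations, path, sep = ";") {
  lines <- vapply(annotations$lineages, paste, character(1), collapse = sep)
  dt <- data.table::data.table(contig = names(annotations$lineages),
                               lineage = unname(lines))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Build the dataset-specific taxonomic tree
#'
#' Inserts every observed lineage path under a synthetic root, so the output
#' space of the refiner is restricted to taxa that appear in the annotations.
#' Nodes are keyed by full path, leaves are the childless nodes, and leaves
#' are indexed deterministically by lexicographic full path.
#'
#' @param annotations An `annotation_set` with at least one non-empty lineage.
#' @return Object of class `taxtree` with fields `nodes` (data.frame: id,
#'   path, name, rank, parent; parent 0 denotes the root), `n_leaves`,
#'   `leaf_ids` (node ids in leaf-index order), `path_to_id`, `children`
#'   (per node id, including root slot `"0"`), `desc_leaves` (per node, the
#'   leaf indices below it) and `incidence` (sparse N_l x n_nodes 0/1 map).
#' @export
build_taxtree <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  lineages <- annotations$lineages[lengths(annotations$lineages) > 0]
  if (length(lineages) == 0) stop("all lineages are empty; cannot build a tree")

  paths <- unique(unlist(lapply(lineages, function(lab) {
    vapply(seq_along(lab), function(r) paste(lab[1:r], collapse = ";"),
           character(1))
  })))
  paths <- sort(paths)                    # parents sort before children
  ranks <- lengths(strsplit(paths, ";", fixed = TRUE))
  ord <- order(ranks, paths)
  paths <- paths[ord]; ranks <- ranks[ord]

  id <- seq_along(paths)
  path_to_id <- stats::setNames(id, paths)
  parent_path <- vapply(strsplit(paths, ";", fixed = TRUE), function(x) {
    if (length(x) == 1) "" else paste(x[-length(x)], collapse = ";")
  }, character(1))
  parent <- ifelse(parent_path == "", 0L,
                   unname(path_to_id[parent_path]))
  name <- vapply(strsplit(paths, ";", fixed = TRUE), function(x) x[length(x)],
                 character(1))
  nodes <- data.frame(id = id, path = paths, name = name, rank = ranks,
                      parent = as.integer(parent), stringsAsFactors = FALSE)

  children <- vector("list", length(id) + 1)  # slot 1 is the root ("0")
  names(children) <- c("0", as.character(id))
  for (i in id) {
    key <- as.character(nodes$parent[i])
    children[[key]] <- c(children[[key]], i)
  }
  # deterministic greedy traversal: children in lexicographic path order
  children <- lapply(children, function(ch) ch[order(nodes$path[ch])])

  is_leaf <- vapply(as.character(id), function(k) length(children[[k]]) == 0,
                    logical(1))
  leaf_ids <- id[is_leaf][order(nodes$path[id[is_leaf]])]
  n_leaves <- length(leaf_ids)
  leaf_index_of <- integer(length(id))
  leaf_index_of[leaf_ids] <- seq_len(n_leaves)

  desc_leaves <- vector("list", length(id))
  for (i in rev(id)) {                    # children have larger ids
    ch <- children[[as.character(i)]]
    desc_leaves[[i]] <- if (length(ch) == 0) leaf_index_of[i]
      else sort(unlist(desc_leaves[ch]))
  }

  pairs <- do.call(rbind, lapply(id, function(i)
    cbind(leaf = desc_leaves[[i]], node = i)))
  incidence <- Matrix::sparseMatrix(i = pairs[, "leaf"], j = pairs[, "node"],
                                    x = 1, dims = c(n_leaves, length(id)))

  structure(list(nodes = nodes, n_leaves = n_leaves, leaf_ids = leaf_ids,
                 leaf_paths = nodes$path[leaf_ids], path_to_id = path_to_id,
                 children = children, desc_leaves = desc_leaves,
                 incidence = incidence),
            class = "taxtree")
}

#' @export
print.taxtree <- function(x, ...) {
  cat(sprintf("taxtree: %d nodes, %d leaves, max depth %d\n",
              nrow(x$nodes), x$n_leaves, max(x$nodes$rank)))
  invisible(x)
}

#' Ancestor path of a tree node
#'
#' @param tree A `taxtree`.
#' @param node_id Node id (or full path string).
#' @return Integer vector of node ids from the domain-level ancestor down to
#'   `node_id` inclusive; the synthetic root is excluded.
#' @export
node_path <- function(tree, node_id) {
  if (is.character(node_id)) {
    if (node_id == "" || identical(node_id, "0")) return(integer(0))
    node_id <- tree$path_to_id[node_id]
    if (is.na(node_id)) stop("unknown node path")
  }
  node_id <- as.integer(node_id)
  if (node_id == 0L) return(integer(0))
  if (node_id < 1L || node_id > nrow(tree$nodes)) stop("unknown node id: ", node_id)
  path <- integer(tree$nodes$rank[node_id])
  i <- node_id
  k <- length(path)
  while (i != 0L) {
    path[k] <- i
    i <- tree$nodes$parent[i]
    k <- k - 1L
  }
  path
}

#' Resolve a lineage to its node id
#' @param tree A `taxtree`.
#' @param labels Character vector of rank labels (domain downward).
#' @return Node id, or `NA` if the path is absent from the tree (0 for an
#'   empty lineage, i.e. the root).
#' @export
lineage_node <- function(tree, labels) {
  if (length(labels) == 0) return(0L)
  id <- tree$path_to_id[paste(labels, collapse = ";")]
  if (is.na(id)) NA_integer_ else unname(id)
}

#' Serialize a taxonomic tree to text
#'
#' One line per node: `full_path<TAB>rank_name`.
#' @param tree A `taxtree`.
#' @param path Output file path.
#' @export
write_taxtree <- function(tree, path) {
  writeLines(paste(tree$nodes$path, TAX_RANKS[tree$nodes$rank], sep = "\t"),
             path)
  invisible(path)
}

#' Read a serialized taxonomic tree
#' @param path File written by [write_taxtree()].
#' @return A `taxtree` (rebuilt from the node paths).
#' @export
read_taxtree <- function(path) {
  lines <- readLines(path)
  node_paths <- sub("\t.*$", "", lines)
  lineages <- strsplit(node_paths, ";", fixed = TRUE)
  names(lineages) <- paste0("n", seq_along(lineages))
  build_taxtree(annotation_set(lineages, source_name = "serialized"))
}
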