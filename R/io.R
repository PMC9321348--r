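#' Read a two-column association edge list
#'
#' Reads whitespace- or tab-delimited `source target` lines into a tibble of
#' unique edges. Lines starting with `#` and blank lines are skipped; extra
#' columns beyond the first two are ignored. Duplicate edges are dropped
#' (first occurrence kept, preserving first-seen order) and their count
#' reported via a message.
#'
#' @param path Path to the edge-list file.
#' @param source_kind,target_kind Entity kind of each column, one of
#'   `"miRNA"`, `"disease"`, `"protein"`. The two kinds must differ.
#' @return A tibble with columns `source` and `target` and attributes
#'   `source_kind` / `target_kind`.
#' @examples
#' f <- tempfile()
#' writeLines(c("m1 d1", "m2 d1", "m1 d1"), f)
#' read_edge_list(f, "miRNA", "disease")
#' @export
read_edge_list <- function(path, source_kind = c("miRNA", "disease", "protein"),
                           target_kind = c("disease", "miRNA", "protein")) {
  source_kind <- match.arg(source_kind)
  target_kind <- match.arg(target_kind)
  if (identical(source_kind, target_kind)) {
    abort("`source_kind` and `target_kind` must differ.")
  }
  if (!file.exists(path)) {
    abort(paste0("Edge-list file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  edges <- parse_two_column(lines, keep, what = "edge list")
  if (nrow(edges) == 0L) {
    warn(paste0("Edge list '", path, "' contains no edges."))
  }
  dup <- duplicated(paste(edges$source, edges$target, sep = "\r"))
  if (any(dup)) {
    inform(paste0("Dropped ", sum(dup), " duplicate edge(s) from '", path, "'."))
  }
  out <- edges[!dup, , drop = FALSE]
  attr(out, "source_kind") <- source_kind
  attr(out, "target_kind") <- target_kind
  out
}

# shared 2-column line parser; errors name the (1-based) offending file line
parse_two_column <- function(lines, keep, what) {
  idx <- which(keep)
  src <- character(length(idx))
  tgt <- character(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "[ \t]+")[[1]]
    if (length(fields) < 2L) {
      abort(paste0("Malformed ", what, " line ", idx[k],
                   ": expected at least 2 fields, got ", length(fields), "."))
    }
    src[k] <- fields[1L]
    tgt[k] <- fields[2L]
  }
  tibble::tibble(source = src, target = tgt)
}

#' Build a binary bipartite adjacency matrix from an edge table
#'
#' Converts an edge tibble (as returned by [read_edge_list()]) into a binary
#' matrix whose rows and columns are named. `A[i, j] = 1` iff
#' `(row i, col j)` is an edge.
#'
#' @param edges A tibble with `source` and `target` columns.
#' @param row_names,col_names Ordered entity name vectors. When `NULL`,
#'   first-seen order in `edges` is used.
#' @return A binary integer matrix with `dimnames`.
#' @examples
#' e <- tibble::tibble(source = c("m1", "m2"), target = c("d1", "d2"))
#' build_adjacency(e)
#' @export
build_adjacency <- function(edges, row_names = NULL, col_names = NULL) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  if (is.null(row_names)) row_names <- unique(edges$source)
  if (is.null(col_names)) col_names <- unique(edges$target)
  bad_r <- setdiff(edges$source, row_names)
  bad_c <- setdiff(edges$target, col_names)
  if (length(bad_r) || length(bad_c)) {
    abort(paste0("Edge endpoint(s) missing from supplied name lists: ",
                 paste(head(c(bad_r, bad_c), 5L), collapse = ", ")))
  }
  if (anyDuplicated(row_names) || anyDuplicated(col_names)) {
    abort("Row/column name lists must not contain duplicates.")
  }
  A <- matrix(0L, length(row_names), length(col_names),
              dimnames = list(row_names, col_names))
  if (nrow(edges) > 0L) {
    A[cbind(match(edges$source, row_names), match(edges$target, col_names))] <- 1L
  }
  A
}

#' List the nonzero entries of an adjacency matrix as an edge tibble
#'
#' Inverse of [build_adjacency()]: recovers the (deduplicated) edge set.
#'
#' @param A A matrix with `dimnames`.
#' @return A tibble with `source`, `target` columns, ordered by row then
#'   column index.
#' @export
adjacency_edges <- function(A) {
  idx <- which(A != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(source = rownames(A)[idx[, 1L]],
                 target = colnames(A)[idx[, 2L]])
}

#' Read a disease hierarchy as a directed acyclic graph
#'
#' Reads two-column `parent child` lines into a `disease_dag` object and
#' verifies acyclicity. The hierarchy may have multiple roots.
#'
#' @param path Path to the DAG file.
#' @return A `disease_dag`: list with `nodes` (character) and `edges`
#'   (tibble with `parent`, `child`).
#' @export
read_disease_dag <- function(path) {
  if (!file.exists(path)) abort(paste0("DAG file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  tab <- parse_two_column(lines, keep, what = "DAG")
  names(tab) <- c("parent", "child")
  dup <- duplicated(paste(tab$parent, tab$child, sep = "\r"))
  tab <- tab[!dup, , drop = FALSE]
  disease_dag(tab)
}

#' Construct a disease DAG from a parent-child edge table
#'
#' @param edges Tibble (or data frame) with columns `parent` and `child`.
#' @param nodes Optional character vector of node names; defaults to the
#'   union of edge endpoints.
#' @return A `disease_dag` object.
#' @export
disease_dag <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("parent", "child") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (any(!nzchar(edges$parent)) || any(!nzchar(edges$child))) {
    abort("DAG node names must be non-empty.")
  }
  if (is.null(nodes)) {
    nodes <- unique(c(edges$parent, edges$child))
  } else {
    nodes <- as.character(nodes)
    miss <- setdiff(unique(c(edges$parent, edges$child)), nodes)
    if (length(miss)) {
      abort(paste0("DAG edge endpoint(s) not in `nodes`: ",
                   paste(head(miss, 5L), collapse = ", ")))
    }
  }
  cyc <- find_cycle(nodes, edges)
  if (!is.null(cyc)) {
    abort(paste0("Disease hierarchy contains a directed cycle: ",
                 paste(cyc, collapse = " -> ")))
  }
  structure(list(nodes = nodes, edges = edges), class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("<disease_dag> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " parent->child edges, ", sum(!(x$nodes %in% x$edges$child)),
      " root(s)\n", sep = "")
  invisible(x)
}

# DFS cycle finder; returns one cycle as a node path, or NULL if acyclic
find_cycle <- function(nodes, edges) {
  kids <- split(edges$child, factor(edges$parent, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, i = 0L))
    state[[start]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ch <- kids[[top$node]]
      if (top$i < length(ch)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- ch[[top$i + 1L]]
        if (state[[nxt]] == 1L) {
          path <- nxt
          cur <- top$node
          while (!identical(cur, nxt)) {
            path <- c(path, cur)
            cur <- parent[[cur]]
          }
          return(rev(c(path, nxt)))
        }
        if (state[[nxt]] == 0L) {
          state[[nxt]] <- 1L
          parent[[nxt]] <- top$node
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
        }
      } else {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' Ancestors of a disease in the hierarchy
#'
#' @param dag A `disease_dag`.
#' @param disease Disease name.
#' @param include_self Include the disease itself (default `FALSE`).
#' @return Character vector of ancestor names.
#' @export
dag_ancestors <- function(dag, disease, include_self = FALSE) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!disease %in% dag$nodes) {
    abort(paste0("Unknown disease in DAG: ", disease))
  }
  parents <- split(dag$edges$parent, dag$edges$child)
  seen <- character(0)
  frontier <- disease
  while (length(frontier)) {
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    up <- setdiff(up, c(seen, disease))
    seen <- c(seen, up)
    frontier <- up
  }
  if (include_self) c(disease, seen) else seen
}

#' Write an adjacency or similarity matrix as tab-delimited text
#'
#' Dense export with a header row and a leading name column, readable back
#' with [read_matrix_tsv()].
#'
#' @param A Matrix with `dimnames`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(A, path) {
  stopifnot(!is.null(rownames(A)), !is.null(colnames(A)))
  utils::write.table(A, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param path Input path.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                              check.names = FALSE))
}
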