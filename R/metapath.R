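#' Meta-path adjacency through a mediator entity type
#'
#' Two same-type entities are connected when they can reach each other
#' through at least one shared mediator: `out[i, j] = 1` iff row `i` and row
#' `j` of the bipartite matrix `B` share a nonzero column (`(B B^T)[i, j] > 0`),
#' for `i != j`. The diagonal is left at 0 so that a zero row still signals
#' an entity with no mediated association; self-loops are added when modules
#' are assembled ([assemble_module()]).
#'
#' This yields the four derived matrices of the heterogeneous network:
#' miRNA-miRNA via disease or protein, and disease-disease via miRNA or
#' protein.
#'
#' @param B Binary matrix, rows = entities being connected, columns =
#'   mediator entities.
#' @return Symmetric binary integer matrix with zero diagonal and the row
#'   names of `B`.
#' @examples
#' B <- rbind(m1 = c(1, 1, 0), m2 = c(0, 1, 0), m3 = c(0, 0, 0))
#' metapath_adjacency(B)
#' @export
metapath_adjacency <- function(B) {
  B <- as.matrix(B)
  stopifnot(all(B %in% c(0, 1)))
  M <- (tcrossprod(B) > 0) * 1L
  diag(M) <- 0L
  dimnames(M) <- list(rownames(B), rownames(B))
  M
}

#' Assemble one network module as a block matrix
#'
#' Stacks a same-type miRNA relation (similarity or meta-path adjacency), the
#' cross-type association matrix and a same-type disease relation into the
#' symmetric `(n_m + n_d)` square block matrix
#' `[[TL, A], [t(A), BR]]`, then inserts unit self-loops so every node has at
#' least one neighbor. Per-node input features are the rows of the assembled
#' matrix.
#'
#' @param TL Symmetric miRNA-side matrix (`n_m` square).
#' @param A Binary miRNA-by-disease association matrix.
#' @param BR Symmetric disease-side matrix (`n_d` square).
#' @return A `module_graph`: list with `values` (the block matrix),
#'   `node_types` (factor `"miRNA"`/`"disease"` per node), `n_m`, `n_d`.
#' @export
assemble_module <- function(TL, A, BR) {
  TL <- as.matrix(TL); A <- as.matrix(A); BR <- as.matrix(BR)
  n_m <- nrow(A); n_d <- ncol(A)
  if (!all(dim(TL) == c(n_m, n_m)) || !all(dim(BR) == c(n_d, n_d))) {
    abort("Block shapes are inconsistent with the association matrix.")
  }
  if (max(abs(TL - t(TL))) > 1e-10 || max(abs(BR - t(BR))) > 1e-10) {
    abort("`TL` and `BR` must be symmetric.")
  }
  G <- rbind(cbind(TL, A), cbind(t(A), BR))
  diag(G) <- pmax(diag(G), 1)
  nm <- c(rownames(A) %||% paste0("m", seq_len(n_m)),
          colnames(A) %||% paste0("d", seq_len(n_d)))
  dimnames(G) <- list(nm, nm)
  structure(
    list(values = G,
         node_types = factor(rep(c("miRNA", "disease"), c(n_m, n_d)),
                             levels = c("miRNA", "disease")),
         n_m = n_m, n_d = n_d),
    class = "module_graph"
  )
}

#' @export
print.module_graph <- function(x, ...) {
  cat("<module_graph> ", x$n_m, " miRNA + ", x$n_d, " disease nodes, ",
      sum(x$values != 0), " nonzero entries\n", sep = "")
  invisible(x)
}

#' Edge list of a module graph
#'
#' Pairs of nodes with strictly positive entries (including self-loops).
#'
#' @param module A `module_graph`.
#' @return Tibble with `from`, `to` node indices and the entry `weight`.
#' @export
module_edges <- function(module) {
  idx <- which(module$values != 0, arr.ind = TRUE)
  tibble::tibble(from = unname(idx[, 1L]), to = unname(idx[, 2L]),
                 weight = module$values[idx])
}

#' Build the three heterogeneous-network modules
#'
#' Constructs the multi-module representation of the network:
#' * `G1` — integrated similarities: `[[MS, A], [t(A), DS]]`;
#' * `G2` — association meta-paths: miRNA-miRNA via shared disease and
#'   disease-disease via shared miRNA around `A`;
#' * `G3` — protein meta-paths: miRNA-miRNA via shared target protein and
#'   disease-disease via shared protein around `A`.
#'
#' @param A Binary miRNA-by-disease association matrix.
#' @param MS,DS Integrated miRNA / disease similarity matrices
#'   (see [integrated_similarities()]).
#' @param MP Binary miRNA-by-protein association matrix (rows aligned
#'   with the rows of `A`).
#' @param DP Binary disease-by-protein association matrix (rows aligned
#'   with the columns of `A`).
#' @return List of three `module_graph` objects named `G1`, `G2`, `G3`.
#' @export
build_modules <- function(A, MS, DS, MP, DP) {
  stopifnot(nrow(MP) == nrow(A), nrow(DP) == ncol(A))
  list(
    G1 = assemble_module(MS, A, DS),
    G2 = assemble_module(metapath_adjacency(A), A, metapath_adjacency(t(A))),
    G3 = assemble_module(metapath_adjacency(MP), A, metapath_adjacency(DP))
  )
}
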