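#' Gaussian interaction profile kernel bandwidth
#'
#' Bandwidth for the GIP kernel over binary interaction profiles, normalized
#' by the mean squared profile norm: `delta = n / sum_i ||x_i||^2` where the
#' sum runs over the `n` profile rows. With this convention the kernel of two
#' identical profiles is 1 and similarity decays with profile distance on the
#' scale of a typical profile.
#'
#' @param profiles Binary matrix, one interaction profile per row.
#' @return Positive scalar bandwidth.
#' @examples
#' gip_bandwidth(rbind(c(1, 0), c(0, 1))) # 1
#' @export
gip_bandwidth <- function(profiles) {
  profiles <- as.matrix(profiles)
  tot <- sum(profiles^2)
  if (tot == 0) {
    abort("All interaction profiles are zero; GIP bandwidth is undefined.")
  }
  nrow(profiles) / tot
}

#' Gaussian interaction profile kernel similarity
#'
#' `S[i, j] = exp(-delta * ||x_i - x_j||^2)` over the rows of `profiles`,
#' with the bandwidth of [gip_bandwidth()]. Entries lie in `(0, 1]` and the
#' diagonal is exactly 1.
#'
#' @inheritParams gip_bandwidth
#' @param delta Optional bandwidth override; defaults to
#'   `gip_bandwidth(profiles)`.
#' @return Symmetric similarity matrix with the row names of `profiles`.
#' @export
gip_kernel <- function(profiles, delta = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(delta)) delta <- gip_bandwidth(profiles)
  stopifnot(is.numeric(delta), delta > 0)
  rs <- rowSums(profiles^2)
  d2 <- outer(rs, rs, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0 # numerical guard
  S <- exp(-delta * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Semantic contribution of a disease's ancestors
#'
#' Decayed contribution scores over a disease and its ancestors in the
#' hierarchy: the disease itself contributes 1 and each ancestor `a`
#' contributes `max(sigma * DC(c))` over its children `c` lying on a
#' directed path from `a` down to the disease.
#'
#' @param dag A `disease_dag`.
#' @param disease Disease name.
#' @param sigma Semantic decay factor in `(0, 1)`; default 0.5.
#' @return Named numeric vector of contributions over the disease and its
#'   ancestors (values in `(0, 1]`, `disease` itself mapped to 1).
#' @examples
#' dag <- disease_dag(tibble::tibble(parent = c("r", "c"), child = c("c", "g")))
#' semantic_contribution(dag, "g") # g = 1, c = 0.5, r = 0.25
#' @export
semantic_contribution <- function(dag, disease, sigma = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), sigma > 0, sigma < 1)
  if (!disease %in% dag$nodes) {
    abort(paste0("Unknown disease in DAG: ", disease))
  }
  anc <- c(disease, dag_ancestors(dag, disease))
  dc <- stats::setNames(rep(0, length(anc)), anc)
  dc[[disease]] <- 1
  in_set <- dag$edges$parent %in% anc & dag$edges$child %in% anc
  ep <- dag$edges$parent[in_set]
  ec <- dag$edges$child[in_set]
  # fixed-point relaxation up the (acyclic) hierarchy; converges in <= |anc| passes
  repeat {
    changed <- FALSE
    for (k in seq_along(ep)) {
      cand <- sigma * dc[[ec[k]]]
      if (cand > dc[[ep[k]]]) {
        dc[[ep[k]]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dc
}

#' Semantic value of a disease
#'
#' Sum of the semantic contributions of the disease and all its ancestors.
#'
#' @param dc Named contribution vector from [semantic_contribution()].
#' @return Scalar semantic value (>= 1).
#' @export
semantic_value <- function(dc) {
  stopifnot(is.numeric(dc), length(dc) >= 1L)
  sum(dc)
}

#' Semantic similarity between two diseases
#'
#' Shared-ancestor similarity: contributions of the common
#' ancestor-or-self nodes, summed from both sides and normalized by the two
#' semantic values. Equals 1 for a disease with itself and 0 for diseases
#' with disjoint ancestor sets.
#'
#' @inheritParams semantic_contribution
#' @param di,dj Disease names.
#' @return Scalar in `[0, 1]`.
#' @export
semantic_similarity <- function(dag, di, dj, sigma = 0.5) {
  dci <- semantic_contribution(dag, di, sigma)
  dcj <- semantic_contribution(dag, dj, sigma)
  shared <- intersect(names(dci), names(dcj))
  sum(dci[shared] + dcj[shared]) / (sum(dci) + sum(dcj))
}

#' All-pairs semantic similarity over a disease list
#'
#' Computes the semantic similarity matrix for the requested diseases.
#' Diseases absent from the hierarchy get `NA` rows/columns (undefined), to
#' be filled by [integrate_similarity()] with the GIP kernel fallback.
#'
#' @inheritParams semantic_contribution
#' @param diseases Character vector of disease names (matrix order).
#' @return Square matrix with `NA` marking undefined entries.
#' @export
semantic_similarity_matrix <- function(dag, diseases, sigma = 0.5) {
  n <- length(diseases)
  S <- matrix(NA_real_, n, n, dimnames = list(diseases, diseases))
  known <- which(diseases %in% dag$nodes)
  if (length(known)) {
    dcs <- lapply(diseases[known], semantic_contribution, dag = dag, sigma = sigma)
    dvs <- vapply(dcs, sum, numeric(1))
    for (a in seq_along(known)) {
      for (b in seq_len(a)) {
        shared <- intersect(names(dcs[[a]]), names(dcs[[b]]))
        val <- if (length(shared)) {
          sum(dcs[[a]][shared] + dcs[[b]][shared]) / (dvs[a] + dvs[b])
        } else 0
        S[known[a], known[b]] <- S[known[b], known[a]] <- val
      }
      S[known[a], known[a]] <- 1
    }
  }
  S
}

#' miRNA functional similarity from shared disease associations
#'
#' Best-match-average similarity: two miRNAs are functionally similar when
#' the diseases associated with one are semantically close to the diseases
#' associated with the other,
#' `FS(i, j) = (sum_{d in D_i} max_{d' in D_j} SS(d, d') +
#'              sum_{d in D_j} max_{d' in D_i} SS(d, d')) / (|D_i| + |D_j|)`.
#' Entries are `NA` (undefined) when either miRNA has no associated disease
#' with a defined semantic similarity row; [integrate_similarity()] fills
#' those from the GIP kernel.
#'
#' @param A Binary miRNA-by-disease association matrix with `dimnames`.
#' @param SS Disease semantic similarity matrix over the columns of `A`
#'   (`NA` marking diseases outside the hierarchy).
#' @return Square miRNA similarity matrix with `NA` for undefined pairs.
#' @export
mirna_functional_similarity <- function(A, SS) {
  stopifnot(ncol(A) == nrow(SS), nrow(SS) == ncol(SS))
  if (!is.null(colnames(A)) && !is.null(rownames(SS)) &&
      !identical(colnames(A), rownames(SS))) {
    abort("Disease order of `A` columns and `SS` must agree.")
  }
  n_m <- nrow(A)
  defined <- which(!is.na(diag(SS))) # diseases inside the hierarchy
  dsets <- lapply(seq_len(n_m), function(i) intersect(which(A[i, ] != 0), defined))
  FS <- matrix(NA_real_, n_m, n_m, dimnames = list(rownames(A), rownames(A)))
  for (i in seq_len(n_m)) {
    Di <- dsets[[i]]
    if (!length(Di)) next
    FS[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      Dj <- dsets[[j]]
      if (!length(Dj)) next
      sub <- SS[Di, Dj, drop = FALSE]
      FS[i, j] <- FS[j, i] <-
        (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
        (length(Di) + length(Dj))
    }
  }
  FS
}

#' Integrate a primary similarity with a kernel fallback
#'
#' Entrywise rule: take the primary similarity where defined, otherwise the
#' fallback; the diagonal is forced to 1. This realizes the integrated
#' miRNA similarity (functional similarity backed by the GIP kernel) and the
#' integrated disease similarity (semantic similarity backed by the GIP
#' kernel).
#'
#' @param primary Square matrix with `NA` marking undefined entries.
#' @param fallback Square similarity matrix of the same shape and order.
#' @return Square similarity matrix with no `NA`, unit diagonal.
#' @export
integrate_similarity <- function(primary, fallback) {
  if (!all(dim(primary) == dim(fallback))) {
    abort("`primary` and `fallback` must have identical shapes.")
  }
  if (!is.null(rownames(primary)) && !is.null(rownames(fallback)) &&
      !identical(rownames(primary), rownames(fallback))) {
    abort("`primary` and `fallback` must use the same entity order.")
  }
  out <- ifelse(is.na(primary), fallback, primary)
  diag(out) <- 1
  dimnames(out) <- dimnames(fallback) %||% dimnames(primary)
  out
}

#' Integrated miRNA and disease similarity matrices
#'
#' Convenience wrapper computing both integrated similarities from the
#' association matrix and the disease hierarchy: miRNA functional similarity
#' with a row-profile GIP fallback, and disease semantic similarity with a
#' column-profile GIP fallback (each side uses its own bandwidth).
#'
#' @param A Binary miRNA-by-disease association matrix.
#' @param dag A `disease_dag` over (a subset of) the columns of `A`.
#' @param sigma Semantic decay factor.
#' @return List with elements `MS` (miRNA) and `DS` (disease).
#' @export
integrated_similarities <- function(A, dag, sigma = 0.5) {
  SS <- semantic_similarity_matrix(dag, colnames(A), sigma = sigma)
  MS <- integrate_similarity(mirna_functional_similarity(A, SS), gip_kernel(A))
  DS <- integrate_similarity(SS, gip_kernel(t(A)))
  list(MS = MS, DS = DS)
}
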