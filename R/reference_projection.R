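# Latent semantic indexing of a labeled healthy reference, projection of
# query cells into that space, and closest-normal kNN classification.

#' Split bulk profiles into pseudo-single cells
#'
#' Each bulk sample is split into `n_cells` pseudo-cells, each a
#' multinomial draw of `frags_per_cell` insertions with probabilities
#' proportional to the bulk profile. Summing the pseudo-cells of a sample
#' approximates its bulk profile.
#'
#' @param bulk_counts matrix, features x bulk samples.
#' @param n_cells pseudo-cells per sample (default 250).
#' @param frags_per_cell insertions per pseudo-cell (default 10000).
#' @param seed integer RNG seed.
#' @return integer matrix, features x (samples * n_cells); columns named
#'   `<sample>#<i>`, with a `sample` attribute giving the source sample per
#'   column.
#' @export
pseudo_single_cells <- function(bulk_counts, n_cells = 250L,
                                frags_per_cell = 10000L, seed = 1L) {
  n_cells <- assert_count(n_cells, "n_cells")
  frags_per_cell <- assert_count(frags_per_cell, "frags_per_cell")
  m <- as.matrix(bulk_counts)
  if (is.null(colnames(m))) colnames(m) <- sprintf("bulk%02d", seq_len(ncol(m)))
  with_seed(seed, {
    cols <- lapply(seq_len(ncol(m)), function(j) {
      p <- m[, j]
      if (sum(p) <= 0) stop("bulk sample ", colnames(m)[j],
                            " has no counts", call. = FALSE)
      rmultinom(n_cells, frags_per_cell, p / sum(p))
    })
    out <- do.call(cbind, cols)
    colnames(out) <- as.vector(vapply(colnames(m), function(s)
      sprintf("%s#%03d", s, seq_len(n_cells)), character(n_cells)))
    rownames(out) <- rownames(m)
    attr(out, "sample") <- rep(colnames(m), each = n_cells)
    out
  })
}

.tfidf <- function(counts, idf, binarize) {
  x <- as.matrix(counts)
  if (binarize) x <- (x > 0) + 0
  tot <- colSums(x)
  zero_cols <- tot == 0
  tot[zero_cols] <- 1
  tf <- sweep(x, 2, tot, "/")
  out <- tf * idf
  attr(out, "zero_cols") <- zero_cols
  out
}

#' Fit a latent semantic indexing model on a labeled reference
#'
#' Term-frequency scales each cell to unit total, inverse-document-
#' frequency weights each feature by `log(1 + n_cells / (1 + n_carrying))`,
#' and a truncated SVD of the TF-IDF matrix gives a k-dimensional
#' embedding. Component signs are fixed by forcing the largest-magnitude
#' feature loading of each component positive, so refits are comparable.
#' The model stores everything needed to project new cells without
#' refitting.
#'
#' @param reference count matrix, features x cells (rownames required).
#' @param k number of SVD components (default 30).
#' @param labels named character vector or vector aligned to columns:
#'   reference cell types.
#' @param binarize binarize counts before TF-IDF (default FALSE).
#' @return list of class `lsi_model`: `features`, `idf`, `u` (features x
#'   k loadings), `d` (singular values), `embedding` (cells x k),
#'   `labels`, `k`, `binarize`.
#' @export
fit_lsi <- function(reference, k = 30L, labels = NULL, binarize = FALSE) {
  k <- assert_count(k, "k", min = 2L)
  m <- as.matrix(reference)
  if (is.null(rownames(m))) stop("`reference` needs feature rownames",
                                 call. = FALSE)
  if (k > min(dim(m))) stop("`k` exceeds the matrix rank bound", call. = FALSE)
  if (!is.null(labels)) {
    labels <- if (!is.null(names(labels)) && !is.null(colnames(m))) {
      unname(labels[colnames(m)])
    } else as.character(labels)
    stopifnot(length(labels) == ncol(m))
  }
  n_cells <- ncol(m)
  df_count <- rowSums(m > 0)
  idf <- log(1 + n_cells / (1 + df_count))
  x <- .tfidf(m, idf, binarize)
  sv <- svd(x, nu = k, nv = k)
  u <- sv$u
  # sign convention: largest-|loading| of each component positive
  flip <- vapply(seq_len(k), function(j) {
    sign(u[which.max(abs(u[, j])), j])
  }, numeric(1))
  u <- sweep(u, 2, flip, "*")
  emb <- t(x) %*% u
  rownames(emb) <- colnames(m)
  structure(
    list(features = rownames(m), idf = idf, u = u, d = sv$d[seq_len(k)],
         embedding = emb, labels = labels, k = k, binarize = binarize),
    class = "lsi_model"
  )
}

#' Project query cells into a fitted LSI space
#'
#' The query is aligned to the model's feature index (missing features
#' zero-filled, extra features dropped), transformed with the model's
#' stored IDF weights and component loadings, and returned as a cells x k
#' embedding. The reference embedding is never recomputed.
#'
#' @param model an `lsi_model` from [fit_lsi()].
#' @param query count matrix, features x cells (rownames required).
#' @return numeric matrix, query cells x k, with attributes
#'   `feature_coverage` (fraction of model features present in the query)
#'   and `zero_cells` (logical; all-zero query cells, embedded at the
#'   origin).
#' @export
project_lsi <- function(model, query) {
  stopifnot(inherits(model, "lsi_model"))
  q <- as.matrix(query)
  if (is.null(rownames(q))) stop("`query` needs feature rownames", call. = FALSE)
  coverage <- mean(model$features %in% rownames(q))
  if (coverage < 0.1) {
    stop(sprintf("only %.1f%% of model features present in query",
                 100 * coverage), call. = FALSE)
  }
  aligned <- matrix(0, length(model$features), ncol(q),
                    dimnames = list(model$features, colnames(q)))
  shared <- intersect(model$features, rownames(q))
  aligned[shared, ] <- q[shared, , drop = FALSE]
  x <- .tfidf(aligned, model$idf, model$binarize)
  emb <- t(x) %*% model$u
  rownames(emb) <- colnames(q)
  attr(emb, "feature_coverage") <- coverage
  attr(emb, "zero_cells") <- attr(x, "zero_cols")
  if (any(attr(x, "zero_cols"))) {
    warning(sum(attr(x, "zero_cols")), " all-zero query cell(s) embedded ",
            "at the origin")
  }
  emb
}

#' Closest-normal classification by k nearest reference neighbors
#'
#' Each query cell is labeled with the majority cell type among its `k`
#' Euclidean-nearest reference cells in LSI space. Exact vote ties are
#' broken in favor of the tied label with the smallest mean neighbor
#' distance.
#'
#' @param model an `lsi_model` with `labels`.
#' @param query_embedding cells x k matrix from [project_lsi()].
#' @param k number of neighbors (default 10).
#' @return data.frame with `cell`, `label`, plus a `votes` attribute
#'   (query cells x types count matrix; rows sum to `k`).
#' @export
knn_classify <- function(model, query_embedding, k = 10L) {
  stopifnot(inherits(model, "lsi_model"))
  if (is.null(model$labels)) stop("model has no reference labels", call. = FALSE)
  k <- assert_count(k, "k")
  ref <- as.matrix(model$embedding)
  q <- as.matrix(query_embedding)
  if (k > nrow(ref)) stop("`k` exceeds the reference size", call. = FALSE)
  stopifnot(ncol(q) == ncol(ref))

  # squared Euclidean distances via the cross-product expansion
  d2 <- outer(rowSums(q^2), rowSums(ref^2), "+") - 2 * q %*% t(ref)
  d2[d2 < 0] <- 0
  types <- sort(unique(model$labels))
  votes <- matrix(0L, nrow(q), length(types),
                  dimnames = list(rownames(q), types))
  label <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    nn <- order(d2[i, ])[seq_len(k)]
    nn_lab <- model$labels[nn]
    tab <- table(factor(nn_lab, levels = types))
    votes[i, ] <- as.integer(tab)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(tp) mean(sqrt(d2[i, nn[nn_lab == tp]])),
                       numeric(1))
      top <- top[which.min(mean_d)]
    }
    label[i] <- top[1L]
  }
  out <- data.frame(cell = rownames(q) %||% sprintf("q%04d", seq_len(nrow(q))),
                    label = label, stringsAsFactors = FALSE)
  attr(out, "votes") <- votes
  out
}
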