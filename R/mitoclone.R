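# Mitochondrial clonal tracing: heteroplasmy computation, variant
# filtering, clustering into mitoclones, clone trees, frequencies,
# pseudobulks and the convergent-evolution test.

#' Per-cell heteroplasmy and per-variant quality statistics
#'
#' Heteroplasmy is the pooled-strand alternate fraction
#' `alt / (alt + ref)`; a cell with zero coverage at a variant is missing
#' (NA), not zero. Per-variant statistics: the number of cells in which
#' the variant is detected (pooled alt > 0), the Pearson correlation of
#' forward versus reverse alternate counts across detected cells (NA when
#' fewer than two such cells or when either strand is constant), and the
#' mean total coverage across all cells.
#'
#' @param allele_counts list of four variants x cells matrices: `alt_fwd`,
#'   `alt_rev`, `ref_fwd`, `ref_rev`.
#' @return list with `heteroplasmy` (variants x cells, NA where coverage
#'   is 0), `coverage` (variants x cells), `stats` (data.frame: variant,
#'   n_cells_detected, strand_correlation, mean_coverage).
#' @export
compute_heteroplasmy <- function(allele_counts) {
  need <- c("alt_fwd", "alt_rev", "ref_fwd", "ref_rev")
  stopifnot(all(need %in% names(allele_counts)))
  a_f <- as.matrix(allele_counts$alt_fwd)
  a_r <- as.matrix(allele_counts$alt_rev)
  r_f <- as.matrix(allele_counts$ref_fwd)
  r_r <- as.matrix(allele_counts$ref_rev)
  if (any(a_f < 0 | a_r < 0 | r_f < 0 | r_r < 0)) {
    stop("allele counts must be non-negative", call. = FALSE)
  }
  alt <- a_f + a_r
  cov <- alt + r_f + r_r
  het <- alt / cov
  het[cov == 0] <- NA_real_

  strand_cor <- vapply(seq_len(nrow(alt)), function(v) {
    carrier <- a_f[v, ] > 0 | a_r[v, ] > 0
    if (sum(carrier) < 2L) return(NA_real_)
    x <- a_f[v, carrier]; y <- a_r[v, carrier]
    if (all(x == y)) return(1)  # exact concordance, no floating-point slack
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))

  stats <- data.frame(
    variant = rownames(alt) %||% sprintf("var%04d", seq_len(nrow(alt))),
    n_cells_detected = as.integer(rowSums(alt > 0)),
    strand_correlation = strand_cor,
    mean_coverage = rowMeans(cov),
    stringsAsFactors = FALSE
  )
  list(heteroplasmy = het, coverage = cov, stats = stats)
}

#' Strict quality filter on mitochondrial variants
#'
#' A variant passes when it is detected in more than `min_cells` cells,
#' its strand correlation exceeds `min_strand_cor`, and its mean coverage
#' exceeds `min_cov` -- all strictly.
#'
#' @param stats data.frame from [compute_heteroplasmy()].
#' @param min_cells,min_strand_cor,min_cov strict lower thresholds
#'   (defaults 3, 0.65, 10).
#' @return character vector of passing variant identifiers.
#' @export
filter_variants <- function(stats, min_cells = 3, min_strand_cor = 0.65,
                            min_cov = 10) {
  pass <- stats$n_cells_detected > min_cells &
    !is.na(stats$strand_correlation) &
    stats$strand_correlation > min_strand_cor &
    stats$mean_coverage > min_cov
  stats$variant[pass]
}

#' Cluster cells into mitochondrial clones
#'
#' The heteroplasmy matrix (restricted to passing variants) is binarized
#' at `binarize_threshold` (missing values treated as not carrying), a
#' k-nearest-neighbor graph is built on the binary profiles and re-weighted
#' by shared-neighbor Jaccard similarity, and communities are found by
#' modularity optimization (Louvain) at the given resolution. Clusters
#' smaller than `min_cluster_size` are merged into the cluster with the
#' nearest mean binary profile. Deterministic under a fixed seed.
#'
#' @param het heteroplasmy matrix, variants x cells.
#' @param binarize_threshold carrier cutoff on heteroplasmy (default 0.1).
#' @param knn neighbors for the SNN graph (default 20).
#' @param resolution Louvain resolution (default 1).
#' @param seed integer RNG seed.
#' @param min_cluster_size clusters below this size are merged (default 5).
#' @param prune SNN edges with Jaccard weight below this are dropped
#'   (default 1/15).
#' @param merge_dist clusters whose mean binary profiles are closer than
#'   this Euclidean distance are merged; modularity clustering tends to
#'   over-partition blocks of identical binary genotypes (default 0.5).
#' @return named integer-like factor: cell -> clone id (`"clone1"`, ...),
#'   numbered by decreasing clone size.
#' @export
cluster_mitoclones <- function(het, binarize_threshold = 0.1, knn = 20L,
                               resolution = 1, seed = 1L,
                               min_cluster_size = 5L, prune = 1 / 15,
                               merge_dist = 0.5) {
  if (nrow(het) < 2L) {
    stop("need >= 2 passing variants to cluster; review the variant filter",
         call. = FALSE)
  }
  b <- (het >= binarize_threshold)
  b[is.na(b)] <- FALSE
  b <- t(b) + 0  # cells x variants
  n <- nrow(b)
  knn <- max(2L, min(knn, n - 1L))

  d <- as.matrix(stats::dist(b))
  # neighbor sets include the cell itself, as is conventional for SNN;
  # ties are broken by cell index, keeping the graph deterministic
  N <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    ord <- unique(c(i, ord))[seq_len(knn + 1L)]
    N[i, ord] <- 1L
  }
  shared <- tcrossprod(N)
  sizes_nn <- rowSums(N)
  jac <- shared / (outer(sizes_nn, sizes_nn, "+") - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- as.integer(igraph::membership(cl))

  # merge undersized clusters into the nearest cluster by mean binary
  # profile, smallest first
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_cluster_size]
    if (length(small) == 0 || length(sizes) == 1L) break
    s <- small[order(sizes[small])][1L]
    cent <- vapply(names(sizes), function(cid)
      colMeans(b[memb == as.integer(cid), , drop = FALSE]),
      numeric(ncol(b)))
    others <- setdiff(names(sizes), s)
    dist_to <- vapply(others, function(o)
      sqrt(sum((cent[, s] - cent[, o])^2)), numeric(1))
    memb[memb == as.integer(s)] <- as.integer(others[which.min(dist_to)])
  }

  # merge clusters with indistinguishable mitochondrial genotypes: SNN +
  # modularity happily over-partitions blocks of identical binary
  # profiles, so clusters whose mean profiles differ by less than
  # `merge_dist` are collapsed (distinct clones differ by >= 1 variant,
  # i.e. centroid distance near 1)
  repeat {
    ids <- unique(memb)
    if (length(ids) == 1L) break
    cent <- vapply(ids, function(cid)
      colMeans(b[memb == cid, , drop = FALSE]), numeric(ncol(b)))
    dc <- as.matrix(stats::dist(t(cent)))
    dc[upper.tri(dc, diag = TRUE)] <- Inf
    if (min(dc) >= merge_dist) break
    pair <- which(dc == min(dc), arr.ind = TRUE)[1L, ]
    memb[memb == ids[pair["row"]]] <- ids[pair["col"]]
  }

  # stable clone ids ordered by decreasing size (ties by first appearance)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(paste0("clone", seq_along(sizes)), names(sizes))
  out <- factor(relabel[as.character(memb)], levels = unname(relabel))
  names(out) <- colnames(het)
  out
}

#' Mean heteroplasmy of each variant within each clone
#'
#' Missing (zero-coverage) entries are excluded from the means. A QC flag
#' marks clones whose strongest defining variant has mean heteroplasmy
#' below `qc_floor`, i.e. clusters primarily driven by low-heteroplasmy
#' variants.
#'
#' @param het heteroplasmy matrix, variants x cells.
#' @param assignment named factor/character: cell -> clone.
#' @param qc_floor QC threshold on the top defining variant (default 0.2).
#' @return matrix clones x variants of mean heteroplasmy, with attribute
#'   `qc_flag` (named logical per clone).
#' @export
clone_variant_summary <- function(het, assignment, qc_floor = 0.2) {
  stopifnot(!is.null(names(assignment)),
            all(colnames(het) %in% names(assignment)))
  assignment <- assignment[colnames(het)]
  clones <- unique(as.character(assignment))
  out <- t(vapply(clones, function(cl) {
    rowMeans(het[, assignment == cl, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(het))))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- clones
  colnames(out) <- rownames(het)
  qc <- apply(out, 1, function(x) {
    mx <- suppressWarnings(max(x, na.rm = TRUE))
    is.finite(mx) && mx < qc_floor
  })
  attr(out, "qc_flag") <- qc
  out
}

#' Reconstruct a clone tree from shared and exclusive variants
#'
#' Each clone's variant set is binarized at `presence_threshold`; a clone
#' whose set strictly contains another's becomes that clone's ancestor
#' (the smallest strict superset is the parent). Clones whose sets overlap
#' without containment are incompatible under a perfect phylogeny; they
#' are attached to their deepest compatible ancestor (the root if none)
#' and the conflicting pair is reported rather than silently resolved.
#'
#' @param summary clones x variants mean-heteroplasmy matrix from
#'   [clone_variant_summary()].
#' @param presence_threshold heteroplasmy cutoff for a clone to "carry" a
#'   variant (default 0.2).
#' @return list of class `clone_tree`: `nodes` (data.frame: clone, parent
#'   -- `"root"` for top-level clones), `variant_sets` (named list),
#'   `conflicts` (data.frame of incompatible clone pairs).
#' @export
build_clone_tree <- function(summary, presence_threshold = 0.2) {
  if (is.null(dim(summary)) || nrow(summary) == 0) {
    stop("empty clone summary", call. = FALSE)
  }
  pres <- !is.na(summary) & summary >= presence_threshold
  sets <- lapply(rownames(summary), function(cl) colnames(summary)[pres[cl, ]])
  names(sets) <- rownames(summary)
  clones <- rownames(summary)

  # a child inherits its parent's variants plus private ones, so an
  # ancestor's variant set is a strict subset of its descendant's
  conflicts <- list()
  parent <- setNames(rep("root", length(clones)), clones)
  for (i in seq_along(clones)) {
    ci <- clones[i]
    subsets <- character()
    for (j in seq_along(clones)) {
      if (i == j) next
      cj <- clones[j]
      inter <- intersect(sets[[ci]], sets[[cj]])
      if (length(inter) &&
          length(inter) < length(sets[[ci]]) &&
          length(inter) < length(sets[[cj]])) {
        if (i < j) conflicts[[length(conflicts) + 1L]] <- c(ci, cj)
      }
      if (length(sets[[cj]]) < length(sets[[ci]]) &&
          all(sets[[cj]] %in% sets[[ci]])) {
        subsets <- c(subsets, cj)
      }
    }
    if (length(subsets)) {
      # deepest compatible ancestor = the largest strict subset
      sz <- vapply(subsets, function(s) length(sets[[s]]), integer(1))
      parent[ci] <- subsets[which.max(sz)]
    }
  }
  conflicts_df <- if (length(conflicts)) {
    do.call(rbind, lapply(conflicts, function(p)
      data.frame(clone_a = p[1], clone_b = p[2], stringsAsFactors = FALSE)))
  } else data.frame(clone_a = character(), clone_b = character())
  structure(
    list(nodes = data.frame(clone = clones, parent = unname(parent[clones]),
                            stringsAsFactors = FALSE),
         variant_sets = sets, conflicts = conflicts_df),
    class = "clone_tree"
  )
}

#' Per-timepoint clone frequencies
#'
#' @param assignment named factor/character: cell -> clone.
#' @param timepoints named character: cell -> timepoint label.
#' @return data.frame with `timepoint`, `clone`, `n_cells`, `frequency`;
#'   frequencies sum to 1 within each timepoint.
#' @export
clone_frequencies <- function(assignment, timepoints) {
  stopifnot(!is.null(names(assignment)), !is.null(names(timepoints)))
  cells <- intersect(names(assignment), names(timepoints))
  if (length(cells) == 0) stop("no shared cells", call. = FALSE)
  tp <- factor(timepoints[cells])
  if (any(table(tp) == 0)) stop("timepoint with zero cells", call. = FALSE)
  cl <- factor(as.character(assignment[cells]))
  tab <- table(timepoint = tp, clone = cl)
  freq <- prop.table(tab, margin = 1)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3] <- "n_cells"
  out$frequency <- as.data.frame(freq)$Freq
  out
}

#' Per-clone, per-timepoint pseudobulk accessibility
#'
#' Sums single-cell counts within each clone and timepoint, then CPM-
#' normalizes the summed profiles. Clone/timepoint groups with fewer than
#' `min_cells` cells are excluded with a warning (small groups give
#' unstable correlation estimates).
#'
#' @param cell_counts matrix, features x cells.
#' @param assignment named factor/character: cell -> clone.
#' @param timepoints named character: cell -> timepoint.
#' @param min_cells minimum cells per clone-timepoint group (default 20).
#' @return list with `pseudobulk` (features x groups CPM matrix) and
#'   `meta` (data.frame: column, clone, timepoint, n_cells).
#' @export
clone_pseudobulk <- function(cell_counts, assignment, timepoints,
                             min_cells = 20L) {
  cells <- intersect(colnames(cell_counts),
                     intersect(names(assignment), names(timepoints)))
  if (length(cells) == 0) stop("no overlapping cells", call. = FALSE)
  grp <- paste(as.character(assignment[cells]), timepoints[cells], sep = "@")
  sums <- sapply(unique(grp), function(g)
    rowSums(cell_counts[, cells[grp == g], drop = FALSE]))
  n <- table(grp)[colnames(sums)]
  keep <- as.integer(n) >= min_cells
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " clone-timepoint group(s) below ",
            min_cells, " cells: ", paste(colnames(sums)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no clone-timepoint group reaches `min_cells`",
                       call. = FALSE)
  sums <- sums[, keep, drop = FALSE]
  parts <- strsplit(colnames(sums), "@", fixed = TRUE)
  meta <- data.frame(
    column = colnames(sums),
    clone = vapply(parts, `[`, character(1), 1),
    timepoint = vapply(parts, `[`, character(1), 2),
    n_cells = as.integer(n[keep]),
    stringsAsFactors = FALSE
  )
  list(pseudobulk = cpm_normalize(sums), meta = meta)
}

#' Test for convergent epigenetic evolution between clones
#'
#' All unordered pairs of clone pseudobulks are Pearson-correlated across
#' peaks within each timepoint independently; the diagnosis and relapse
#' correlation sets are compared with an unpaired two-sided Student's
#' t-test (equal variances; `welch = TRUE` for the unequal-variance
#' variant). Convergence is declared when the mean relapse correlation
#' exceeds the mean diagnosis correlation with p < 0.05.
#'
#' @param pseudobulk features x groups matrix from [clone_pseudobulk()].
#' @param meta matching `meta` data.frame from [clone_pseudobulk()].
#' @param welch use Welch's t-test instead of Student's (default FALSE).
#' @return list with `cor_dx`, `cor_rel` (named numeric vectors of pairwise
#'   correlations), `mean_diff` (rel - dx), `t`, `p`, `converged`
#'   (logical; NA when p is undefined), `degenerate` (TRUE when the t-test
#'   is undefined, e.g. zero-variance correlation sets).
#' @export
convergence_test <- function(pseudobulk, meta, welch = FALSE) {
  pair_cors <- function(tp) {
    cols <- meta$column[meta$timepoint == tp]
    if (length(cols) < 2L) {
      stop("need >= 2 clones at timepoint '", tp, "'", call. = FALSE)
    }
    cmb <- utils::combn(cols, 2)
    r <- apply(cmb, 2, function(pr)
      cor(pseudobulk[, pr[1]], pseudobulk[, pr[2]]))
    names(r) <- apply(cmb, 2, paste, collapse = "|")
    r
  }
  cor_dx <- pair_cors("dx")
  cor_rel <- pair_cors("rel")
  mean_diff <- mean(cor_rel) - mean(cor_dx)
  tt <- tryCatch(
    t.test(cor_rel, cor_dx, var.equal = !welch),
    error = function(e) NULL
  )
  degenerate <- is.null(tt) || !is.finite(tt$p.value)
  p <- if (degenerate) NA_real_ else tt$p.value
  list(
    cor_dx = cor_dx, cor_rel = cor_rel, mean_diff = mean_diff,
    t = if (degenerate) NA_real_ else unname(tt$statistic),
    p = p,
    converged = if (degenerate) NA else (mean_diff > 0 && p < 0.05),
    degenerate = degenerate
  )
}

#' Lineage bias of mitochondrial clones
#'
#' Cross-tabulates clone membership against closest-normal cell-type
#' labels and tests for homogeneity of lineage composition across clones
#' with a chi-square test (Monte Carlo p-value when any expected count is
#' below 5). Standardized residuals point at the biased lineages.
#'
#' @param assignment named factor/character: cell -> clone.
#' @param calls data.frame with `cell` and `label` columns (e.g. from
#'   [knn_classify()]).
#' @param seed RNG seed for the Monte Carlo p-value (default 1).
#' @return list with `table` (clones x labels counts), `p`, `stdres`
#'   (standardized residuals), `simulated` (logical).
#' @export
clone_lineage_bias <- function(assignment, calls, seed = 1L) {
  stopifnot(!is.null(names(assignment)),
            all(c("cell", "label") %in% names(calls)))
  cells <- intersect(names(assignment), calls$cell)
  if (length(cells) == 0) stop("no shared cells between assignment and calls",
                               call. = FALSE)
  cl <- as.character(assignment[cells])
  if (length(unique(cl)) < 2L) stop("need >= 2 clones", call. = FALSE)
  lab <- calls$label[match(cells, calls$cell)]
  tab <- table(clone = cl, lineage = lab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  simulate <- any(expected < 5)
  ct <- with_seed(seed, suppressWarnings(
    chisq.test(tab, simulate.p.value = simulate, B = 2000)
  ))
  list(table = tab, p = ct$p.value, stdres = ct$stdres, simulated = simulate)
}
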