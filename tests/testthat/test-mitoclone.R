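.toy_counts <- function(alt_f, alt_r, ref_f, ref_r) {
  mk <- function(x) matrix(x, 1, length(x),
                           dimnames = list("v1", paste0("c", seq_along(x))))
  list(alt_fwd = mk(alt_f), alt_rev = mk(alt_r),
       ref_fwd = mk(ref_f), ref_rev = mk(ref_r))
}

test_that("heteroplasmy pools strands and treats zero coverage as missing", {
  hp <- compute_heteroplasmy(.toy_counts(3, 2, 3, 2))
  expect_equal(unname(hp$heteroplasmy[1, 1]), 0.5)   # alt 5 / cov 10
  hp0 <- compute_heteroplasmy(.toy_counts(0, 0, 0, 0))
  expect_true(is.na(hp0$heteroplasmy[1, 1]))
  expect_error(compute_heteroplasmy(.toy_counts(-1, 0, 5, 5)),
               "non-negative")
  # perfectly concordant strands across carrying cells
  cc <- .toy_counts(c(5, 2, 8), c(5, 2, 8), c(5, 8, 2), c(5, 8, 2))
  expect_equal(compute_heteroplasmy(cc)$stats$strand_correlation, 1)
  expect_equal(compute_heteroplasmy(cc)$stats$n_cells_detected, 3L)
})

test_that("variant filter applies all three thresholds strictly", {
  st <- data.frame(
    variant = c("pass", "cells_at_bound", "cor_at_bound", "cov_at_bound",
                "cor_na"),
    n_cells_detected = c(5L, 3L, 10L, 5L, 5L),
    strand_correlation = c(0.8, 0.9, 0.65, 0.8, NA),
    mean_coverage = c(15, 50, 50, 10, 50)
  )
  expect_identical(filter_variants(st), "pass")
  # brute-force re-evaluation of the predicate over a synthetic experiment
  fx <- mito_fixture()
  got <- filter_variants(fx$hp$stats)
  brute <- fx$hp$stats$variant[
    fx$hp$stats$n_cells_detected > 3 &
      !is.na(fx$hp$stats$strand_correlation) &
      fx$hp$stats$strand_correlation > 0.65 &
      fx$hp$stats$mean_coverage > 10]
  expect_identical(got, brute)
  # the planted artifact variants are the ones removed
  fails <- setdiff(fx$hp$stats$variant, got)
  expect_setequal(fails,
                  fx$expt$variants$variant[fx$expt$variants$artifact])
})

test_that("clustering recovers planted clones and is seed-stable", {
  fx <- mito_fixture()
  pass <- filter_variants(fx$hp$stats)
  het <- fx$hp$heteroplasmy[pass, , drop = FALSE]
  a1 <- cluster_mitoclones(het, seed = 21)
  a2 <- cluster_mitoclones(het, seed = 21)
  expect_identical(a1, a2)
  ari <- mclust::adjustedRandIndex(as.character(a1),
                                   fx$expt$truth$clone_labels[names(a1)])
  expect_gte(ari, 0.9)
  # single planted clone gives a single cluster
  e1 <- gen_mito_experiment(60, 60, clone_spec(1), seed = 2,
                            n_artifact_variants = 0)
  hp1 <- compute_heteroplasmy(e1$allele_counts)
  a3 <- cluster_mitoclones(hp1$heteroplasmy, seed = 3)
  expect_equal(length(unique(as.character(a3))), 1L)
  expect_error(cluster_mitoclones(het[0, , drop = FALSE]), "variant")
})

test_that("clone-by-variant summaries expose planted heteroplasmy and QC", {
  fx <- mito_fixture()
  pass <- filter_variants(fx$hp$stats)
  het <- fx$hp$heteroplasmy[pass, , drop = FALSE]
  truth <- fx$expt$truth$clone_labels[colnames(het)]
  summ <- clone_variant_summary(het, truth)
  # clone1's private variants sit near the planted 0.9 in clone1 ...
  own <- names(fx$expt$truth$variant_assignments)[
    fx$expt$truth$variant_assignments == "clone1"]
  expect_true(all(summ["clone1", own] > 0.8 & summ["clone1", own] <= 1))
  # ... and near zero in the sibling clones
  expect_true(all(summ["clone2", own] < 0.05, na.rm = TRUE))
  expect_false(any(attr(summ, "qc_flag")))
  # a cluster driven only by low heteroplasmy raises the QC flag
  low <- matrix(0.05, 2, 6, dimnames = list(c("v1", "v2"), paste0("c", 1:6)))
  lowsum <- clone_variant_summary(low, setNames(rep("cl", 6), colnames(low)))
  expect_true(attr(lowsum, "qc_flag")[["cl"]])
})

test_that("clone trees nest by variant-set containment and surface conflicts", {
  mk <- function(sets, vars) {
    m <- matrix(0, length(sets), length(vars),
                dimnames = list(names(sets), vars))
    for (cl in names(sets)) m[cl, sets[[cl]]] <- 0.8
    m
  }
  tr <- build_clone_tree(mk(list(A = "v1", B = c("v1", "v2")), c("v1", "v2")))
  expect_equal(tr$nodes$parent[tr$nodes$clone == "B"], "A")
  expect_equal(tr$nodes$parent[tr$nodes$clone == "A"], "root")
  expect_equal(nrow(tr$conflicts), 0L)

  tr2 <- build_clone_tree(mk(list(A = "v1", B = "v2"), c("v1", "v2")))
  expect_true(all(tr2$nodes$parent == "root"))

  tr3 <- build_clone_tree(mk(list(A = c("v1", "v2"), B = c("v2", "v3")),
                             c("v1", "v2", "v3")))
  expect_equal(nrow(tr3$conflicts), 1L)
  expect_true(all(tr3$nodes$parent == "root"))
  expect_error(build_clone_tree(matrix(0, 0, 0)), "empty")

  # a three-level chain reconstructs its full depth
  tr4 <- build_clone_tree(mk(list(A = "v1", B = c("v1", "v2"),
                                  C = c("v1", "v2", "v3")),
                             c("v1", "v2", "v3")))
  expect_equal(tr4$nodes$parent[match(c("A", "B", "C"), tr4$nodes$clone)],
               c("root", "A", "B"))
})

test_that("clone frequencies are conserved and match planted values", {
  fx <- mito_fixture()
  truth <- fx$expt$truth
  tps <- setNames(fx$expt$cells$timepoint, fx$expt$cells$cell)
  fr <- clone_frequencies(truth$clone_labels, tps)
  for (tp in c("dx", "rel")) {
    expect_equal(sum(fr$frequency[fr$timepoint == tp]), 1, tolerance = 1e-12)
  }
  # within 3 multinomial standard errors of the planted frequencies
  n_dx <- sum(fx$expt$cells$timepoint == "dx")
  for (i in seq_along(truth$freq_dx)) {
    p <- truth$freq_dx[i]
    obs <- fr$frequency[fr$timepoint == "dx" &
                          fr$clone == paste0("clone", i)]
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n_dx))
  }
  single <- clone_frequencies(setNames(rep("c1", 4), paste0("x", 1:4)),
                              setNames(rep("dx", 4), paste0("x", 1:4)))
  expect_equal(single$frequency, 1)
})

test_that("pseudobulks are additive before normalization and filter small clones", {
  set.seed(9)
  counts <- matrix(rpois(50 * 30, 10), 50, 30,
                   dimnames = list(NULL, paste0("c", 1:30)))
  cells <- colnames(counts)
  tps <- setNames(rep("dx", 30), cells)
  whole <- setNames(rep("cl", 30), cells)
  halves <- setNames(rep(c("h1", "h2"), 15), cells)
  pb_whole <- clone_pseudobulk(counts, whole, tps, min_cells = 1)
  # summing the two half pseudobulks (pre-normalization) gives the whole
  raw_whole <- rowSums(counts)
  raw_h <- rowSums(counts[, halves == "h1"]) + rowSums(counts[, halves == "h2"])
  expect_equal(raw_h, raw_whole)
  expect_equal(unname(pb_whole$pseudobulk[, 1]),
               unname(raw_whole / sum(raw_whole) * 1e6))
  # a single-cell clone's pseudobulk is that cell's CPM profile
  solo <- setNames(c("s", rep("cl", 29)), cells)
  pb_solo <- clone_pseudobulk(counts, solo, tps, min_cells = 1)
  expect_equal(unname(pb_solo$pseudobulk[, "s@dx"]),
               unname(counts[, 1] / sum(counts[, 1]) * 1e6))
  expect_warning(clone_pseudobulk(counts, solo, tps, min_cells = 5),
                 "excluding")
  expect_error(clone_pseudobulk(counts, setNames("cl", "zz"), tps), "overlap")
})

test_that("convergence test detects the planted pull and flags degeneracy", {
  fx <- mito_fixture()
  tps <- setNames(fx$expt$cells$timepoint, fx$expt$cells$cell)
  pb <- clone_pseudobulk(fx$expt$atac_counts, fx$expt$truth$clone_labels, tps)
  cv <- convergence_test(pb$pseudobulk, pb$meta)
  expect_true(cv$mean_diff > 0)
  expect_lt(cv$p, 0.05)
  expect_true(cv$converged)
  expect_length(cv$cor_dx, 3)   # three clone pairs per timepoint

  # identical clone profiles: correlations all 1, t-test undefined
  flatpb <- matrix(rep(c(1e6 / 2, 1e6 / 2), 4), 2, 4,
                   dimnames = list(NULL, c("a@dx", "b@dx", "a@rel", "b@rel")))
  meta <- data.frame(column = colnames(flatpb),
                     clone = rep(c("a", "b"), 2),
                     timepoint = rep(c("dx", "rel"), each = 2))
  # add a second feature so correlation is defined, but constant everywhere
  flatpb <- rbind(flatpb, flatpb[1, ] * 0 + c(2e5, 8e5, 2e5, 8e5))
  flatpb <- rbind(flatpb, 1e6 - colSums(flatpb))
  cv2 <- convergence_test(flatpb, meta)
  expect_true(cv2$degenerate)
  expect_true(is.na(cv2$p))

  expect_error(convergence_test(pb$pseudobulk[, 1, drop = FALSE],
                                pb$meta[1, , drop = FALSE]),
               "timepoint")
})

test_that("lineage bias is detected for a clone confined to one lineage", {
  set.seed(4)
  cells <- sprintf("c%03d", 1:120)
  clones <- setNames(rep(c("cl1", "cl2", "cl3"), each = 40), cells)
  lin <- ifelse(clones == "cl1", "HSC",
                sample(c("HSC", "GMP", "Mono"), 120, replace = TRUE))
  calls <- data.frame(cell = cells, label = lin)
  lb <- clone_lineage_bias(clones, calls)
  expect_lt(lb$p, 0.05)
  expect_equal(names(which.max(lb$stdres["cl1", ])), "HSC")

  unif <- data.frame(cell = cells,
                     label = rep(c("HSC", "GMP", "Mono"), 40))
  expect_true(clone_lineage_bias(clones, unif)$p > 1e-4)

  expect_error(clone_lineage_bias(clones,
                                  data.frame(cell = "zz", label = "HSC")),
               "shared")
  expect_error(clone_lineage_bias(setNames(rep("cl1", 120), cells), calls),
               ">= 2 clones")
})
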