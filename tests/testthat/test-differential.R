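test_that("paired NB model recovers planted peaks with controlled errors", {
  fx <- diff_fixture()
  planted <- names(fx$atac$truth$differential_peaks)
  sig <- fx$res$feature[!is.na(fx$res$p_adj) & fx$res$p_adj < 0.05]
  expect_gte(mean(planted %in% sig), 0.8)           # sensitivity
  null_peaks <- setdiff(fx$res$feature, planted)
  expect_lte(mean(null_peaks %in% sig), 0.05)       # false positive rate
  # planted direction is recovered in the sign of the fold change
  est <- fx$res$log2FC[match(planted, fx$res$feature)]
  expect_true(all(sign(est) == sign(fx$atac$truth$differential_peaks)))
})

test_that("all-zero features are excluded rather than called significant", {
  fx <- diff_fixture()
  counts <- fx$atac$counts
  counts[1, ] <- 0L
  res <- differential_accessibility(counts, fx$atac$samples$timepoint,
                                    fx$atac$samples$patient)
  expect_true(is.na(res$p_adj[1]) || res$p_adj[1] >= 0.05)
})

test_that("a design confounding patient with condition is rejected", {
  m <- matrix(rpois(400, 20), 100, 4)
  expect_error(
    differential_accessibility(m, c("dx", "dx", "rel", "rel"),
                               c("p1", "p2", "p3", "p4")),
    "both timepoints"
  )
  expect_error(
    differential_accessibility(m, c("dx", "relapse", "rel", "rel"),
                               c("p1", "p1", "p2", "p2")),
    "condition"
  )
})

test_that("relapse signature ranks planted genes into the right sets", {
  fx <- signature_fixture()
  sig <- fx$sig
  expect_length(intersect(sig$top_set, sig$bottom_set), 0)
  planted <- fx$genes$truth$differential_peaks
  up <- names(planted)[planted > 0]
  dn <- names(planted)[planted < 0]
  expect_gte(mean(up %in% sig$top_set), 0.9)
  expect_gte(mean(dn %in% sig$bottom_set), 0.9)
  # requesting more genes than available shrinks the sets with a warning
  expect_warning(
    s2 <- derive_relapse_signature(fx$genes$counts,
                                   fx$genes$samples$timepoint,
                                   fx$genes$samples$patient, n_set = 500),
    "shrinking"
  )
  expect_true(length(s2$top_set) <= nrow(fx$genes$counts) / 2)
})

test_that("relapse score is zero under symmetry and exact on a toy matrix", {
  sig <- list(top_set = c("g1", "g2"), bottom_set = c("g3", "g4"))
  flat <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(unname(relapse_score(flat, sig, normalize = FALSE)),
               c(0, 0, 0))
  toy <- matrix(c(3, 1, 1, 1), 4, 1, dimnames = list(paste0("g", 1:4), "c1"))
  expect_equal(unname(relapse_score(toy, sig, normalize = FALSE)), 2)
  # missing signature genes: proceed with a warning below 80% coverage
  part <- toy[c("g1", "g3"), , drop = FALSE]
  expect_warning(relapse_score(part, sig, normalize = FALSE), "50%")
  expect_error(relapse_score(toy[0, , drop = FALSE], sig), "no signature")
})

test_that("cells with a planted signature shift score higher at relapse", {
  fx <- signature_fixture()
  scores <- relapse_score(fx$genes$counts, fx$sig)
  rel <- scores[fx$genes$samples$timepoint == "rel"]
  dx <- scores[fx$genes$samples$timepoint == "dx"]
  expect_lt(t.test(rel, dx, alternative = "greater")$p.value, 0.05)
})

test_that("locus scan flags a planted differential locus and only that", {
  fx <- fixture("locus", {
    atac <- gen_bulk_atac(400, 6, frac_differential = 0.1, effect_lfc = 2.5,
                          seed = 707, locus_cluster = TRUE)
    res <- differential_accessibility(atac$counts, atac$samples$timepoint,
                                      atac$samples$patient)
    list(atac = atac, res = res)
  })
  le <- locus_enrichment(fx$res, fx$atac$peaks)
  hits <- le[le$p_adj < 0.05, ]
  expect_gt(nrow(hits), 0)
  # planted peaks sit at the head of each chromosome
  planted_max <- max(fx$atac$peaks$end[
    sprintf("%s:%d-%d", fx$atac$peaks$chrom, fx$atac$peaks$start,
            fx$atac$peaks$end) %in% names(fx$atac$truth$differential_peaks)])
  expect_true(all(hits$start <= planted_max))
  # BH adjustment matches a direct re-computation
  expect_equal(le$p_adj, p.adjust(le$p, method = "BH"))

  expect_error(locus_enrichment(fx$res, fx$atac$peaks, window = 100),
               "widest feature")
  none <- fx$res
  none$p_adj <- 1
  expect_equal(nrow(locus_enrichment(none, fx$atac$peaks)), 0L)
})

test_that("compartment overlap fractions are exact set arithmetic", {
  mk <- function(sig_ids, all_ids) {
    data.frame(feature = all_ids, log2FC = 1,
               p = ifelse(all_ids %in% sig_ids, 1e-6, 0.9),
               p_adj = ifelse(all_ids %in% sig_ids, 1e-6, 0.9))
  }
  u <- sprintf("f%02d", 1:60)
  a <- mk(u[1:40], u)
  b <- mk(u[31:40], u)     # B subset of A
  o <- compartment_overlap(b, a)
  expect_equal(o$a_in_b, 1)            # all of B's hits are in A
  expect_equal(o$b_in_a, 0.25)         # 10 of A's 40 hits are in B
  o2 <- compartment_overlap(mk(u[1:5], u), mk(u[6:10], u))
  expect_equal(o2$a_in_b, 0)
  expect_equal(o2$b_in_a, 0)
  expect_error(compartment_overlap(a, mk(u[1:5], u[1:50])), "universe")
})
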