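test_that("identical peaks from two samples collapse to one 500 bp peak", {
  p <- data.frame(chrom = "chr1", start = 1000, end = 1500, score = 10)
  cp <- iterative_overlap_merge(list(a = p, b = p))
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$end - cp$start, 500)
  expect_equal(cp$n_samples, 2L)
})

test_that("greedy removal keeps the stronger of two overlapping peaks", {
  s <- data.frame(chrom = "chr1", start = c(1000, 1200), end = c(1500, 1700),
                  score = c(10, 5))
  cp <- iterative_overlap_merge(list(a = s, b = s))
  expect_equal(nrow(cp), 1L)
  # score-10 peak: midpoint 1250, re-centered to 1000-1500
  expect_equal(cp$start, 1000)
})

test_that("hand-traced five-peak example resolves exactly per the greedy rule", {
  # sample A: P1(0-500, 10), P2(400-900, 8), P3(2000-2500, 6)
  # sample B: P4(450-950, 9), P5(2100-2600, 2)
  # per-sample score-per-million ordering: P4(.818e6) > P1(.417e6) >
  #   P2(.333e6) > P3(.25e6) > P5(.182e6)
  # greedy: keep P4; P1 overlaps P4 (after standardization) -> dropped;
  #   P2 overlaps P4 -> dropped; keep P3; P5 overlaps P3 -> dropped
  a <- data.frame(chrom = "chr1", start = c(0, 400, 2000),
                  end = c(500, 900, 2500), score = c(10, 8, 6))
  b <- data.frame(chrom = "chr1", start = c(450, 2100),
                  end = c(950, 2600), score = c(9, 2))
  cp <- iterative_overlap_merge(list(A = a, B = b))
  expect_equal(nrow(cp), 2L)
  expect_equal(cp$start, c(450, 2000))  # P4 and P3 standardized
  expect_equal(cp$n_samples, c(2L, 2L))
})

test_that("peaks supported by fewer than min_samples are excluded", {
  s1 <- data.frame(chrom = "chr1", start = c(1000, 5000),
                   end = c(1500, 5500), score = c(10, 5))
  s2 <- data.frame(chrom = "chr1", start = 1000, end = 1500, score = 8)
  cp <- iterative_overlap_merge(list(a = s1, b = s2), min_samples = 2)
  expect_equal(nrow(cp), 1L)           # the 5000 peak is a singleton
  expect_equal(cp$start, 1000)
  expect_equal(nrow(iterative_overlap_merge(list(a = s1), min_samples = 2)), 0L)
  expect_warning(iterative_overlap_merge(list()), "no input peaks")
})

test_that("consensus output is sorted, non-overlapping and idempotent", {
  set.seed(11)
  mk <- function() {
    st <- sort(sample(seq(0, 2e5, by = 100), 60))
    data.frame(chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
               start = st, end = st + sample(300:800, 60, replace = TRUE),
               score = runif(60, 1, 50))
  }
  cp <- iterative_overlap_merge(list(a = mk(), b = mk(), c = mk()))
  expect_true(all(cp$end - cp$start == 500))
  by_chr <- split(cp, cp$chrom)
  for (d in by_chr) {
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))  # pairwise disjoint
  }
  again <- iterative_overlap_merge(
    list(self = data.frame(cp[, c("chrom", "start", "end", "score")])),
    min_samples = 1
  )
  expect_equal(again$start, cp$start)
  expect_equal(again$chrom, cp$chrom)
})

test_that("cut sites are counted with the half-open convention", {
  peaks <- data.frame(chrom = "chr1", start = 100, end = 600)
  pos <- list(
    s1 = data.frame(chrom = "chr1", pos = c(100, 599)),  # both inside
    s2 = data.frame(chrom = "chr1", pos = c(99, 600)),   # both outside
    s3 = data.frame(chrom = character(0), pos = integer(0))
  )
  m <- counts_in_peaks(pos, peaks)
  expect_equal(unname(m[1, ]), c(2L, 0L, 0L))
  expect_error(
    counts_in_peaks(list(x = data.frame(chrom = "chrX", pos = 1)), peaks),
    "chrX"
  )
})

test_that("CPM normalization conserves column totals and guards re-entry", {
  m <- matrix(c(1, 1, 3, 1), 2, 2)
  cm <- cpm_normalize(m)
  expect_equal(unname(cm[, 1]), c(5e5, 5e5))
  expect_true(all(abs(colSums(cm) - 1e6) < 1e-6))
  expect_error(cpm_normalize(cm), "already normalized")
  z <- cbind(m, 0)
  expect_error(cpm_normalize(z), "zero total")
  cz <- cpm_normalize(z, allow_empty = TRUE)
  expect_equal(unname(cz[, 3]), c(0, 0))
})

test_that("diagnosis-relapse similarity averages replicates before correlating", {
  set.seed(3)
  base <- matrix(rpois(200 * 4, 20), 200, 4,
                 dimnames = list(NULL, c("p1_dx", "p1_rel", "p2_dx", "p2_rel")))
  base[, "p1_rel"] <- base[, "p1_dx"]  # identical profiles
  pairing <- data.frame(sample = colnames(base),
                        patient = rep(c("p1", "p2"), each = 2),
                        timepoint = rep(c("dx", "rel"), 2))
  r <- dx_rel_similarity(cpm_normalize(base), pairing)
  expect_equal(unname(r["p1"]), 1.0)

  # anti-correlated constructed profile
  m2 <- cbind(dx = seq_len(100), rel = rev(seq_len(100)))
  colnames(m2) <- c("q_dx", "q_rel")
  p2 <- data.frame(sample = colnames(m2), patient = "q",
                   timepoint = c("dx", "rel"))
  expect_true(dx_rel_similarity(cpm_normalize(m2), p2) < 0)

  # duplicating a replicate leaves the correlation unchanged
  m3 <- cbind(base, p1_dx_b = base[, "p1_dx"])
  p3 <- rbind(pairing, data.frame(sample = "p1_dx_b", patient = "p1",
                                  timepoint = "dx"))
  r3 <- dx_rel_similarity(cpm_normalize(m3), p3)
  expect_equal(unname(r3["p1"]), unname(r["p1"]))

  expect_warning(
    dx_rel_similarity(cpm_normalize(base[, 1:3]), pairing[1:3, ]),
    "lacks a timepoint"
  )
  expect_error(dx_rel_similarity(base, pairing), "normalized")
})
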