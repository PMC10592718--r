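# Consensus peak construction and peak-level count utilities. Coordinates
# are BED-style throughout: 0-based, half-open [start, end).

.peaks_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Build a fixed-width consensus peak set by iterative overlap removal
#'
#' Per-sample peaks are standardized to a fixed width centered on their
#' summit (if a `summit` column is present) or interval midpoint, and each
#' sample's scores are rescaled to score-per-million so samples of
#' different depth are comparable. The pooled peaks are ranked by
#' normalized score (ties broken by coordinate, then source sample) and
#' greedily retained: a peak is kept unless it overlaps an already-retained
#' stronger peak. Retained peaks are kept in the consensus only when
#' overlapped by standardized peaks from at least `min_samples` distinct
#' samples (the retained peak's own source counts).
#'
#' @param per_sample_peaks named list of data.frames with columns `chrom`,
#'   `start`, `end`, `score` and optionally `summit` (absolute bp).
#' @param width fixed peak width in bp (default 500).
#' @param min_samples minimum distinct supporting samples (default 2).
#' @return data.frame of class `consensus_peaks` with `chrom`, `start`,
#'   `end`, `score` (normalized score of the retained peak), `n_samples`,
#'   sorted by coordinate and pairwise non-overlapping.
#' @export
iterative_overlap_merge <- function(per_sample_peaks, width = 500L,
                                    min_samples = 2L) {
  width <- assert_count(width, "width")
  min_samples <- assert_count(min_samples, "min_samples")
  if (is.null(names(per_sample_peaks))) {
    names(per_sample_peaks) <- sprintf("sample%02d",
                                       seq_along(per_sample_peaks))
  }
  per_sample_peaks <- Filter(function(d) !is.null(d) && nrow(d) > 0,
                             per_sample_peaks)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(),
                      n_samples = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("consensus_peaks", "data.frame")
  if (length(per_sample_peaks) == 0) {
    warning("no input peaks; returning empty consensus")
    return(empty)
  }

  pooled <- do.call(rbind, lapply(names(per_sample_peaks), function(s) {
    d <- per_sample_peaks[[s]]
    stopifnot(all(c("chrom", "start", "end", "score") %in% names(d)))
    if (any(is.na(d$score))) stop("every peak needs a score", call. = FALSE)
    center <- if ("summit" %in% names(d) && !anyNA(d$summit)) {
      as.integer(d$summit)
    } else {
      as.integer(floor((d$start + d$end) / 2))
    }
    start <- pmax(0L, center - as.integer(floor(width / 2)))
    data.frame(chrom = as.character(d$chrom), start = start,
               end = start + width,
               score = d$score / sum(d$score) * 1e6,
               sample = s, stringsAsFactors = FALSE)
  }))

  ord <- order(-pooled$score, pooled$chrom, pooled$start, pooled$sample)
  pooled <- pooled[ord, , drop = FALSE]
  gr <- .peaks_to_granges(pooled)

  # greedy iterative removal: keep the strongest peak of each overlap
  # cluster, drop everything it overlaps, repeat on what is left
  keep <- logical(nrow(pooled))
  active <- seq_len(nrow(pooled))
  while (length(active)) {
    sub <- gr[active]
    cl <- GenomicRanges::findOverlaps(sub, GenomicRanges::reduce(sub))
    cluster_of <- S4Vectors::subjectHits(cl)[order(S4Vectors::queryHits(cl))]
    best <- active[!duplicated(cluster_of)]  # active is score-ordered
    keep[best] <- TRUE
    drop <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(sub, gr[best])
    )
    active <- setdiff(active, union(best, active[unique(drop)]))
  }

  kept <- pooled[keep, , drop = FALSE]
  if (nrow(kept) == 0) return(empty)

  # sample support: distinct source samples among pooled standardized peaks
  # overlapping each kept peak
  ov <- GenomicRanges::findOverlaps(.peaks_to_granges(kept), gr)
  support <- vapply(seq_len(nrow(kept)), function(i) {
    hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    length(unique(pooled$sample[hits]))
  }, integer(1))
  kept$n_samples <- support
  kept <- kept[support >= min_samples, , drop = FALSE]
  kept$sample <- NULL
  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("consensus_peaks", "data.frame")
  kept
}

#' Count Tn5 cut sites per consensus peak
#'
#' Cut sites are single-bp, shift-corrected positions (0-based). A cut site
#' at the peak start coordinate is counted; one at the end coordinate is
#' not (half-open convention).
#'
#' @param positions named list, one element per sample/cell, each a
#'   data.frame with columns `chrom` and `pos` (0-based cut site).
#' @param consensus consensus peak data.frame (`chrom`, `start`, `end`).
#' @return integer matrix, peaks x columns, rownames `chrom:start-end`.
#' @export
counts_in_peaks <- function(positions, consensus) {
  stopifnot(is.list(positions), is.data.frame(consensus))
  if (is.null(names(positions))) {
    names(positions) <- sprintf("col%03d", seq_along(positions))
  }
  gr_peaks <- .peaks_to_granges(consensus)
  peak_chroms <- unique(consensus$chrom)
  out <- matrix(0L, nrow(consensus), length(positions),
                dimnames = list(feature_ids(consensus$chrom, consensus$start,
                                            consensus$end),
                                names(positions)))
  for (j in seq_along(positions)) {
    d <- positions[[j]]
    if (nrow(d) == 0) next
    if (!all(d$chrom %in% peak_chroms)) {
      stop("cut sites on chromosomes absent from the peak set: ",
           paste(setdiff(unique(d$chrom), peak_chroms), collapse = ", "),
           call. = FALSE)
    }
    gr_pos <- GenomicRanges::GRanges(
      seqnames = d$chrom,
      ranges = IRanges::IRanges(start = d$pos + 1L, width = 1L)
    )
    out[, j] <- GenomicRanges::countOverlaps(gr_peaks, gr_pos)
  }
  out
}

#' Counts-per-million normalization
#'
#' Scales every column to sum to one million. Refuses to normalize a
#' matrix already marked normalized (double-normalization guard).
#'
#' @param m raw count matrix (features x columns).
#' @param allow_empty keep all-zero columns (as zero) instead of erroring.
#' @return numeric matrix with attribute `normalized = TRUE`.
#' @export
cpm_normalize <- function(m, allow_empty = FALSE) {
  stopifnot(is.matrix(m) || is(m, "Matrix"))
  if (isTRUE(attr(m, "normalized"))) {
    stop("matrix is already normalized", call. = FALSE)
  }
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    if (!allow_empty) stop("column(s) with zero total counts: ",
                           paste(which(tot == 0), collapse = ", "),
                           call. = FALSE)
    tot[tot == 0] <- 1
  }
  out <- sweep(as.matrix(m), 2, tot, "/") * 1e6
  attr(out, "normalized") <- TRUE
  out
}

#' Diagnosis-relapse chromatin similarity per patient
#'
#' Replicate columns are averaged within each patient and timepoint on the
#' CPM scale, then the Pearson product-moment correlation across all
#' features between the diagnosis and relapse profiles is reported per
#' patient.
#'
#' @param m CPM-normalized matrix (features x samples; see
#'   [cpm_normalize()]).
#' @param pairing data.frame with columns `sample`, `patient`, `timepoint`
#'   (values `"dx"` / `"rel"`) mapping columns of `m`.
#' @return named numeric vector of per-patient correlations in \[-1, 1\].
#' @export
dx_rel_similarity <- function(m, pairing) {
  if (!isTRUE(attr(m, "normalized"))) {
    stop("`m` must be CPM-normalized (see cpm_normalize())", call. = FALSE)
  }
  stopifnot(all(c("sample", "patient", "timepoint") %in% names(pairing)),
            all(pairing$sample %in% colnames(m)))
  res <- c()
  for (p in unique(pairing$patient)) {
    dx_cols <- pairing$sample[pairing$patient == p & pairing$timepoint == "dx"]
    rel_cols <- pairing$sample[pairing$patient == p & pairing$timepoint == "rel"]
    if (length(dx_cols) == 0 || length(rel_cols) == 0) {
      warning("patient ", p, " lacks a timepoint; skipped")
      next
    }
    dx_prof <- rowMeans(m[, dx_cols, drop = FALSE])
    rel_prof <- rowMeans(m[, rel_cols, drop = FALSE])
    res[p] <- cor(dx_prof, rel_prof, method = "pearson")
  }
  res
}

#' Directed overlap of differential features between two compartments
#'
#' Given differential results for the same feature universe in two
#' compartments (e.g. non-LSC and LSC), reports the fraction of features
#' significant in A that are also significant in B, and vice versa.
#'
#' @param diff_a,diff_b data.frames as returned by
#'   [differential_accessibility()] over the same features.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return list with `a_in_b`, `b_in_a`, `n_a`, `n_b`, `n_overlap`.
#' @export
compartment_overlap <- function(diff_a, diff_b, alpha = 0.05) {
  if (!setequal(diff_a$feature, diff_b$feature)) {
    stop("the two results must cover the same feature universe",
         call. = FALSE)
  }
  sig_a <- diff_a$feature[!is.na(diff_a$p_adj) & diff_a$p_adj < alpha]
  sig_b <- diff_b$feature[!is.na(diff_b$p_adj) & diff_b$p_adj < alpha]
  n_ov <- length(intersect(sig_a, sig_b))
  list(
    a_in_b = if (length(sig_a)) n_ov / length(sig_a) else NA_real_,
    b_in_a = if (length(sig_b)) n_ov / length(sig_b) else NA_real_,
    n_a = length(sig_a), n_b = length(sig_b), n_overlap = n_ov
  )
}
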