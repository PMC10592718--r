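# Paired differential accessibility, the relapse signature, and
# locus-level enrichment of differential peaks.

#' Paired differential accessibility between diagnosis and relapse
#'
#' Fits the standard negative-binomial count model (median-of-ratios size
#' factors, per-feature dispersion shrinkage, Wald test) with design
#' `~ patient + condition`, so the relapse-versus-diagnosis contrast is
#' estimated within patients. P-values are Benjamini-Hochberg adjusted.
#' Works identically on peak counts and gene scores; non-integer inputs
#' (gene scores) are rounded for the count model.
#'
#' @param counts raw count matrix, features x samples.
#' @param condition character/factor of `"dx"` / `"rel"` per column.
#' @param patient character/factor of patient labels per column.
#' @return data.frame with `feature`, `log2FC` (relapse vs diagnosis), `p`,
#'   `p_adj`. Features that cannot be tested (e.g. all-zero) have NA.
#' @export
differential_accessibility <- function(counts, condition, patient) {
  stopifnot(ncol(counts) == length(condition),
            ncol(counts) == length(patient))
  condition <- factor(as.character(condition), levels = c("dx", "rel"))
  if (anyNA(condition)) stop("`condition` must be 'dx' or 'rel'", call. = FALSE)
  patient <- factor(patient)
  both <- rowSums(table(patient, condition) > 0) == 2L
  if (sum(both) < 2L) {
    stop("need >= 2 patients with both timepoints (design otherwise ",
         "confounds patient and condition)", call. = FALSE)
  }
  m <- round(as.matrix(counts))
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%05d", seq_len(nrow(m)))

  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = m,
    colData = S4Vectors::DataFrame(condition = condition, patient = patient),
    design = ~ patient + condition
  )
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("condition", "rel", "dx"))
  data.frame(
    feature = rownames(m),
    log2FC = res$log2FoldChange,
    p = res$pvalue,
    p_adj = res$padj,
    stringsAsFactors = FALSE
  )
}

#' Derive the relapse chromatin signature from stable patients
#'
#' Genes are ranked by their paired relapse-versus-diagnosis log2 fold
#' change of accessibility scores (patient as covariate); the top and
#' bottom `n_set` genes form the signature. When fewer than `2 * n_set`
#' genes are testable the set sizes shrink to half the available genes,
#' with a warning.
#'
#' @param gene_score_matrix gene accessibility scores (genes x samples)
#'   from stable patients; rounded internally for the count model.
#' @param condition,patient per-column labels as in
#'   [differential_accessibility()].
#' @param n_set signature set size (default 500).
#' @return list of class `relapse_signature`: `ranked` (data.frame from the
#'   differential fit, ordered by decreasing log2FC), `top_set`,
#'   `bottom_set` (character vectors, disjoint).
#' @export
derive_relapse_signature <- function(gene_score_matrix, condition, patient,
                                     n_set = 500L) {
  n_set <- assert_count(n_set, "n_set")
  res <- differential_accessibility(gene_score_matrix, condition, patient)
  ranked <- res[!is.na(res$log2FC), , drop = FALSE]
  ranked <- ranked[order(-ranked$log2FC), , drop = FALSE]
  n_avail <- nrow(ranked)
  if (n_avail < 2L * n_set) {
    n_set <- max(1L, floor(n_avail / 2))
    warning("fewer than 2 * n_set genes available; shrinking sets to ",
            n_set, " genes each")
  }
  structure(
    list(
      ranked = ranked,
      top_set = head(ranked$feature, n_set),
      bottom_set = tail(ranked$feature, n_set)
    ),
    class = "relapse_signature"
  )
}

#' Relapse chromatin score per cell or sample
#'
#' Depth-normalizes each column of the gene-score matrix (constant total of
#' 10,000), then scores each column as the sum of normalized scores over
#' the signature's top genes minus the sum over its bottom genes. Higher
#' values indicate a more relapse-like chromatin state.
#'
#' @param cell_gene_scores gene accessibility scores, genes x columns.
#' @param sig a `relapse_signature` (or list with `top_set`/`bottom_set`).
#' @param normalize depth-normalize columns first (default TRUE).
#' @return named numeric vector, one score per column.
#' @export
relapse_score <- function(cell_gene_scores, sig, normalize = TRUE) {
  top <- intersect(sig$top_set, rownames(cell_gene_scores))
  bottom <- intersect(sig$bottom_set, rownames(cell_gene_scores))
  frac <- (length(top) + length(bottom)) /
    (length(sig$top_set) + length(sig$bottom_set))
  if (frac == 0) stop("no signature genes present in the matrix", call. = FALSE)
  if (frac < 0.8) {
    warning(sprintf("only %.0f%% of signature genes present", 100 * frac))
  }
  x <- as.matrix(cell_gene_scores)
  if (normalize) {
    tot <- colSums(x)
    tot[tot == 0] <- 1
    x <- sweep(x, 2, tot, "/") * 1e4
  }
  colSums(x[top, , drop = FALSE]) - colSums(x[bottom, , drop = FALSE])
}

#' Chromosomal loci enriched for differential peaks
#'
#' Slides a window along each chromosome and asks, separately for
#' significantly opened and significantly closed peaks, whether the window
#' holds a higher proportion of them than the genome-wide rate
#' (one-sided binomial test against the global significant fraction,
#' Benjamini-Hochberg adjusted across all window tests). Peaks are
#' assigned to windows by midpoint.
#'
#' @param differential data.frame from [differential_accessibility()].
#' @param peaks data.frame (`chrom`, `start`, `end`) aligned with
#'   `differential` rows.
#' @param window window width in bp (default 100000).
#' @param step step size in bp (default 25000).
#' @param alpha adjusted-p cutoff defining a significant peak (default 0.05).
#' @return data.frame with `chrom`, `start`, `end`, `direction`
#'   (`"enriched"` = excess opened peaks, `"depleted"` = excess closed),
#'   `n_peaks`, `n_sig`, `p`, `p_adj`, ordered by `p`.
#' @export
locus_enrichment <- function(differential, peaks, window = 1e5, step = 2.5e4,
                             alpha = 0.05) {
  stopifnot(nrow(differential) == nrow(peaks))
  if (window < max(peaks$end - peaks$start)) {
    stop("`window` must be at least as wide as the widest feature",
         call. = FALSE)
  }
  sig <- !is.na(differential$p_adj) & differential$p_adj < alpha
  up <- sig & differential$log2FC > 0
  dn <- sig & differential$log2FC < 0
  if (!any(sig)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_peaks = integer(), n_sig = integer(),
                      p = numeric(), p_adj = numeric()))
  }
  mid <- (peaks$start + peaks$end) / 2
  p_up <- mean(up)
  p_dn <- mean(dn)

  rows <- list()
  for (ch in unique(peaks$chrom)) {
    on <- peaks$chrom == ch
    lo <- floor(min(peaks$start[on]) / step) * step
    hi <- max(peaks$end[on])
    starts <- seq(lo, max(lo, hi - 1), by = step)
    for (ws in starts) {
      inw <- on & mid >= ws & mid < ws + window
      n <- sum(inw)
      if (n == 0) next
      for (dir in c("enriched", "depleted")) {
        k <- if (dir == "enriched") sum(up[inw]) else sum(dn[inw])
        p0 <- if (dir == "enriched") p_up else p_dn
        if (p0 == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = ws, end = ws + window, direction = dir,
          n_peaks = n, n_sig = k,
          p = pbinom(k - 1, n, p0, lower.tail = FALSE),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
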