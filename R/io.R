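# Plain-text readers/writers for the pipeline's external formats:
# MTX count matrices with TSV sidecars, BED peaks, and JSON reports.

#' Write a count matrix as MatrixMarket with TSV sidecars
#'
#' Writes `matrix.mtx`, `features.tsv` (row names) and `columns.tsv`
#' (column names) under `dir`.
#'
#' @param m matrix or sparse Matrix, features x columns.
#' @param dir output directory (created if needed).
#' @export
write_count_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- as(as(Matrix::Matrix(as.matrix(m), sparse = TRUE), "CsparseMatrix"),
           "generalMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m) %||% sprintf("f%05d", seq_len(nrow(m))),
             file.path(dir, "features.tsv"))
  writeLines(colnames(m) %||% sprintf("c%05d", seq_len(ncol(m))),
             file.path(dir, "columns.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_count_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`, `columns.tsv`.
#' @return dense matrix with dimnames restored.
#' @export
read_count_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir, call. = FALSE)
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "columns.tsv"))
  m
}

#' Write peaks as BED (0-based half-open)
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, optionally `score`.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  d <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = feature_ids(peaks$chrom, peaks$start, peaks$end),
    score = peaks$score %||% 0, strand = "."
  )
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of peaks (0-based half-open)
#'
#' @param path BED file with at least chrom/start/end; column 5 is taken as
#'   the score when present.
#' @return data.frame with `chrom`, `start`, `end` and `score`.
#' @export
read_peaks_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = d[[1]], start = as.integer(d[[2]]),
                    end = as.integer(d[[3]]), stringsAsFactors = FALSE)
  if (ncol(d) >= 5) out$score <- as.numeric(d[[5]])
  out
}

#' Write per-strand mitochondrial allele counts
#'
#' Writes one MTX directory per strand matrix (`alt_fwd`, `alt_rev`,
#' `ref_fwd`, `ref_rev`) plus `variants.tsv` metadata.
#'
#' @param allele_counts list of the four strand matrices.
#' @param variants variant metadata data.frame.
#' @param dir output directory.
#' @export
write_allele_counts <- function(allele_counts, variants, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("alt_fwd", "alt_rev", "ref_fwd", "ref_rev")) {
    write_count_mtx(allele_counts[[nm]], file.path(dir, nm))
  }
  write.table(variants, file.path(dir, "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read per-strand allele counts written by [write_allele_counts()]
#'
#' @param dir directory created by [write_allele_counts()].
#' @return list with `allele_counts` (four matrices) and `variants`.
#' @export
read_allele_counts <- function(dir) {
  counts <- lapply(c(alt_fwd = "alt_fwd", alt_rev = "alt_rev",
                     ref_fwd = "ref_fwd", ref_rev = "ref_rev"),
                   function(nm) read_count_mtx(file.path(dir, nm)))
  list(allele_counts = counts,
       variants = read.delim(file.path(dir, "variants.tsv"),
                             stringsAsFactors = FALSE))
}

# Write an R object as pretty JSON (unboxing length-1 vectors).
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
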