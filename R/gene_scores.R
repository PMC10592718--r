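# Decay-weighted gene accessibility scores from a 5-kb tile matrix.

#' Tile weights for one gene under the exponential-decay model
#'
#' A tile (midpoint `m`) gets weight `1 + exp(-1)` when `m` lies inside the
#' extended gene window (TSS - 5 kb through TTS, in strand orientation),
#' `exp(-d/5000) + exp(-1)` when it flanks the window at distance `d`, and
#' 0 when `d > 20000` bp or when the tile has run into an adjacent gene
#' (midpoint at or beyond the neighbor's nearest boundary).
#'
#' @param model one-row data.frame or list with `chrom`, `strand`, `tss`,
#'   `tts`, `left_neighbor_bound`, `right_neighbor_bound` (NA = unbounded).
#' @param tiles data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param promoter_ext upstream extension of the window past the TSS
#'   (default 5000 bp).
#' @param decay_scale exponential decay scale (default 5000 bp).
#' @param max_dist weight is 0 beyond this distance (default 20000 bp).
#' @return numeric weight per tile.
#' @export
gene_tile_weights <- function(model, tiles, promoter_ext = 5000,
                              decay_scale = 5000, max_dist = 20000) {
  m <- (tiles$start + tiles$end) / 2
  w <- numeric(nrow(tiles))
  same <- tiles$chrom == model$chrom
  if (!any(same)) return(w)

  if (model$strand == "+") {
    ws <- model$tss - promoter_ext
    we <- model$tts
  } else {
    ws <- model$tts
    we <- model$tss + promoter_ext
  }
  inside <- same & m >= ws & m <= we
  w[inside] <- 1 + exp(-1)

  flank <- same & !inside
  d <- ifelse(m < ws, ws - m, m - we)
  w[flank] <- exp(-abs(d[flank]) / decay_scale) + exp(-1)
  w[same & d > max_dist & !inside] <- 0

  lb <- model$left_neighbor_bound
  rb <- model$right_neighbor_bound
  if (!is.na(lb)) w[same & m <= lb] <- 0
  if (!is.na(rb)) w[same & m >= rb] <- 0
  w
}

#' Gene accessibility scores from a tile count matrix
#'
#' Tile counts are depth-normalized per column (scaled to a constant total
#' of 10,000), then each gene's score is the weighted sum of its nearby
#' tiles under the exponential-decay weighting of [gene_tile_weights()].
#' The scores act as a chromatin-derived proxy for gene expression.
#'
#' @param tile_counts matrix (tiles x columns) of insertion counts.
#' @param tiles data.frame aligned with `tile_counts` rows (`chrom`,
#'   `start`, `end`).
#' @param models gene-model data.frame (see [gen_gene_models()]).
#' @param normalize depth-normalize columns first (default TRUE).
#' @param ... passed to [gene_tile_weights()].
#' @return numeric matrix, genes x columns.
#' @export
gene_scores <- function(tile_counts, tiles, models, normalize = TRUE, ...) {
  stopifnot(nrow(tile_counts) == nrow(tiles))
  # overlapping gene bodies break the neighbor-truncation rule
  ord <- order(models$chrom, pmin(models$tss, models$tts))
  mo <- models[ord, ]
  same_chrom <- mo$chrom[-1] == mo$chrom[-nrow(mo)]
  if (nrow(mo) > 1 &&
      any(same_chrom &
          pmin(mo$tss, mo$tts)[-1] < pmax(mo$tss, mo$tts)[-nrow(mo)])) {
    stop("gene models overlap; scores are undefined", call. = FALSE)
  }
  x <- if (normalize) {
    tot <- colSums(tile_counts)
    tot[tot == 0] <- 1
    sweep(as.matrix(tile_counts), 2, tot, "/") * 1e4
  } else as.matrix(tile_counts)

  w <- vapply(seq_len(nrow(models)),
              function(i) gene_tile_weights(models[i, ], tiles, ...),
              numeric(nrow(tiles)))
  out <- t(w) %*% x
  rownames(out) <- models$gene
  colnames(out) <- colnames(tile_counts)
  out
}
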