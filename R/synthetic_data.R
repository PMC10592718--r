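# Synthetic-data generators. Every generator takes an explicit seed, is
# byte-identical across calls with the same arguments, and returns its
# planted ground truth alongside the data so downstream stages can be
# scored against the truth.

# Draw one VAF pair consistent with a requested class. Stable pairs are
# drawn from a mixture covering all threshold regions (both high, both
# low, in the 0.05-0.1 dead zone, and single-threshold crossings that do
# not satisfy the two-sided rule).
.rand_vaf_pair <- function(class) {
  if (class == "gained") {
    c(runif(1, 0, 0.045), runif(1, 0.11, 0.7))
  } else if (class == "lost") {
    c(runif(1, 0.11, 0.7), runif(1, 0, 0.045))
  } else {
    mode <- sample.int(4L, 1L)
    if (mode == 1L) {        # both above 0.1: classic stable clone
      v <- runif(1, 0.12, 0.6)
      c(v, min(0.95, max(0.11, v + rnorm(1, 0, 0.05))))
    } else if (mode == 2L) { # both below 0.05
      c(runif(1, 0, 0.045), runif(1, 0, 0.045))
    } else if (mode == 3L) { # dead zone [0.05, 0.1]
      c(runif(1, 0.05, 0.1), runif(1, 0.05, 0.1))
    } else {                 # one-sided move that fails the paired rule
      if (runif(1) < 0.5) c(runif(1, 0.05, 0.1), runif(1, 0.11, 0.5))
      else c(runif(1, 0.11, 0.5), runif(1, 0.05, 0.1))
    }
  }
}

#' Generate a synthetic paired-VAF cohort with planted clonal bins
#'
#' Each patient is assigned a clonal bin (stable / gain / loss /
#' gain_and_loss) according to `bin_fractions`, then mutations are drawn so
#' that classifying the generated VAF pairs with the package's thresholds
#' reproduces the planted bin exactly. A fraction of mutations is emitted as
#' non-quantifiable (presence/absence semantics). Relapse-free survival
#' times are exponential with proportional hazards: the stable group's
#' hazard is `planted_hr` times the unstable group's; a configurable
#' fraction of patients is censored by an independent exponential censoring
#' time.
#'
#' @param n_patients number of patients (>= 4).
#' @param bin_fractions length-4 non-negative vector summing to 1, in the
#'   order stable, gain, loss, gain_and_loss.
#' @param mean_mutations_per_patient mean mutation count (each patient gets
#'   at least as many mutations as its bin requires).
#' @param planted_hr hazard ratio of stable versus unstable patients.
#' @param seed integer RNG seed.
#' @param frac_nonquantifiable fraction of mutations emitted with
#'   presence/absence instead of VAF (default 0.1).
#' @param censor_frac target censoring fraction (default 0.2).
#' @return list with `mutations` (data.frame: patient_id, gene, variant_id,
#'   vaf_dx, vaf_rel, quantifiable, present_dx, present_rel), `clinical`
#'   (data.frame: patient_id, time_to_relapse, event, age, sex), and `truth`
#'   (list: patient_bins, mutation_dynamics, hazard_ratio, seed).
#' @export
gen_vaf_cohort <- function(n_patients, bin_fractions = c(0.43, 0.2, 0.17, 0.2),
                           mean_mutations_per_patient = 4,
                           planted_hr = 1.5, seed = 1L,
                           frac_nonquantifiable = 0.1, censor_frac = 0.2) {
  n_patients <- assert_count(n_patients, "n_patients", min = 4L)
  if (length(bin_fractions) != 4L || any(bin_fractions < 0) ||
      abs(sum(bin_fractions) - 1) > 1e-8) {
    stop("`bin_fractions` must be 4 non-negative fractions summing to 1",
         call. = FALSE)
  }
  assert_fraction(frac_nonquantifiable, "frac_nonquantifiable")
  assert_fraction(censor_frac, "censor_frac")
  if (planted_hr <= 0) stop("`planted_hr` must be positive", call. = FALSE)

  bins <- c("stable", "gain", "loss", "gain_and_loss")
  genes <- c("NPM1", "DNMT3A", "FLT3", "RUNX1", "TET2", "WT1", "IDH1", "IDH2",
             "NRAS", "KRAS", "PTPN11", "TP53", "ASXL1", "SRSF2", "CEBPA")

  with_seed(seed, {
    patient_bin <- sample(bins, n_patients, replace = TRUE, prob = bin_fractions)
    mut_rows <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      b <- patient_bin[i]
      need <- switch(b, stable = 0L, gain = 1L, loss = 1L, gain_and_loss = 2L)
      n_mut <- max(need, 1L + rpois(1, max(0, mean_mutations_per_patient - 1)))
      classes <- rep("stable", n_mut)
      if (b == "gain") classes[1L] <- "gained"
      if (b == "loss") classes[1L] <- "lost"
      if (b == "gain_and_loss") classes[1:2] <- c("gained", "lost")
      # extra gained/lost events beyond the required ones, bin-consistent
      if (b != "stable" && n_mut > need) {
        extra <- which(runif(n_mut - need) < 0.2) + need
        pool <- switch(b, gain = "gained", loss = "lost",
                       gain_and_loss = c("gained", "lost"))
        if (length(extra)) {
          classes[extra] <- sample(pool, length(extra), replace = TRUE)
        }
      }
      quant <- runif(n_mut) >= frac_nonquantifiable
      vafs <- t(vapply(classes, .rand_vaf_pair, numeric(2)))
      mut_rows[[i]] <- data.frame(
        patient_id = sprintf("P%03d", i),
        gene = sample(genes, n_mut, replace = TRUE),
        class = classes,
        vaf_dx = ifelse(quant, vafs[, 1], NA_real_),
        vaf_rel = ifelse(quant, vafs[, 2], NA_real_),
        quantifiable = quant,
        present_dx = ifelse(quant, NA, classes != "gained"),
        present_rel = ifelse(quant, NA, classes != "lost"),
        stringsAsFactors = FALSE
      )
    }
    mutations <- do.call(rbind, mut_rows)
    mutations$variant_id <- sprintf("%s_%s_v%04d", mutations$patient_id,
                                    mutations$gene, seq_len(nrow(mutations)))
    truth_classes <- setNames(mutations$class, mutations$variant_id)
    mutations$class <- NULL
    mutations <- mutations[, c("patient_id", "gene", "variant_id", "vaf_dx",
                               "vaf_rel", "quantifiable", "present_dx",
                               "present_rel")]

    # exponential survival with proportional hazards; base median ~365 d
    base_rate <- log(2) / 365
    rate <- base_rate * ifelse(patient_bin == "stable", planted_hr, 1)
    t_event <- rexp(n_patients, rate)
    cens_rate <- if (censor_frac > 0) {
      base_rate * censor_frac / (1 - censor_frac)
    } else 0
    t_cens <- if (cens_rate > 0) rexp(n_patients, cens_rate) else rep(Inf, n_patients)
    clinical <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      time_to_relapse = pmax(1, round(pmin(t_event, t_cens))),
      event = as.integer(t_event <= t_cens),
      age = pmin(90, pmax(18, round(rnorm(n_patients, 55, 13)))),
      sex = sample(c("F", "M"), n_patients, replace = TRUE),
      stringsAsFactors = FALSE
    )

    list(
      mutations = mutations,
      clinical = clinical,
      truth = list(
        patient_bins = setNames(patient_bin, clinical$patient_id),
        mutation_dynamics = truth_classes,
        hazard_ratio = planted_hr,
        seed = as.integer(seed)
      )
    )
  })
}

#' Generate paired bulk ATAC-seq counts with planted differential peaks
#'
#' Counts are negative-binomial with a log-normal per-peak baseline and a
#' patient-level baseline shift shared by the two timepoints of a pair.
#' A fraction of peaks is differential between diagnosis and relapse with
#' log2 fold change `+effect_lfc` (first half) or `-effect_lfc` (second
#' half) applied at relapse. Peak coordinates (500 bp, non-overlapping) are
#' generated alongside the matrix; with `locus_cluster = TRUE` the
#' differential peaks are placed contiguously at the start of chromosome
#' `chrS` to plant a differential locus.
#'
#' @param n_peaks number of peaks (>= 100).
#' @param n_pairs number of diagnosis/relapse patient pairs (>= 2).
#' @param frac_differential fraction of peaks that are differential.
#' @param effect_lfc planted |log2 fold change| at relapse.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param seed integer RNG seed.
#' @param base_mean mean baseline count (default 50).
#' @param locus_cluster cluster planted peaks into one locus (default FALSE).
#' @return list with `counts` (peaks x samples integer matrix), `peaks`
#'   (data.frame chrom/start/end), `samples` (data.frame: sample, patient,
#'   timepoint), and `truth` (list: differential_peaks named lfc vector,
#'   seed).
#' @export
gen_bulk_atac <- function(n_peaks, n_pairs, frac_differential = 0.1,
                          effect_lfc = 2, dispersion = 0.2, seed = 1L,
                          base_mean = 50, locus_cluster = FALSE) {
  n_peaks <- assert_count(n_peaks, "n_peaks", min = 100L)
  n_pairs <- assert_count(n_pairs, "n_pairs", min = 2L)
  assert_fraction(frac_differential, "frac_differential")
  if (dispersion <= 0) stop("`dispersion` must be positive", call. = FALSE)

  with_seed(seed, {
    n_diff <- round(n_peaks * frac_differential)
    diff_idx <- if (locus_cluster) seq_len(n_diff) else
      sort(sample.int(n_peaks, n_diff))
    lfc <- numeric(n_peaks)
    if (n_diff > 0) {
      half <- ceiling(n_diff / 2)
      lfc[diff_idx] <- rep(c(effect_lfc, -effect_lfc),
                           c(half, n_diff - half))
    }

    # two chromosomes, 500 bp peaks spaced 1.5-2.5 kb apart
    chrom <- rep(c("chrS", "chrT"), length.out = n_peaks)
    start <- integer(n_peaks)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      gaps <- sample(1500:2500, length(idx), replace = TRUE)
      start[idx] <- cumsum(gaps) + 10000L
    }
    peaks <- data.frame(chrom = chrom, start = start, end = start + 500L,
                        stringsAsFactors = FALSE)
    peak_id <- feature_ids(peaks$chrom, peaks$start, peaks$end)

    base <- exp(rnorm(n_peaks, log(base_mean), 0.7))
    patients <- sprintf("PT%02d", seq_len(n_pairs))
    samples <- data.frame(
      sample = c(paste0(patients, "_dx"), paste0(patients, "_rel")),
      patient = rep(patients, 2),
      timepoint = rep(c("dx", "rel"), each = n_pairs),
      stringsAsFactors = FALSE
    )
    pat_shift <- exp(rnorm(n_pairs, 0, 0.3))
    counts <- matrix(0L, n_peaks, nrow(samples),
                     dimnames = list(peak_id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      p <- match(samples$patient[j], patients)
      mu <- base * pat_shift[p]
      if (samples$timepoint[j] == "rel") mu <- mu * 2^lfc
      counts[, j] <- rnbinom(n_peaks, mu = mu, size = 1 / dispersion)
    }

    list(
      counts = counts, peaks = peaks, samples = samples,
      truth = list(
        differential_peaks = setNames(lfc[diff_idx], peak_id[diff_idx]),
        seed = as.integer(seed)
      )
    )
  })
}

#' Generate non-overlapping gene models on a single chromosome
#'
#' Genes are packed left-to-right with random lengths (5-30 kb) and gaps
#' (2-40 kb), alternating-random strand. Neighbor bounds (the nearest
#' boundary of the adjacent gene on each side) are recorded for the
#' gene-score truncation rule.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param seed integer RNG seed.
#' @param chrom chromosome name (default "chrG").
#' @return data.frame with gene, chrom, strand, start, end, tss, tts,
#'   left_neighbor_bound, right_neighbor_bound (NA when no neighbor).
#' @export
gen_gene_models <- function(n_genes, chrom_length, seed = 1L, chrom = "chrG") {
  n_genes <- assert_count(n_genes, "n_genes")
  if (n_genes * 7000 > chrom_length) {
    stop("cannot pack ", n_genes, " genes into ", chrom_length, " bp",
         call. = FALSE)
  }
  with_seed(seed, {
    lens <- sample(5000:30000, n_genes, replace = TRUE)
    gaps <- sample(2000:40000, n_genes, replace = TRUE)
    # rescale so everything fits
    total <- sum(lens) + sum(gaps)
    if (total > chrom_length) {
      scale <- (chrom_length - sum(lens)) / sum(gaps)
      if (scale <= 0) stop("cannot pack genes: lengths exceed chromosome",
                           call. = FALSE)
      gaps <- pmax(500L, as.integer(gaps * scale))
      if (sum(lens) + sum(gaps) > chrom_length) {
        stop("cannot pack genes into requested chromosome length",
             call. = FALSE)
      }
    }
    start <- cumsum(gaps) + cumsum(c(0, lens[-n_genes]))
    end <- start + lens
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    data.frame(
      gene = sprintf("G%04d", seq_len(n_genes)),
      chrom = chrom, strand = strand,
      start = as.integer(start), end = as.integer(end),
      tss = as.integer(ifelse(strand == "+", start, end)),
      tts = as.integer(ifelse(strand == "+", end, start)),
      left_neighbor_bound = c(NA_integer_, as.integer(end[-n_genes])),
      right_neighbor_bound = c(as.integer(start[-1]), NA_integer_),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a labeled healthy-reference cell-by-peak matrix
#'
#' Each cell type has its own block of type-specific peaks whose mean
#' accessibility is multiplied by `exp(separation)`; `separation = 0` makes
#' all types identically distributed (classification can only reach chance
#' level), large values make types trivially separable. Counts are Poisson
#' with a per-cell depth factor.
#'
#' @param n_cells number of reference cells.
#' @param n_types number of cell types (>= 2).
#' @param n_peaks number of peaks.
#' @param separation non-negative separation strength.
#' @param seed integer RNG seed.
#' @param base_mean baseline mean count per peak (default 0.5).
#' @return list with `counts` (peaks x cells integer matrix) and `labels`
#'   (named character vector, cell -> type).
#' @export
gen_reference_scatac <- function(n_cells, n_types, n_peaks, separation = 2,
                                 seed = 1L, base_mean = 0.5) {
  n_cells <- assert_count(n_cells, "n_cells")
  n_types <- assert_count(n_types, "n_types", min = 2L)
  n_peaks <- assert_count(n_peaks, "n_peaks", min = n_types)
  if (separation < 0) stop("`separation` must be non-negative", call. = FALSE)

  with_seed(seed, {
    types <- sprintf("type%02d", seq_len(n_types))
    labels <- sample(types, n_cells, replace = TRUE)
    block <- split(seq_len(n_peaks),
                   rep(seq_len(n_types), length.out = n_peaks))
    base <- exp(rnorm(n_peaks, log(base_mean), 0.5))
    mu_type <- matrix(rep(base, n_types), n_peaks, n_types)
    for (t in seq_len(n_types)) {
      mu_type[block[[t]], t] <- mu_type[block[[t]], t] * exp(separation)
    }
    depth <- exp(rnorm(n_cells, 0, 0.3))
    counts <- matrix(0L, n_peaks, n_cells,
                     dimnames = list(sprintf("peak%05d", seq_len(n_peaks)),
                                     sprintf("cell%04d", seq_len(n_cells))))
    for (j in seq_len(n_cells)) {
      counts[, j] <- rpois(n_peaks, mu_type[, match(labels[j], types)] * depth[j])
    }
    list(counts = counts, labels = setNames(labels, colnames(counts)))
  })
}

#' Describe a planted mitochondrial clone hierarchy
#'
#' Helper constructor for [gen_mito_experiment()]. Clone `i`'s parent is
#' `parents[i]` (0 = root); a cell of clone `i` carries the variants
#' assigned to clone `i` and to all its ancestors.
#'
#' @param freq_dx,freq_rel clone frequencies at diagnosis and relapse; each
#'   must sum to 1.
#' @param parents integer parent index per clone (0 = attached to root).
#' @param vars_per_clone variants private to each clone branch (default 2).
#' @param heteroplasmy expected allele fraction of a clone's variants in its
#'   carrying cells (default 0.9).
#' @return list of class `clone_spec`.
#' @export
clone_spec <- function(freq_dx, freq_rel = freq_dx,
                       parents = rep(0L, length(freq_dx)),
                       vars_per_clone = 2L, heteroplasmy = 0.9) {
  n <- length(freq_dx)
  if (length(freq_rel) != n || length(parents) != n) {
    stop("`freq_dx`, `freq_rel` and `parents` must have equal length",
         call. = FALSE)
  }
  if (abs(sum(freq_dx) - 1) > 1e-8 || abs(sum(freq_rel) - 1) > 1e-8) {
    stop("clone frequencies must sum to 1 at each timepoint", call. = FALSE)
  }
  if (any(parents >= seq_len(n))) {
    stop("`parents[i]` must reference an earlier clone (topological order)",
         call. = FALSE)
  }
  assert_fraction(heteroplasmy, "heteroplasmy")
  structure(list(freq_dx = freq_dx, freq_rel = freq_rel,
                 parents = as.integer(parents),
                 vars_per_clone = as.integer(vars_per_clone),
                 heteroplasmy = heteroplasmy),
            class = "clone_spec")
}

#' Generate a synthetic mitochondrial single-cell experiment
#'
#' Cells are assigned to clones by the per-timepoint frequencies in `spec`.
#' For each variant and cell, per-strand coverage is Poisson distributed
#' (`mean_coverage / 2` per strand, shared by both strands); carrying cells
#' draw alternate counts binomially at the clone's heteroplasmy. With
#' `strand_noise = 0` the two strands report identical alternate counts
#' (strand correlation exactly 1 where defined); a fraction `strand_noise`
#' of cells has the two strands redrawn independently. A configurable set of
#' artifact variants (low cell count, discordant strands) is appended to
#' exercise variant filtering. Accessibility counts are Poisson around
#' clone-specific centroids: each clone has a distinct centroid at
#' diagnosis and an independently drifted centroid at relapse (same
#' deviation scale, keeping diagnosis and relapse inter-clone similarity
#' exchangeable under the null); when `convergence = TRUE` the relapse
#' centroids are additionally pulled toward one common relapse centroid
#' (`alpha * common + (1 - alpha) * clone`), raising inter-clone
#' similarity at relapse.
#'
#' @param n_cells_dx,n_cells_rel cells per timepoint.
#' @param spec a [clone_spec()].
#' @param mean_coverage mean total read coverage per variant per cell.
#' @param strand_noise fraction of carrying cells with independently
#'   redrawn strands.
#' @param convergence plant convergent epigenetic evolution at relapse?
#' @param seed integer RNG seed.
#' @param alpha pull strength toward the common relapse centroid (default 0.7).
#' @param n_peaks accessibility peaks (default 300).
#' @param n_artifact_variants strand-discordant artifact variants (default 3).
#' @return list with `allele_counts` (list of variants x cells matrices:
#'   alt_fwd, alt_rev, ref_fwd, ref_rev), `variants` (data.frame),
#'   `atac_counts` (peaks x cells), `cells` (data.frame: cell, timepoint),
#'   and `truth` (clone_labels, clone_tree parents, variant_assignments,
#'   heteroplasmy_levels, convergence_planted, freq_dx, freq_rel, seed).
#' @export
gen_mito_experiment <- function(n_cells_dx, n_cells_rel, spec,
                                mean_coverage = 20, strand_noise = 0.05,
                                convergence = FALSE, seed = 1L, alpha = 0.7,
                                n_peaks = 300L, n_artifact_variants = 3L) {
  n_cells_dx <- assert_count(n_cells_dx, "n_cells_dx")
  n_cells_rel <- assert_count(n_cells_rel, "n_cells_rel")
  if (!inherits(spec, "clone_spec")) stop("`spec` must be a clone_spec",
                                          call. = FALSE)
  if (mean_coverage <= 0) stop("`mean_coverage` must be positive", call. = FALSE)
  assert_fraction(strand_noise, "strand_noise")
  assert_fraction(alpha, "alpha")

  n_clones <- length(spec$freq_dx)
  with_seed(seed, {
    n_cells <- n_cells_dx + n_cells_rel
    timepoint <- rep(c("dx", "rel"), c(n_cells_dx, n_cells_rel))
    cell_id <- sprintf("%s_cell%04d", timepoint, seq_len(n_cells))
    clone <- integer(n_cells)
    clone[timepoint == "dx"] <- sample.int(n_clones, n_cells_dx,
                                           replace = TRUE, prob = spec$freq_dx)
    clone[timepoint == "rel"] <- sample.int(n_clones, n_cells_rel,
                                            replace = TRUE, prob = spec$freq_rel)

    # variants: vars_per_clone private to each clone branch; carried by the
    # clone and all its descendants
    n_real <- n_clones * spec$vars_per_clone
    var_clone <- rep(seq_len(n_clones), each = spec$vars_per_clone)
    pos <- sort(sample(100:16400, n_real + n_artifact_variants))
    subs <- paste0(sample(c("A", "C", "G", "T"), n_real + n_artifact_variants,
                          replace = TRUE), ">",
                   sample(c("A", "C", "G", "T"), n_real + n_artifact_variants,
                          replace = TRUE))
    var_id <- sprintf("%d%s", pos, gsub(">", "", subs))
    n_var <- n_real + n_artifact_variants

    # clone ancestry: does cell clone c carry variants of clone v?
    anc <- matrix(FALSE, n_clones, n_clones)  # anc[c, v]: v in ancestry of c
    for (c_i in seq_len(n_clones)) {
      v <- c_i
      while (v != 0L) {
        anc[c_i, v] <- TRUE
        v <- spec$parents[v]
      }
    }

    dims <- list(var_id, cell_id)
    alt_f <- matrix(0L, n_var, n_cells, dimnames = dims)
    alt_r <- matrix(0L, n_var, n_cells, dimnames = dims)
    cov_s <- matrix(rpois(n_var * n_cells, mean_coverage / 2), n_var, n_cells,
                    dimnames = dims)
    for (v in seq_len(n_real)) {
      carrier <- anc[clone, var_clone[v]]
      if (!any(carrier)) next
      idx <- which(carrier)
      a <- rbinom(length(idx), cov_s[v, idx], spec$heteroplasmy)
      alt_f[v, idx] <- a
      alt_r[v, idx] <- a
      noisy <- idx[runif(length(idx)) < strand_noise]
      if (length(noisy)) {
        alt_f[v, noisy] <- rbinom(length(noisy), cov_s[v, noisy],
                                  spec$heteroplasmy)
        alt_r[v, noisy] <- rbinom(length(noisy), cov_s[v, noisy],
                                  spec$heteroplasmy)
      }
    }
    # artifact variants: detected in too few cells to pass the filter,
    # with the two strands drawn independently (discordant)
    if (n_artifact_variants > 0) {
      for (v in n_real + seq_len(n_artifact_variants)) {
        idx <- sample.int(n_cells, min(n_cells, sample(2:3, 1)))
        alt_f[v, idx] <- rbinom(length(idx), cov_s[v, idx], 0.5)
        alt_r[v, idx] <- rbinom(length(idx), cov_s[v, idx], 0.5)
      }
    }
    ref_f <- cov_s - alt_f
    ref_r <- cov_s - alt_r

    # accessibility: clone centroids at dx; optional convergence at relapse
    base <- exp(rnorm(n_peaks, log(2), 0.5))
    centroid_dx <- sapply(seq_len(n_clones), function(i) {
      base * exp(rnorm(n_peaks, 0, 0.6))
    })
    # relapse centroids: every clone drifts (independent redraw at the same
    # deviation scale); under convergence the drifted centroids are pulled
    # toward one common relapse centroid
    common_rel <- base * exp(rnorm(n_peaks, 0, 0.6))
    drift <- sapply(seq_len(n_clones), function(i) {
      base * exp(rnorm(n_peaks, 0, 0.6))
    })
    centroid_rel <- if (convergence) {
      alpha * common_rel + (1 - alpha) * drift
    } else drift
    atac <- matrix(0L, n_peaks, n_cells,
                   dimnames = list(sprintf("mpeak%04d", seq_len(n_peaks)),
                                   cell_id))
    for (j in seq_len(n_cells)) {
      mu <- if (timepoint[j] == "dx") centroid_dx[, clone[j]]
            else centroid_rel[, clone[j]]
      atac[, j] <- rpois(n_peaks, mu)
    }

    variants <- data.frame(
      variant = var_id, position = pos, substitution = subs,
      artifact = rep(c(FALSE, TRUE), c(n_real, n_artifact_variants)),
      stringsAsFactors = FALSE
    )
    list(
      allele_counts = list(alt_fwd = alt_f, alt_rev = alt_r,
                           ref_fwd = ref_f, ref_rev = ref_r),
      variants = variants,
      atac_counts = atac,
      cells = data.frame(cell = cell_id, timepoint = timepoint,
                         stringsAsFactors = FALSE),
      truth = list(
        clone_labels = setNames(paste0("clone", clone), cell_id),
        clone_tree = spec$parents,
        variant_assignments = setNames(paste0("clone", var_clone),
                                       var_id[seq_len(n_real)]),
        heteroplasmy_levels = setNames(rep(spec$heteroplasmy, n_real),
                                       var_id[seq_len(n_real)]),
        convergence_planted = convergence,
        freq_dx = spec$freq_dx, freq_rel = spec$freq_rel,
        seed = as.integer(seed)
      )
    )
  })
}
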