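# End-to-end orchestration of the two headline analyses on synthetic
# cohorts, with persisted intermediates and a reproducibility manifest.

.stable_defaults <- list(
  seed = 1L, out_dir = NULL,
  n_patients = 120L, bin_fractions = c(0.43, 0.2, 0.17, 0.2),
  mean_mutations_per_patient = 4, planted_hr = 1.5,
  n_peaks = 600L, n_pairs = 6L, frac_differential = 0.1,
  effect_lfc = 2, dispersion = 0.2,
  n_genes = 400L, n_signature = 50L, min_events = 20L
)

.mito_defaults <- list(
  seed = 1L, out_dir = NULL,
  n_cells_dx = 300L, n_cells_rel = 300L,
  freq_dx = c(0.5, 0.3, 0.2), freq_rel = c(0.2, 0.3, 0.5),
  parents = c(0L, 0L, 0L), vars_per_clone = 2L, heteroplasmy = 0.9,
  mean_coverage = 20, strand_noise = 0.05, convergence = TRUE,
  alpha = 0.7, n_peaks = 300L,
  binarize_threshold = 0.1, knn = 20L, resolution = 1,
  min_clone_cells = 20L
)

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected; unspecified keys take the documented module
#' defaults. The configuration round-trips losslessly through JSON.
#'
#' @param analysis `"stable"` (mutation dynamics + chromatin signature) or
#'   `"mito"` (mitoclone convergence).
#' @param ... stage parameters overriding the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(analysis = c("stable", "mito"), ...) {
  analysis <- match.arg(analysis)
  defaults <- if (analysis == "stable") .stable_defaults else .mito_defaults
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, override)
  cfg$analysis <- analysis
  structure(cfg, class = "pipeline_config")
}

.write_stage <- function(out_dir, name, writer) {
  if (is.null(out_dir)) return(invisible(NULL))
  writer(file.path(out_dir, name))
}

.manifest <- function(cfg, out_dir) {
  if (is.null(out_dir)) return(NULL)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("relapseEvo")),
    files = as.list(setNames(unname(sums), files))
  )
  write_json_report(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

#' Run the stable-relapse analysis end to end on a synthetic cohort
#'
#' Generates a paired-VAF cohort and paired bulk accessibility data, then
#' executes mutation classification, patient binning, ternary summaries,
#' relapse-free survival, diagnosis-relapse similarity, peak-level
#' differential accessibility, the relapse signature (from a gene-level
#' matrix) and per-sample relapse scores. Truth-based recovery metrics are
#' included in the report. Fully deterministic given the config seed.
#'
#' @param config a `pipeline_config` with `analysis = "stable"`.
#' @return list report with per-stage results and `recovery` metrics;
#'   intermediates and a manifest are persisted when `out_dir` is set.
#' @export
run_stable_relapse_analysis <- function(config = pipeline_config("stable")) {
  stopifnot(inherits(config, "pipeline_config"),
            identical(config$analysis, "stable"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  cohort <- gen_vaf_cohort(
    n_patients = config$n_patients, bin_fractions = config$bin_fractions,
    mean_mutations_per_patient = config$mean_mutations_per_patient,
    planted_hr = config$planted_hr,
    seed = derive_seed(config$seed, "cohort")
  )
  classes <- classify_mutations(cohort$mutations)
  bins <- bin_patients(cohort$mutations)
  ternary <- ternary_coordinates(cohort$mutations,
                                 min_events = config$min_events)
  clinical <- merge(cohort$clinical, bins, by = "patient_id")
  surv <- relapse_free_survival(clinical)

  atac <- gen_bulk_atac(
    n_peaks = config$n_peaks, n_pairs = config$n_pairs,
    frac_differential = config$frac_differential,
    effect_lfc = config$effect_lfc, dispersion = config$dispersion,
    seed = derive_seed(config$seed, "atac")
  )
  similarity <- dx_rel_similarity(cpm_normalize(atac$counts), atac$samples)
  diff_peaks <- differential_accessibility(atac$counts,
                                           atac$samples$timepoint,
                                           atac$samples$patient)

  genes <- gen_bulk_atac(
    n_peaks = config$n_genes, n_pairs = config$n_pairs,
    frac_differential = config$frac_differential,
    effect_lfc = config$effect_lfc, dispersion = config$dispersion,
    seed = derive_seed(config$seed, "genescores")
  )
  rownames(genes$counts) <- sprintf("G%04d", seq_len(config$n_genes))
  names(genes$truth$differential_peaks) <-
    rownames(genes$counts)[match(names(genes$truth$differential_peaks),
                                 feature_ids(genes$peaks$chrom,
                                             genes$peaks$start,
                                             genes$peaks$end))]
  sig <- suppressWarnings(derive_relapse_signature(
    genes$counts, genes$samples$timepoint, genes$samples$patient,
    n_set = config$n_signature
  ))
  scores <- relapse_score(genes$counts, sig)

  planted_up <- names(genes$truth$differential_peaks)[
    genes$truth$differential_peaks > 0]
  recovery <- list(
    bin_recovery = mean(bins$clonal_bin ==
                          cohort$truth$patient_bins[bins$patient_id]),
    class_recovery = mean(classes ==
                            cohort$truth$mutation_dynamics[
                              cohort$mutations$variant_id]),
    signature_recovery = if (length(planted_up)) {
      mean(planted_up %in% sig$top_set)
    } else NA_real_,
    mean_score_rel_minus_dx =
      mean(scores[genes$samples$timepoint == "rel"]) -
      mean(scores[genes$samples$timepoint == "dx"])
  )

  report <- list(
    config_seed = config$seed,
    n_mutations = nrow(cohort$mutations),
    bins = bins, ternary = ternary,
    survival = list(hr = surv$hr, hr_ci = surv$hr_ci, wald_p = surv$wald_p,
                    logrank_p = surv$logrank_p,
                    n_stable = surv$n_stable, n_unstable = surv$n_unstable),
    similarity = similarity,
    n_significant_peaks = sum(diff_peaks$p_adj < 0.05, na.rm = TRUE),
    signature = list(top_set = sig$top_set, bottom_set = sig$bottom_set),
    relapse_scores = scores,
    recovery = recovery
  )

  if (!is.null(out_dir)) {
    write.csv(cohort$mutations, file.path(out_dir, "mutations.csv"),
              row.names = FALSE)
    write.csv(clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)
    write.csv(data.frame(variant_id = cohort$mutations$variant_id,
                         class = classes),
              file.path(out_dir, "mutation_classes.csv"), row.names = FALSE)
    write.csv(bins, file.path(out_dir, "patient_bins.csv"), row.names = FALSE)
    write.csv(ternary, file.path(out_dir, "ternary.csv"), row.names = FALSE)
    write.table(diff_peaks, file.path(out_dir, "differential_peaks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sig$ranked, file.path(out_dir, "signature_ranked.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_count_mtx(atac$counts, file.path(out_dir, "peak_counts"))
    write_json_report(report[c("config_seed", "survival",
                               "n_significant_peaks", "recovery")],
                      file.path(out_dir, "report.json"))
    report$manifest <- .manifest(config, out_dir)
  }
  report
}

#' Run the mitoclone convergence analysis end to end
#'
#' Generates a synthetic mitochondrial single-cell experiment, then
#' executes heteroplasmy computation, strict variant filtering, clone
#' clustering, per-clone variant summaries, clone-tree reconstruction,
#' per-timepoint frequencies, pseudobulk construction, and the
#' convergent-evolution test. Truth-based recovery (adjusted Rand index)
#' is reported.
#'
#' @param config a `pipeline_config` with `analysis = "mito"`.
#' @return list report; intermediates and a manifest are persisted when
#'   `out_dir` is set.
#' @export
run_mitoclone_analysis <- function(config = pipeline_config("mito")) {
  stopifnot(inherits(config, "pipeline_config"),
            identical(config$analysis, "mito"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  spec <- clone_spec(config$freq_dx, config$freq_rel, config$parents,
                     config$vars_per_clone, config$heteroplasmy)
  expt <- gen_mito_experiment(
    n_cells_dx = config$n_cells_dx, n_cells_rel = config$n_cells_rel,
    spec = spec, mean_coverage = config$mean_coverage,
    strand_noise = config$strand_noise, convergence = config$convergence,
    seed = derive_seed(config$seed, "mito"), alpha = config$alpha,
    n_peaks = config$n_peaks
  )
  hp <- compute_heteroplasmy(expt$allele_counts)
  passing <- filter_variants(hp$stats)
  assignment <- cluster_mitoclones(
    hp$heteroplasmy[passing, , drop = FALSE],
    binarize_threshold = config$binarize_threshold,
    knn = config$knn, resolution = config$resolution,
    seed = derive_seed(config$seed, "cluster")
  )
  summ <- clone_variant_summary(hp$heteroplasmy[passing, , drop = FALSE],
                                assignment)
  tree <- build_clone_tree(summ)
  tps <- setNames(expt$cells$timepoint, expt$cells$cell)
  freqs <- clone_frequencies(assignment, tps)
  pb <- clone_pseudobulk(expt$atac_counts, assignment, tps,
                         min_cells = config$min_clone_cells)
  conv <- convergence_test(pb$pseudobulk, pb$meta)

  report <- list(
    config_seed = config$seed,
    n_variants_passing = length(passing),
    n_clones = length(unique(as.character(assignment))),
    ari = mclust::adjustedRandIndex(as.character(assignment),
                                    expt$truth$clone_labels[names(assignment)]),
    tree = tree$nodes,
    tree_conflicts = tree$conflicts,
    frequencies = freqs,
    convergence = list(mean_cor_dx = mean(conv$cor_dx),
                       mean_cor_rel = mean(conv$cor_rel),
                       mean_diff = conv$mean_diff, t = conv$t, p = conv$p,
                       converged = conv$converged),
    convergence_planted = expt$truth$convergence_planted
  )

  if (!is.null(out_dir)) {
    write_allele_counts(expt$allele_counts, expt$variants,
                        file.path(out_dir, "allele_counts"))
    write.table(hp$stats, file.path(out_dir, "variant_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.csv(data.frame(cell = names(assignment),
                         clone = as.character(assignment)),
              file.path(out_dir, "clone_assignment.csv"), row.names = FALSE)
    write.csv(freqs, file.path(out_dir, "clone_frequencies.csv"),
              row.names = FALSE)
    write_json_report(list(nodes = tree$nodes, conflicts = tree$conflicts),
                      file.path(out_dir, "clone_tree.json"))
    write_json_report(report[c("config_seed", "n_variants_passing",
                               "n_clones", "ari", "convergence",
                               "convergence_planted")],
                      file.path(out_dir, "report.json"))
    report$manifest <- .manifest(config, out_dir)
  }
  report
}
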