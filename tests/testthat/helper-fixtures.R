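# Shared fixtures. Expensive objects (anything that runs the NB
# differential fit) are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Paired bulk cohort with planted differential peaks plus its fit.
diff_fixture <- function() {
  fixture("diff", {
    atac <- gen_bulk_atac(300, 6, frac_differential = 0.1, effect_lfc = 2,
                          dispersion = 0.2, seed = 101)
    res <- differential_accessibility(atac$counts, atac$samples$timepoint,
                                      atac$samples$patient)
    list(atac = atac, res = res)
  })
}

# Gene-level paired cohort (synthetic accessibility scores) and the
# relapse signature derived from it.
signature_fixture <- function() {
  fixture("signature", {
    genes <- gen_bulk_atac(200, 6, frac_differential = 0.2, effect_lfc = 2,
                           dispersion = 0.2, seed = 202)
    rownames(genes$counts) <- sprintf("G%04d", seq_len(nrow(genes$counts)))
    names(genes$truth$differential_peaks) <- rownames(genes$counts)[
      match(names(genes$truth$differential_peaks),
            sprintf("%s:%d-%d", genes$peaks$chrom, genes$peaks$start,
                    genes$peaks$end))]
    sig <- suppressWarnings(derive_relapse_signature(
      genes$counts, genes$samples$timepoint, genes$samples$patient,
      n_set = 20))
    list(genes = genes, sig = sig)
  })
}

# Default three-clone mitochondrial experiment and its heteroplasmy.
mito_fixture <- function() {
  fixture("mito", {
    sp <- clone_spec(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
    expt <- gen_mito_experiment(300, 300, sp, mean_coverage = 20,
                                strand_noise = 0.05, convergence = TRUE,
                                seed = 303)
    hp <- compute_heteroplasmy(expt$allele_counts)
    list(spec = sp, expt = expt, hp = hp)
  })
}

# Small end-to-end stable-relapse run (one NB fit), reused across tests.
stable_run_fixture <- function() {
  fixture("stable_run", {
    out <- file.path(tempdir(), "stable_run_a")
    cfg <- pipeline_config("stable", seed = 11L, out_dir = out,
                           n_patients = 60L, n_peaks = 150L,
                           n_genes = 120L, n_signature = 12L, n_pairs = 4L)
    list(cfg = cfg, report = run_stable_relapse_analysis(cfg))
  })
}

# Well-separated three-type reference and its LSI model.
lsi_fixture <- function() {
  fixture("lsi", {
    ref <- gen_reference_scatac(300, 3, 400, separation = 2, seed = 404)
    model <- fit_lsi(ref$counts, k = 15, labels = ref$labels)
    list(ref = ref, model = model)
  })
}
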