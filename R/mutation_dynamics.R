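#' Classify paired diagnosis-relapse mutations as gained, lost or stable
#'
#' A quantifiable mutation is *gained* when its variant allele frequency
#' (VAF) moves from below 0.05 at diagnosis to above 0.1 at relapse, *lost*
#' when it moves from above 0.1 at diagnosis to below 0.05 at relapse, and
#' *stable* otherwise. All inequalities are strict: a VAF sitting exactly on
#' a threshold does not cross it. Mutations whose VAF cannot be quantified
#' (e.g. FLT3-ITD, NPM1 insertions) are classified on presence/absence
#' instead: absent-to-present is gained, present-to-absent is lost.
#'
#' @param mutations data.frame with columns `vaf_dx`, `vaf_rel` (fractions in
#'   \[0,1\]) and optionally `quantifiable` (logical, default `TRUE`) plus
#'   `present_dx`, `present_rel` (logical; used only when `quantifiable` is
#'   `FALSE`).
#' @return Character vector, one of `"gained"`, `"lost"`, `"stable"` per row.
#' @examples
#' classify_mutations(data.frame(vaf_dx = c(0.02, 0.4), vaf_rel = c(0.3, 0.4)))
#' @export
classify_mutations <- function(mutations) {
  stopifnot(is.data.frame(mutations))
  n <- nrow(mutations)
  quant <- if ("quantifiable" %in% names(mutations)) {
    as.logical(mutations$quantifiable)
  } else rep(TRUE, n)
  quant[is.na(quant)] <- TRUE

  out <- rep("stable", n)
  if (any(quant)) {
    vd <- mutations$vaf_dx[quant]
    vr <- mutations$vaf_rel[quant]
    if (anyNA(vd) || anyNA(vr)) {
      stop("quantifiable mutations must have both `vaf_dx` and `vaf_rel`",
           call. = FALSE)
    }
    assert_fraction(vd, "vaf_dx")
    assert_fraction(vr, "vaf_rel")
    cls <- rep("stable", sum(quant))
    cls[vd < 0.05 & vr > 0.1] <- "gained"
    cls[vd > 0.1 & vr < 0.05] <- "lost"
    out[quant] <- cls
  }
  if (any(!quant)) {
    pd <- as.logical(mutations$present_dx[!quant])
    pr <- as.logical(mutations$present_rel[!quant])
    if (anyNA(pd) || anyNA(pr)) {
      stop("non-quantifiable mutations must have `present_dx`/`present_rel`",
           call. = FALSE)
    }
    cls <- rep("stable", sum(!quant))
    cls[!pd & pr] <- "gained"
    cls[pd & !pr] <- "lost"
    out[!quant] <- cls
  }
  out
}

#' Bin a patient by the dynamics of its mutations
#'
#' Patients are placed into one of four clonal-evolution bins from the
#' classes of their individual mutations: `stable` (no gained, no lost
#' mutation), `gain` (at least one gained, none lost), `loss` (at least one
#' lost, none gained), `gain_and_loss` (both). The result does not depend on
#' mutation order.
#'
#' @param x either a character vector of per-mutation classes
#'   (`"gained"`/`"lost"`/`"stable"`) or a data.frame accepted by
#'   [classify_mutations()].
#' @return One of `"stable"`, `"gain"`, `"loss"`, `"gain_and_loss"`.
#' @export
bin_patient <- function(x) {
  if (is.data.frame(x)) x <- classify_mutations(x)
  if (length(x) == 0L) stop("patient has no mutations to bin", call. = FALSE)
  bad <- setdiff(unique(x), c("gained", "lost", "stable"))
  if (length(bad)) {
    stop("unknown mutation class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  g <- any(x == "gained")
  l <- any(x == "lost")
  if (g && l) "gain_and_loss" else if (g) "gain" else if (l) "loss" else "stable"
}

#' Bin every patient in a mutation table
#'
#' @param mutations data.frame with a `patient_id` column plus the columns
#'   required by [classify_mutations()].
#' @return data.frame with `patient_id` and `clonal_bin`.
#' @export
bin_patients <- function(mutations) {
  stopifnot(is.data.frame(mutations), "patient_id" %in% names(mutations))
  cls <- classify_mutations(mutations)
  ids <- unique(mutations$patient_id)
  bins <- vapply(ids, function(p) bin_patient(cls[mutations$patient_id == p]),
                 character(1))
  data.frame(patient_id = ids, clonal_bin = bins, stringsAsFactors = FALSE)
}

#' Per-gene mutation-dynamics fractions for a ternary plot
#'
#' For each gene with at least `min_events` mutations across the cohort,
#' returns the fraction of its mutations classified gained, lost and stable.
#' The three fractions sum to one; the event count is returned for dot
#' sizing.
#'
#' @param mutations data.frame with `gene` plus the columns required by
#'   [classify_mutations()].
#' @param min_events minimum number of mutations a gene needs to be reported
#'   (default 20).
#' @return data.frame with `gene`, `n_events`, `frac_gained`, `frac_lost`,
#'   `frac_stable`, ordered by decreasing `n_events`.
#' @export
ternary_coordinates <- function(mutations, min_events = 20L) {
  stopifnot(is.data.frame(mutations), "gene" %in% names(mutations))
  min_events <- assert_count(min_events, "min_events")
  cls <- classify_mutations(mutations)
  tab <- table(gene = mutations$gene, class = factor(cls,
    levels = c("gained", "lost", "stable")))
  n <- rowSums(tab)
  keep <- n >= min_events
  tab <- tab[keep, , drop = FALSE]
  n <- n[keep]
  out <- data.frame(
    gene = rownames(tab),
    n_events = as.integer(n),
    frac_gained = as.numeric(tab[, "gained"] / n),
    frac_lost = as.numeric(tab[, "lost"] / n),
    frac_stable = as.numeric(tab[, "stable"] / n),
    stringsAsFactors = FALSE
  )
  out[order(-out$n_events, out$gene), , drop = FALSE]
}

#' Relapse-free survival: clonally stable versus unstable patients
#'
#' Patients are grouped into `stable` (clonal bin `stable`) versus
#' `unstable` (any other bin). Returns Kaplan-Meier survival tables per
#' group, the Cox proportional-hazards ratio for stable versus unstable
#' adjusted for age and sex (Efron tie handling), the Wald p-value of the
#' group term, and the log-rank p-value.
#'
#' @param patients data.frame with `patient_id`, `clonal_bin`,
#'   `time_to_relapse` (days, positive), `event` (logical/0-1), `age`
#'   (years), `sex` (two-level category).
#' @return list with elements `km` (data.frame: group, time, n_risk,
#'   n_event, surv), `hr`, `hr_ci` (length-2), `wald_p`, `logrank_p`,
#'   `n_stable`, `n_unstable`, and the fitted `cox` model.
#' @export
relapse_free_survival <- function(patients) {
  need <- c("patient_id", "clonal_bin", "time_to_relapse", "event", "age", "sex")
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(patients$time_to_relapse <= 0)) {
    stop("`time_to_relapse` must be positive", call. = FALSE)
  }
  grp <- factor(ifelse(patients$clonal_bin == "stable", "stable", "unstable"),
                levels = c("unstable", "stable"))
  if (nlevels(droplevels(grp)) < 2L || min(table(grp)) < 2L) {
    stop("need at least 2 patients in each of the stable and unstable groups",
         call. = FALSE)
  }
  d <- data.frame(
    time = patients$time_to_relapse,
    event = as.integer(patients$event),
    group = grp,
    age = patients$age,
    sex = factor(patients$sex)
  )
  if (nlevels(d$sex) > 2L) stop("`sex` must have at most two levels", call. = FALSE)

  fit_km <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  s <- summary(fit_km)
  km <- data.frame(
    group = sub("^group=", "", as.character(s$strata)),
    time = s$time, n_risk = s$n.risk, n_event = s$n.event, surv = s$surv,
    stringsAsFactors = FALSE
  )
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)

  cox <- survival::coxph(
    survival::Surv(time, event) ~ group + age + sex,
    data = d, ties = "efron"
  )
  sc <- summary(cox)
  row <- grep("^groupstable$", rownames(sc$coefficients))
  hr <- unname(sc$coefficients[row, "exp(coef)"])
  wald_p <- unname(sc$coefficients[row, "Pr(>|z|)"])
  ci <- unname(sc$conf.int[row, c("lower .95", "upper .95")])

  list(
    km = km, hr = hr, hr_ci = ci, wald_p = wald_p, logrank_p = logrank_p,
    n_stable = sum(grp == "stable"), n_unstable = sum(grp == "unstable"),
    cox = cox
  )
}
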