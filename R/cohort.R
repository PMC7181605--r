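# Longitudinal biopsy cohort: loading/validation, a synthetic-cohort
# generator with the published cohort's statistical structure, and the
# progression and clinical-association analyses.

TIMEPOINTS <- c("D0", "D15_30", "M3", "M12")

BANFF_COLS <- c("ci", "ct", "i", "ti", "t", "g", "ptc", "v", "cg", "mm",
                "cv", "ah")

#' Per-timepoint mIF means and SDs of the transplant cohort
#'
#' Percent fibrosis at donor baseline (D0), days 15-30, month 3 and month
#' 12, with the number of biopsies available at each timepoint in the
#' 66-patient cohort.
#'
#' @return Data frame with columns timepoint, n, mean, sd.
#' @export
timepoint_specs_default <- function() {
  data.frame(timepoint = TIMEPOINTS, n = c(43L, 20L, 28L, 28L),
             mean = c(8.4, 10.0, 13.6, 15.9), sd = c(3.8, 3.9, 6.7, 5.2))
}

#' Assemble and validate a cohort table
#'
#' @param patients data frame with at least `patient_id`; clinical columns
#'   (`time_to_recovery_days`, `creatinine_m12`, `creatinine_last`,
#'   `ldh_d3`, `delayed_graft_function`) optional.
#' @param biopsies data frame with `patient_id`, `timepoint` and at least
#'   one of `mif_percent` / Banff grade columns.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(patients, biopsies) {
  patients <- as.data.frame(patients); biopsies <- as.data.frame(biopsies)
  if (!"patient_id" %in% names(patients))
    fq_error("fq_schema_error", "patients needs a patient_id column")
  if (anyDuplicated(patients$patient_id))
    fq_error("fq_schema_error", "duplicate patient_id in patients")
  if (!all(c("patient_id", "timepoint") %in% names(biopsies)))
    fq_error("fq_schema_error", "biopsies need patient_id and timepoint columns")
  if (!all(biopsies$timepoint %in% TIMEPOINTS))
    fq_error("fq_schema_error",
             sprintf("timepoint must be one of %s",
                     paste(TIMEPOINTS, collapse = ", ")))
  unknown <- setdiff(biopsies$patient_id, patients$patient_id)
  if (length(unknown) > 0L)
    fq_error("fq_schema_error",
             sprintf("biopsies reference unknown patients: %s",
                     paste(unique(unknown), collapse = ", ")))
  key <- paste(biopsies$patient_id, biopsies$timepoint)
  if (anyDuplicated(key))
    fq_error("fq_schema_error",
             sprintf("duplicate (patient, timepoint): %s",
                     paste(unique(key[duplicated(key)]), collapse = ", ")))
  has_mif <- "mif_percent" %in% names(biopsies) && any(!is.na(biopsies$mif_percent))
  has_banff <- any(BANFF_COLS %in% names(biopsies))
  if (!has_mif && !has_banff)
    fq_error("fq_schema_error",
             "biopsies need mif_percent and/or Banff grade columns")
  if ("ci" %in% names(biopsies)) {
    ok <- is.na(biopsies$ci) | (biopsies$ci %in% 0:3)
    if (!all(ok))
      fq_error("fq_schema_error", "Banff ci grades must be integers in 0..3")
  }
  structure(list(patients = patients, biopsies = biopsies),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients, %d biopsies (%s)\n",
              nrow(x$patients), nrow(x$biopsies),
              paste(sprintf("%s=%d", TIMEPOINTS,
                            vapply(TIMEPOINTS, function(tp)
                              sum(x$biopsies$timepoint == tp), 0L)),
                    collapse = ", ")))
  invisible(x)
}

#' Load a cohort from patients/biopsies CSV files
#'
#' @param patients_path,biopsies_path headered CSVs; see [cohort_table()]
#'   for required columns.
#' @return A `cohort_table`.
#' @export
load_cohort <- function(patients_path, biopsies_path) {
  for (p in c(patients_path, biopsies_path))
    if (!file.exists(p))
      fq_error("fq_input_error", sprintf("cohort file not found: %s", p))
  cohort_table(utils::read.csv(patients_path),
               utils::read.csv(biopsies_path))
}

#' Write a cohort to patients.csv and biopsies.csv
#'
#' @param cohort a `cohort_table`.
#' @param out_dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(out_dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$biopsies, file.path(out_dir, "biopsies.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Generate a synthetic longitudinal cohort
#'
#' Each patient carries a latent fibrosis-severity factor; the fibrosis
#' score at timepoint t is `mean_t + sd_t * (sqrt(rho) z_i + sqrt(1-rho)
#' e_it)` (a Gaussian copula with within-patient correlation `rho` across
#' timepoints), truncated to `[0, 100]`. The Banff ci grade is the count
#' of `ci_thresholds` below the score, with thresholds calibrated so the
#' per-grade means approximate the published validation groups. Clinical
#' outcomes are linear in the latent month-12 score with noise scaled to
#' hit the target R-squared in expectation; the day-3 LDH peak is coupled
#' to recovery time the same way. Biopsy availability is subsampled to the
#' published per-timepoint counts (scaled when `n_patients != 66`), keeping
#' the month-3 and month-12 sets aligned and at least seven patients with
#' all of D15-30, M3 and M12 so a paired subgroup exists.
#'
#' @param n_patients cohort size (default 66).
#' @param timepoint_specs data frame (timepoint, n, mean, sd); default
#'   [timepoint_specs_default()].
#' @param within_patient_corr latent correlation `rho` in `[0, 1)`.
#' @param ci_thresholds ascending cut points mapping percent fibrosis to
#'   Banff ci grades 0-3.
#' @param r2_time_to_recovery,r2_creatinine_m12,r2_creatinine_last target
#'   R-squared of each outcome on month-12 fibrosis.
#' @param r2_ldh_recovery target R-squared of recovery time on day-3 LDH.
#' @param threshold_jitter_sd SD of per-biopsy jitter on the ci thresholds
#'   (0 = deterministic grading).
#' @param seed RNG seed.
#' @return A `cohort_table`.
#' @export
generate_synthetic_cohort <- function(n_patients = 66L,
                                      timepoint_specs = timepoint_specs_default(),
                                      within_patient_corr = 0.5,
                                      ci_thresholds = c(9.5, 13.5, 19.0),
                                      r2_time_to_recovery = 0.29,
                                      r2_creatinine_m12 = 0.32,
                                      r2_creatinine_last = 0.29,
                                      r2_ldh_recovery = 0.1028,
                                      threshold_jitter_sd = 0,
                                      seed = 1L) {
  stopifnot(n_patients >= 8, within_patient_corr >= 0, within_patient_corr < 1,
            !is.unsorted(ci_thresholds, strictly = TRUE))
  for (r2 in c(r2_time_to_recovery, r2_creatinine_m12, r2_creatinine_last,
               r2_ldh_recovery))
    if (r2 < 0 || r2 >= 1)
      fq_error("fq_parameter_error", "target R-squared must lie in [0, 1)")
  sp <- as.data.frame(timepoint_specs)
  stopifnot(all(c("timepoint", "n", "mean", "sd") %in% names(sp)),
            all(TIMEPOINTS %in% sp$timepoint))
  sp <- sp[match(TIMEPOINTS, sp$timepoint), ]
  with_seed(seed, {
    rho <- within_patient_corr
    z <- stats::rnorm(n_patients)
    mif <- sapply(seq_len(nrow(sp)), function(t) {
      u <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n_patients)
      pmin(pmax(sp$mean[t] + sp$sd[t] * u, 0), 100)
    })
    colnames(mif) <- TIMEPOINTS

    # availability per timepoint, scaled from the published counts
    counts <- pmin(round(sp$n * n_patients / 66), n_patients)
    idx_m12 <- sort(sample.int(n_patients, counts[4]))
    idx_m3 <- if (counts[3] == counts[4]) idx_m12 else
      sort(sample.int(n_patients, counts[3]))
    core <- intersect(idx_m3, idx_m12)
    n_paired <- min(7L, length(core), counts[2])
    paired <- if (n_paired > 0) sample(core, n_paired) else integer(0)
    rest <- setdiff(seq_len(n_patients), paired)
    idx_d15 <- sort(c(paired, sample(rest, max(0, counts[2] - n_paired))))
    idx_d0 <- sort(sample.int(n_patients, counts[1]))
    avail <- list(D0 = idx_d0, D15_30 = idx_d15, M3 = idx_m3, M12 = idx_m12)

    # clinical outcomes driven by the latent M12 score
    m12 <- mif[, "M12"]
    mk_outcome <- function(base_mean, base_sd, r2, x, x_mean, x_sd) {
      beta <- sqrt(r2) * base_sd / x_sd
      base_mean + beta * (x - x_mean) + stats::rnorm(n_patients) *
        base_sd * sqrt(1 - r2)
    }
    ttr <- pmax(mk_outcome(22.6, 9.8, r2_time_to_recovery, m12,
                           sp$mean[4], sp$sd[4]), 1)
    creat_m12 <- mk_outcome(15, 20, r2_creatinine_m12, m12,
                            sp$mean[4], sp$sd[4])
    creat_last <- mk_outcome(20, 25, r2_creatinine_last, m12,
                             sp$mean[4], sp$sd[4])
    ldh <- pmax(mk_outcome(2539, 1089, r2_ldh_recovery, ttr, 22.6, 9.8), 100)
    dgf <- stats::runif(n_patients) < stats::plogis((ttr - 8) / 3)

    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      time_to_recovery_days = ttr,
      creatinine_m12 = creat_m12, creatinine_last = creat_last,
      ldh_d3 = ldh, delayed_graft_function = dgf)

    grade_of <- function(v) {
      thr <- matrix(ci_thresholds, length(v), 3, byrow = TRUE)
      if (threshold_jitter_sd > 0)
        thr <- thr + stats::rnorm(length(thr), 0, threshold_jitter_sd)
      rowSums(v > thr)
    }
    biopsies <- do.call(rbind, lapply(TIMEPOINTS, function(tp) {
      ids <- avail[[tp]]
      if (length(ids) == 0L) return(NULL)
      v <- mif[ids, tp]
      data.frame(patient_id = patients$patient_id[ids], timepoint = tp,
                 mif_percent = v, ci = grade_of(v))
    }))
    cohort_table(patients, biopsies)
  })
}

mif_at <- function(cohort, tp) {
  b <- cohort$biopsies[cohort$biopsies$timepoint == tp, ]
  stats::setNames(b$mif_percent, b$patient_id)
}

#' Per-timepoint summaries and consecutive-timepoint progression tests
#'
#' For each consecutive timepoint pair both an unpaired comparison on the
#' full cross-sectional samples (two-sample Wilcoxon and Welch t) and a
#' paired comparison on the subset of patients biopsied at both timepoints
#' ([paired_location_test()]) are reported, because longitudinal biopsy
#' cohorts mix overlapping cross-sections with small paired subgroups.
#'
#' @param cohort a `cohort_table` with mif_percent present.
#' @return A `progression_summary`: `summaries` data frame (per timepoint
#'   n/mean/sd for mIF and, when present, ci) and `comparisons` data frame
#'   (pair, unpaired and paired p-values, paired n).
#' @export
progression_analysis <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  b <- cohort$biopsies[!is.na(cohort$biopsies$mif_percent), ]
  present <- TIMEPOINTS[TIMEPOINTS %in% b$timepoint]
  if (length(present) < 2L)
    fq_error("fq_precondition_error", "need >= 2 timepoints with data")
  summaries <- do.call(rbind, lapply(present, function(tp) {
    v <- b$mif_percent[b$timepoint == tp]
    ci <- if ("ci" %in% names(b)) b$ci[b$timepoint == tp] else NA
    data.frame(timepoint = tp, n = length(v), mif_mean = mean(v),
               mif_sd = stats::sd(v),
               ci_mean = mean(ci), ci_sd = stats::sd(ci))
  }))
  comparisons <- NULL
  for (i in seq_len(length(present) - 1L)) {
    a <- present[i]; bb <- present[i + 1L]
    va <- b$mif_percent[b$timepoint == a]
    vb <- b$mif_percent[b$timepoint == bb]
    if (length(va) < 5L || length(vb) < 5L) next
    degen <- stats::sd(c(va, vb)) == 0
    p_w <- if (degen) 1 else
      suppressWarnings(stats::wilcox.test(vb, va)$p.value)
    p_t <- if (degen) 1 else stats::t.test(vb, va)$p.value
    pa <- mif_at(cohort, a); pb <- mif_at(cohort, bb)
    shared <- intersect(names(pa), names(pb))
    paired <- tryCatch(paired_location_test(pa[shared], pb[shared]),
                       fq_error = function(e) NULL)
    comparisons <- rbind(comparisons, data.frame(
      from = a, to = bb,
      p_unpaired_wilcoxon = p_w, p_unpaired_t = p_t,
      n_paired = length(shared),
      p_paired_wilcoxon = if (is.null(paired)) NA_real_ else paired$p_wilcoxon,
      p_paired_t = if (is.null(paired)) NA_real_ else paired$p_paired_t))
  }
  structure(list(summaries = summaries, comparisons = comparisons),
            class = "progression_summary")
}

#' @export
print.progression_summary <- function(x, ...) {
  cat("Per-timepoint mIF:\n")
  print(x$summaries, digits = 3)
  cat("Consecutive comparisons:\n")
  print(x$comparisons, digits = 3)
  invisible(x)
}

#' Pre-registered clinical association fits
#'
#' Simple least-squares fits of each clinical outcome on the fibrosis
#' score: month-12 mIF against recovery time and creatinine increase at
#' month 12 / last follow-up, month-3 mIF against month-12 creatinine
#' increase, and day-3 LDH against recovery time. Patients missing either
#' variable are dropped pairwise; associations with fewer than
#' `min_pairs` complete pairs are skipped with a reason.
#'
#' @param cohort a `cohort_table`.
#' @param min_pairs minimum complete pairs per association (default 10).
#' @return Named list of [ols_simple()] results; skipped associations are
#'   character reasons.
#' @export
association_analysis <- function(cohort, min_pairs = 10L) {
  stopifnot(inherits(cohort, "cohort_table"))
  pts <- cohort$patients
  m12 <- mif_at(cohort, "M12"); m3 <- mif_at(cohort, "M3")
  get_x <- list(
    mif_m12_vs_time_to_recovery = list(m12, "time_to_recovery_days"),
    mif_m12_vs_creatinine_m12 = list(m12, "creatinine_m12"),
    mif_m12_vs_creatinine_last = list(m12, "creatinine_last"),
    mif_m3_vs_creatinine_m12 = list(m3, "creatinine_m12"),
    ldh_d3_vs_time_to_recovery = list(
      if ("ldh_d3" %in% names(pts))
        stats::setNames(pts$ldh_d3, pts$patient_id)
      else stats::setNames(numeric(0), character(0)),
      "time_to_recovery_days"))
  out <- list()
  for (nm in names(get_x)) {
    x <- get_x[[nm]][[1]]
    ycol <- get_x[[nm]][[2]]
    if (!ycol %in% names(pts)) { out[[nm]] <- "outcome column absent"; next }
    y <- stats::setNames(pts[[ycol]], pts$patient_id)
    ids <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
    if (length(ids) < min_pairs) {
      out[[nm]] <- sprintf("skipped: %d complete pairs < %d", length(ids),
                           min_pairs)
      next
    }
    out[[nm]] <- ols_simple(unname(x[ids]), unname(y[ids]))
  }
  out
}
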