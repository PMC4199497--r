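# Group comparisons, multiple-comparison correction, and robust regression
# of network metrics against CRS-R scores.

#' Welch's unequal-variance t-test
#'
#' Unpaired t-test assuming unequal group variances, with
#' Welch-Satterthwaite degrees of freedom. Degenerate input (both groups
#' constant and equal) returns t = 0, p = 1.
#'
#' @param values_a,values_b per-subject metric values for the two groups
#'   (>= 2 finite values each).
#' @param labels optional c(band, metric) labels carried into the result.
#' @return data.frame with columns `t`, `df`, `p` (two-sided), plus labels.
#' @export
welch_ttest <- function(values_a, values_b, labels = NULL) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need >= 2 finite values per group")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      out <- data.frame(t = 0, df = length(values_a) + length(values_b) - 2,
                        p = 1)
    } else stop("zero variance in both groups with unequal means")
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    out <- data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value)
  }
  if (!is.null(labels)) {
    out$band <- labels[1]
    if (length(labels) > 1) out$metric <- labels[2]
  }
  out
}

#' Bonferroni-Holm step-down correction
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order (monotone, >= input,
#'   <= full Bonferroni).
#' @export
holm_correct <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Robust linear regression of a metric against CRS-R
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (MASS::rlm). R^2 is reported as the squared correlation between fitted
#' and observed responses; the slope p-value uses the robust standard error
#' with t on n - 2 degrees of freedom. A perfect linear fit falls back to
#' ordinary least squares (the IRLS scale estimate degenerates at zero
#' residuals).
#'
#' @param x predictor (per-patient network metric).
#' @param y response (CRS-R scores).
#' @param conf_level confidence level for the slope interval.
#' @return data.frame: `slope`, `intercept`, `r_squared`, `p`,
#'   `slope_lo`, `slope_hi`, `n`.
#' @export
robust_regression <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired finite observations")
  if (stats::var(x) == 0) stop("constant predictor: slope undefined")
  ols <- stats::lm(y ~ x)
  if (suppressWarnings(summary(ols)$sigma) < 1e-10) {
    co <- stats::coef(ols)
    return(data.frame(slope = unname(co[2]), intercept = unname(co[1]),
                      r_squared = 1, p = 0, slope_lo = unname(co[2]),
                      slope_hi = unname(co[2]), n = n))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
  co <- summary(fit)$coefficients
  slope <- co["x", "Value"]; se <- co["x", "Std. Error"]
  tval <- slope / se
  df <- n - 2
  p <- 2 * stats::pt(-abs(tval), df)
  ci <- slope + c(-1, 1) * stats::qt(1 - (1 - conf_level) / 2, df) * se
  # squared fitted-observed correlation; 0 when either side is constant
  r2 <- if (stats::var(y) == 0 || stats::var(stats::fitted(fit)) == 0) 0
        else stats::cor(stats::fitted(fit), y)^2
  data.frame(slope = slope, intercept = co["(Intercept)", "Value"],
             r_squared = r2, p = p, slope_lo = ci[1], slope_hi = ci[2], n = n)
}

# Welch test for one metric across bands, Holm-corrected within the metric
# family (correction across frequency bands, never across metrics).
band_family_tests <- function(tbl, value_col, group_col = "is_patient",
                              bands = NULL) {
  bands <- bands %||% unique(tbl$band)
  rows <- lapply(bands, function(b) {
    sub <- tbl[tbl$band == b, ]
    welch_ttest(sub[[value_col]][!sub[[group_col]]],
                sub[[value_col]][sub[[group_col]]],
                labels = c(b, value_col))
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- holm_correct(out$p)
  # sign convention: t > 0 means controls > patients
  out[, c("metric", "band", "t", "df", "p", "p_corrected")]
}

#' Assemble the cohort statistical report
#'
#' Runs the full battery of group analyses on the per-subject tables
#' produced by the pipeline: band power contribution comparisons, mean-dwPLI
#' comparisons, all graph-metric group tests (Holm-corrected within each
#' metric across the analysed bands), within-group NMI tests,
#' relative-to-healthy NMI, robust regressions of alpha network metrics
#' against CRS-R (all patients and MCS-only), and imagery-subgroup
#' comparisons (uncorrected). The t sign convention is controls minus
#' patients.
#'
#' @param results a `cohort_results` object from [run_cohort_pipeline()].
#' @return object of class `cohort_report`, a list of data.frames:
#'   `contribution_tests`, `band_variability_tests`, `dwpli_tests`,
#'   `graph_tests`, `nmi_tests`, `regressions`, `imagery_tests`, plus
#'   `patient_table` (per-patient alpha metrics with CRS-R and
#'   relative-to-healthy NMI) and `notes`.
#' @export
cohort_report <- function(results) {
  stopifnot(inherits(results, "cohort_results"))
  subjects <- results$subjects
  is_pat <- is_patient_group(subjects$group)
  notes <- character(0)
  if (all(is_pat) || !any(is_pat)) {
    notes <- c(notes, "single-group cohort: group tests skipped")
    group_tests_possible <- FALSE
  } else group_tests_possible <- sum(is_pat) >= 2 && sum(!is_pat) >= 2

  # band power contributions (channel-averaged percentages), 5 bands
  contribution_tests <- NULL
  variability_tests <- NULL
  if (group_tests_possible) {
    ct <- results$band_power
    ct$is_patient <- is_pat[match(ct$subject_id, subjects$subject_id)]
    contribution_tests <- band_family_tests(ct, "contribution",
                                            bands = unique(ct$band))
    bv <- results$band_variability
    bv$is_patient <- is_pat[match(bv$subject_id, subjects$subject_id)]
    names(bv)[names(bv) == "variability"] <- "band_variability"
    variability_tests <- band_family_tests(bv, "band_variability",
                                           bands = unique(bv$band))
  }

  # mean dwPLI and graph metrics per band
  gm <- results$graph_metrics
  gm$is_patient <- is_pat[match(gm$subject_id, subjects$subject_id)]
  dwpli_tests <- graph_tests <- NULL
  if (group_tests_possible) {
    dwpli_tests <- band_family_tests(gm, "mean_dwpli")
    metric_cols <- c("clustering", "path_length", "efficiency", "modularity",
                     "participation_sd", "modular_span")
    graph_tests <- do.call(rbind, lapply(metric_cols, function(mc)
      band_family_tests(gm, mc)))
  }

  # within-group NMI: per subject, mean NMI to all other same-group subjects;
  # relative-to-healthy: per patient, mean NMI to all controls
  nmi_tests <- NULL
  rel_nmi <- NULL
  if (!is.null(results$nmi)) {
    nmi_rows <- lapply(names(results$nmi), function(b) {
      M <- results$nmi[[b]]
      idx <- match(subjects$subject_id, rownames(M))
      wg <- vapply(seq_along(idx), function(i) {
        same <- which(is_pat == is_pat[i])
        same <- setdiff(same, i)
        mean(M[idx[i], idx[same]])
      }, numeric(1))
      data.frame(subject_id = subjects$subject_id, band = b,
                 within_group_nmi = wg, stringsAsFactors = FALSE)
    })
    nmi_tbl <- do.call(rbind, nmi_rows)
    if (group_tests_possible) {
      nmi_tbl$is_patient <- is_pat[match(nmi_tbl$subject_id,
                                         subjects$subject_id)]
      nmi_tests <- band_family_tests(nmi_tbl, "within_group_nmi")
    }
    rel_rows <- lapply(names(results$nmi), function(b) {
      M <- results$nmi[[b]]
      ctrl <- subjects$subject_id[!is_pat]
      pats <- subjects$subject_id[is_pat]
      if (!length(ctrl) || !length(pats)) return(NULL)
      data.frame(subject_id = pats, band = b,
                 relative_nmi = rowMeans(M[pats, ctrl, drop = FALSE]),
                 stringsAsFactors = FALSE)
    })
    rel_nmi <- do.call(rbind, rel_rows)
  }

  # per-patient alpha metrics joined with CRS-R for the clinical regressions
  pat <- subjects[is_pat, ]
  alpha_gm <- gm[gm$band == "alpha" & gm$subject_id %in% pat$subject_id, ]
  patient_table <- merge(pat, alpha_gm, by = "subject_id")
  if (!is.null(rel_nmi)) {
    ra <- rel_nmi[rel_nmi$band == "alpha", c("subject_id", "relative_nmi")]
    patient_table <- merge(patient_table, ra, by = "subject_id", all.x = TRUE)
  }
  reg_metrics <- intersect(c("clustering", "path_length", "participation_sd",
                             "modular_span", "relative_nmi", "mean_dwpli"),
                           names(patient_table))
  regressions <- NULL
  if (nrow(patient_table) >= 3) {
    reg_rows <- list()
    for (mc in reg_metrics) {
      for (subset_name in c("all_patients", "MCS_only")) {
        ptab <- if (subset_name == "all_patients") patient_table
                else patient_table[patient_table$group == "MCS", ]
        if (nrow(ptab) < 3 || stats::var(ptab[[mc]]) == 0) next
        rr <- robust_regression(ptab[[mc]], ptab$crs_r)
        rr$metric <- mc; rr$subset <- subset_name
        reg_rows[[paste(mc, subset_name)]] <- rr
      }
    }
    regressions <- do.call(rbind, reg_rows)
    rownames(regressions) <- NULL
  } else notes <- c(notes, "too few patients for CRS-R regressions")

  # imagery subgroup comparisons (uncorrected, as single contrasts)
  imagery_tests <- NULL
  if (any(is_pat) && sum(!is.na(patient_table$imagery)) >= 4) {
    img_rows <- list()
    for (mc in reg_metrics) {
      for (subset_name in c("all_patients", "MCS_only")) {
        ptab <- if (subset_name == "all_patients") patient_table
                else patient_table[patient_table$group == "MCS", ]
        yes <- ptab[[mc]][ptab$imagery %in% TRUE]
        no <- ptab[[mc]][ptab$imagery %in% FALSE]
        if (length(yes) < 2 || length(no) < 2) next
        tt <- welch_ttest(no, yes, labels = c("alpha", mc))
        tt$subset <- subset_name
        img_rows[[paste(mc, subset_name)]] <- tt
      }
    }
    imagery_tests <- do.call(rbind, img_rows)
    if (!is.null(imagery_tests)) rownames(imagery_tests) <- NULL
  }

  structure(list(
    contribution_tests = contribution_tests,
    band_variability_tests = variability_tests,
    dwpli_tests = dwpli_tests,
    graph_tests = graph_tests,
    nmi_tests = nmi_tests,
    relative_nmi = rel_nmi,
    regressions = regressions,
    imagery_tests = imagery_tests,
    patient_table = patient_table,
    notes = notes,
    seed = results$seed
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  if (!is.null(x$graph_tests)) {
    cat("graph-metric group tests (t > 0: controls > patients):\n")
    print(x$graph_tests, digits = 3)
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

fmt_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  paste(utils::capture.output(print(df, row.names = FALSE)), collapse = "\n")
}

#' Write a cohort report as deterministic Markdown
#'
#' Output depends only on the report contents (no timestamps), so identical
#' configuration and seed reproduce identical bytes.
#'
#' @param report a [cohort_report()].
#' @param path output file.
#' @export
write_report_markdown <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  sec <- function(title, df) {
    if (is.null(df)) return(character(0))
    c(paste0("## ", title), "", "```", fmt_table(df), "```", "")
  }
  lines <- c(
    "# Cohort network analysis report", "",
    sprintf("Master seed: %s. t > 0 means controls > patients.",
            report$seed %||% "unset"), "",
    sec("Band power contribution tests", report$contribution_tests),
    sec("Band power temporal variability tests", report$band_variability_tests),
    sec("Mean dwPLI tests", report$dwpli_tests),
    sec("Graph metric tests (Holm-corrected across bands within metric)",
        report$graph_tests),
    sec("Within-group NMI tests", report$nmi_tests),
    sec("Robust regressions of alpha metrics on CRS-R", report$regressions),
    sec("Imagery subgroup comparisons (uncorrected)", report$imagery_tests),
    sec("Per-patient alpha metrics", report$patient_table)
  )
  if (length(report$notes))
    lines <- c(lines, "## Notes", "", paste("-", report$notes), "")
  writeLines(lines, path)
  invisible(path)
}
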