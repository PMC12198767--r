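#' Mixed-model specification
#'
#' Contract for the group-level models: a response column, fixed effects and
#' a random intercept per subject. The special fixed effect
#' `"group_timepoint"` expands to the four-cell factor {control TP1, patient
#' TP1, patient TP2, patient TP3} (group plus timepoint-within-group), whose
#' pairwise contrasts are the comparisons corrected downstream.
#'
#' @param response response column name (e.g. `"r_norm"`).
#' @param fixed_effects character vector of column names and/or
#'   `"group_timepoint"`.
#' @param random_intercept grouping column for the random intercept.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, fixed_effects = "group_timepoint",
                       random_intercept = "subject_id") {
  structure(list(response = response, fixed_effects = fixed_effects,
                 random_intercept = random_intercept),
            class = "model_spec")
}

# Four-cell group/timepoint factor, control reference cell first.
make_cell_factor <- function(table) {
  cell <- paste(table$group, table$timepoint, sep = " ")
  lv <- unique(cell[order(table$group != "control", table$timepoint)])
  factor(cell, levels = lv)
}

#' Fit a linear mixed-effects model with a subject random intercept
#'
#' Estimates the model by REML (lmerTest/lme4 backend), returning the
#' fixed-effect table (estimates, SEs, Satterthwaite dfs, 95% CIs,
#' p-values) and — when the cell factor is in the model — all pairwise cell
#' contrasts with raw p-values, ready for FDR correction.
#'
#' @param table data.frame holding the response, fixed-effect columns and
#'   the subject column.
#' @param spec a [model_spec].
#' @return list with `fit`, `coefficients` (data.frame), `contrasts`
#'   (data.frame or NULL), `anova` (type-III F table).
#' @export
fit_mixed_model <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$response %in% names(table)) {
    stop(sprintf("response `%s` not in table", spec$response), call. = FALSE)
  }
  if (anyNA(table[[spec$response]])) {
    stop("missing values in the response; exclude undefined outcomes first",
         call. = FALSE)
  }
  dat <- table
  fe <- spec$fixed_effects
  if ("group_timepoint" %in% fe) dat$group_timepoint <- make_cell_factor(dat)
  missing_fe <- setdiff(fe, names(dat))
  if (length(missing_fe) > 0) {
    stop(sprintf("fixed effects not in table: %s", paste(missing_fe, collapse = ", ")),
         call. = FALSE)
  }
  # singular (collinear) designs are an input error: name the columns
  mm <- stats::model.matrix(
    stats::reformulate(fe), data = dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop(sprintf("singular fixed-effect design; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    spec$response, "~", paste(fe, collapse = " + "),
    "+ (1 |", spec$random_intercept, ")"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  if (stats::var(dat[[spec$response]]) == 0) {
    # constant response: the mixed model is degenerate; ordinary least
    # squares gives the (exactly determined) coefficients
    fit <- stats::lm(stats::reformulate(fe, response = spec$response), data = dat)
    sm <- as.data.frame(stats::coef(summary(fit)))
    names(sm) <- c("Estimate", "Std. Error", "t value", "Pr(>|t|)")
    sm$df <- stats::df.residual(fit)
  } else {
    fit <- suppressMessages(lmerTest::lmer(fml, data = dat, control = ctrl))
    sm <- as.data.frame(stats::coef(summary(fit)))
  }
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[["Estimate"]],
    std_error = sm[["Std. Error"]], df = sm[["df"]],
    ci_low = sm[["Estimate"]] - stats::qt(0.975, sm[["df"]]) * sm[["Std. Error"]],
    ci_high = sm[["Estimate"]] + stats::qt(0.975, sm[["df"]]) * sm[["Std. Error"]],
    p_value = sm[["Pr(>|t|)"]], row.names = NULL, stringsAsFactors = FALSE)
  contrasts <- NULL
  if ("group_timepoint" %in% fe) {
    emm <- emmeans::emmeans(fit, "group_timepoint",
                            lmer.df = "satterthwaite",
                            lmerTest.limit = 1e6)
    ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
    contrasts <- data.frame(
      contrast = as.character(ct$contrast), estimate = ct$estimate,
      std_error = ct$SE, df = ct$df, t_ratio = ct$t.ratio, p_value = ct$p.value,
      stringsAsFactors = FALSE)
  }
  an <- tryCatch(as.data.frame(stats::anova(fit, type = 3)), error = function(e) NULL)
  list(fit = fit, coefficients = coefs, contrasts = contrasts, anova = an)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1, order-preserving with
#' the input vector).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Balanced-subsample check of the group effect
#'
#' Draws `reps` random subsets of `n_draw` patients (without replacement,
#' independently per replicate), pools each with all controls and refits the
#' group model, summarizing the group fixed effect per replicate. Guards the
#' main comparison against unequal group sizes.
#'
#' @param outcomes outcome rows (e.g. one metric's slice of an
#'   `attack_battery`'s `outcomes`) with columns `subject_id`, `group`,
#'   `timepoint` and the response.
#' @param response response column (default `"r_norm"`).
#' @param n_draw patients per replicate (default 18).
#' @param reps replicates (default 4).
#' @param seed integer seed.
#' @return data.frame with one row per replicate: `replicate`,
#'   `group_estimate`, `std_error`, `p_value`, `patients` (ids,
#'   comma-separated).
#' @export
subsample_balance_check <- function(outcomes, response = "r_norm",
                                    n_draw = 18, reps = 4, seed = 1L) {
  pat_ids <- unique(outcomes$subject_id[outcomes$group == "patient"])
  if (n_draw > length(pat_ids)) {
    stop("`n_draw` exceeds the number of patients", call. = FALSE)
  }
  draws <- with_seed(seed, lapply(seq_len(reps), function(i) sort(sample(pat_ids, n_draw))))
  out <- lapply(seq_len(reps), function(i) {
    keep <- outcomes$group == "control" | outcomes$subject_id %in% draws[[i]]
    dat <- outcomes[keep, , drop = FALSE]
    dat <- dat[!is.na(dat[[response]]), , drop = FALSE]
    dat$is_patient <- as.numeric(dat$group == "patient")
    fml <- stats::as.formula(paste(response, "~ is_patient + (1 | subject_id)"))
    fit <- lmerTest::lmer(fml, data = dat,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
    sm <- stats::coef(summary(fit))
    data.frame(replicate = i, group_estimate = sm["is_patient", "Estimate"],
               std_error = sm["is_patient", "Std. Error"],
               p_value = sm["is_patient", "Pr(>|t|)"],
               patients = paste(draws[[i]], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-way ANOVA of resilience by primary lesion location
#'
#' Outcomes are first averaged across all timepoints and attacks for each
#' patient (each patient has one stroke location), then compared between
#' locations with a classical one-way F test; pairwise comparisons use
#' Bonferroni correction (min(1, m p)). Locations with fewer than 2
#' patients are excluded with a warning; if the aggregated outcomes have
#' zero variance the F statistic is undefined and flagged.
#'
#' @param outcomes outcome rows for one metric with columns `subject_id`,
#'   `group` and the response.
#' @param subjects subject table with `subject_id` and the grouping column.
#' @param response response column (default `"r_norm"`).
#' @param grouping grouping column (default `"lesion_location"`).
#' @return list with `f_statistic`, `df`, `p_value`, `group_means`,
#'   `pairwise` (Bonferroni-adjusted), `excluded_groups`.
#' @export
anova_by_location <- function(outcomes, subjects, response = "r_norm",
                              grouping = "lesion_location") {
  pat <- outcomes[outcomes$group == "patient" & !is.na(outcomes[[response]]), ,
                  drop = FALSE]
  agg <- stats::aggregate(pat[[response]],
                          by = list(subject_id = pat$subject_id), FUN = mean)
  names(agg)[2] <- "value"
  info <- subjects[!duplicated(subjects$subject_id),
                   c("subject_id", grouping), drop = FALSE]
  agg <- merge(agg, info, by = "subject_id")
  agg$location <- factor(agg[[grouping]])
  counts <- table(agg$location)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning(sprintf("excluding locations with < 2 patients: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    agg <- agg[!agg$location %in% small, , drop = FALSE]
    agg$location <- droplevels(agg$location)
  }
  if (nlevels(agg$location) < 2) stop("need >= 2 locations with >= 2 patients", call. = FALSE)
  if (stats::sd(agg$value) == 0) {
    warning("zero variance in aggregated outcomes; F undefined", call. = FALSE)
    return(list(f_statistic = NA_real_, df = c(NA, NA), p_value = NA_real_,
                group_means = tapply(agg$value, agg$location, mean),
                pairwise = NULL, excluded_groups = small))
  }
  fit <- stats::aov(value ~ location, data = agg)
  an <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(agg$value, agg$location,
                               p.adjust.method = "bonferroni", pool.sd = TRUE)
  list(f_statistic = an[["F value"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       p_value = an[["Pr(>F)"]][1],
       group_means = tapply(agg$value, agg$location, mean),
       pairwise = pw$p.value,
       excluded_groups = small)
}

#' Assemble the full analysis report
#'
#' Gathers the study's result structure from the upstream tables: group x
#' timepoint resilience means (with SEM) per metric plus FDR-corrected
#' pairwise cell contrasts, baseline metric means, hub / anti-hub PC
#' summaries, PC-resilience correlations, the patient/lesion factor model
#' coefficient table, and the lesion-location ANOVA. Any missing upstream
#' table raises an error naming it.
#'
#' @param battery an `attack_battery`.
#' @param pc_table from [compute_node_pc()] (optional; hub analyses skipped
#'   if NULL).
#' @param subjects subject table (required for factor models / location
#'   ANOVA on cohorts with patients).
#' @param baseline from [baseline_metrics()] (optional).
#' @param k hub-list length.
#' @param alpha significance level applied to FDR-corrected contrasts.
#' @return an object of class `resilience_report` (a nested list, JSON-ready
#'   via [write_report()]).
#' @export
build_report <- function(battery, pc_table = NULL, subjects = NULL,
                         baseline = NULL, k = 10, alpha = 0.05) {
  if (missing(battery) || is.null(battery)) stop("missing input: battery", call. = FALSE)
  if (!inherits(battery, "attack_battery")) stop("`battery` must be an attack_battery", call. = FALSE)
  outc <- battery$outcomes[!battery$outcomes$undefined, , drop = FALSE]
  if (nrow(outc) == 0) stop("missing input: battery outcomes are empty", call. = FALSE)

  # group x TP means +/- SEM per metric, subject-level means first
  summarize_cells <- function(df, value_col) {
    per_subj <- stats::aggregate(df[[value_col]],
      by = list(subject_id = df$subject_id, group = df$group,
                timepoint = df$timepoint, metric = df$metric), FUN = mean)
    cells <- stats::aggregate(per_subj$x,
      by = list(group = per_subj$group, timepoint = per_subj$timepoint,
                metric = per_subj$metric),
      FUN = function(v) c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                          n = length(v)))
    data.frame(cells[1:3], mean = cells$x[, "mean"], sem = cells$x[, "sem"],
               n = cells$x[, "n"], stringsAsFactors = FALSE)
  }
  resilience_summary <- summarize_cells(outc, "r_norm")

  # mixed model + FDR-corrected pairwise contrasts per metric
  group_models <- lapply(split(outc, outc$metric), function(df) {
    fit <- fit_mixed_model(df, model_spec("r_norm"))
    ct <- fit$contrasts
    ct$p_fdr <- bh_fdr(ct$p_value)
    list(coefficients = fit$coefficients, contrasts = ct, anova = fit$anova)
  })
  n_signif <- sum(vapply(group_models, function(m) sum(m$contrasts$p_fdr < alpha),
                         numeric(1)))

  report <- list(
    normalization = battery$normalization,
    n_outcomes = nrow(outc),
    n_skipped = nrow(battery$skip_log),
    n_undefined = sum(battery$outcomes$undefined),
    resilience_summary = resilience_summary,
    group_models = lapply(group_models, function(m) {
      list(contrasts = m$contrasts)
    }),
    n_fdr_significant_contrasts = n_signif
  )

  if (!is.null(baseline)) {
    report$baseline_summary <- summarize_cells(
      data.frame(baseline, stringsAsFactors = FALSE), "auc")
  }

  if (!is.null(pc_table)) {
    lists <- rank_nodes_by_control_pc(pc_table, k = k,
                                      control_timepoint = battery$control_timepoint)
    report$hub_nodes <- lists$top
    report$anti_hub_nodes <- lists$bottom
    report$pc_summaries <- pc_group_summaries(pc_table, lists)
    if (any(outc$group == "patient")) {
      report$pc_resilience_correlations <-
        pc_resilience_correlations(pc_table, battery, lists)
    }
    pat_pc <- pc_table$pc[pc_table$group == "patient" & pc_table$pc > 0]
    ctl_pc <- pc_table$pc[pc_table$group == "control" & pc_table$pc > 0]
    report$pc_distribution_fit <- list(
      control = if (length(ctl_pc) >= 30) fit_exponentiated_weibull(ctl_pc),
      patient = if (length(pat_pc) >= 30) fit_exponentiated_weibull(pat_pc))
  }

  if (!is.null(subjects) && any(outc$group == "patient") &&
      "lesion_location" %in% names(subjects)) {
    info <- subjects[!duplicated(subjects$subject_id),
                     c("subject_id", "age", "sex", "nihss", "lesion_size",
                       "lesion_type", "lesion_location")]
    factor_models <- lapply(split(outc, outc$metric), function(df) {
      pat <- df[df$group == "patient", , drop = FALSE]
      dat <- merge(pat, info, by = "subject_id")
      dat <- dat[stats::complete.cases(dat[, c("r_norm", "age", "sex", "nihss",
                                               "lesion_size", "lesion_type",
                                               "lesion_location")]), ]
      fe <- c("timepoint", "age", "sex", "nihss",
              "lesion_size", "lesion_type", "lesion_location")
      fe <- fe[vapply(fe, function(col) length(unique(dat[[col]])) > 1, logical(1))]
      tryCatch({
        fit <- fit_mixed_model(dat, model_spec("r_norm", fixed_effects = fe))
        coefs <- fit$coefficients
        coefs$p_fdr <- bh_fdr(coefs$p_value)
        coefs
      }, error = function(e) list(error = conditionMessage(e)))
    })
    report$factor_models <- factor_models
    loc_anova <- lapply(split(outc, outc$metric), function(df) {
      res <- tryCatch(anova_by_location(df, subjects), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      res$group_means <- as.list(res$group_means)
      res$pairwise <- if (!is.null(res$pairwise)) as.data.frame(res$pairwise)
      res
    })
    report$location_anova <- loc_anova
  }

  structure(report, class = c("resilience_report", "list"))
}

#' Write a report as JSON (plus return the path invisibly)
#'
#' @param report a `resilience_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}

#' @exportS3Method base::print
print.resilience_report <- function(x, ...) {
  cat(sprintf("<resilience_report> %d outcomes (%d skipped, %d undefined), %d FDR-significant contrasts\n",
              x$n_outcomes, x$n_skipped, x$n_undefined,
              x$n_fdr_significant_contrasts))
  invisible(x)
}
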