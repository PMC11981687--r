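# Trial normalization, effect sizes, the mixed-effects condition contrast
# and the shared trial-table formats.

#' Normalize a trial to its first control segment
#'
#' Every BFI sample of the trial is multiplied by
#' `100 / median(control_before valid BFI)`, so the normalized first control
#' has median 100 (percent) by construction and any overall scale of the raw
#' BFI cancels.
#'
#' @param traces Named list of the three segment `bfi_trace`s:
#'   `control_before`, `test`, `control_after` (missing segments allowed
#'   except `control_before`).
#' @return List with `traces` (normalized, `bfi` now in percent) and
#'   `record`, a one-row data.frame of per-segment medians of the normalized
#'   BFI.
#' @export
normalize_trial <- function(traces) {
  cb <- traces$control_before
  if (is.null(cb)) stop("control_before segment required")
  m0 <- valid_median(cb$bfi, cb$valid)
  if (!is.finite(m0) || m0 <= 0)
    stop("control_before has no valid samples; trial unusable")
  scale <- 100 / m0
  norm <- lapply(traces, function(tr) {
    tr$bfi <- tr$bfi * scale
    tr
  })
  med <- vapply(norm, function(tr) valid_median(tr$bfi, tr$valid), numeric(1))
  record <- as.data.frame(as.list(stats::setNames(
    med, paste0("rbfi_median_", names(med)))))
  list(traces = norm, record = record)
}

#' Cohen's d effect size
#'
#' `(mean_a - mean_b) / s_pooled` with the pooled standard deviation using
#' n-1 weights.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return Effect size; `NA` when the pooled SD is zero.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  if (sp == 0) return(NA_real_)
  (mean(group_a) - mean(group_b)) / sp
}

#' Linear mixed-effects condition contrast
#'
#' Fits `rbfi ~ Trial + Condition + (Condition | Subject)` with Trial as a
#' categorical per-trial fixed effect, via lme4/lmerTest (Satterthwaite
#' degrees of freedom for the p-value). On a singular random-slope fit the
#' model falls back to a random intercept only, `(1 | Subject)`, with a
#' logged warning.
#'
#' @param table Data.frame with columns `subject_id`, `trial_id`,
#'   `condition`, and the outcome column named by `metric`.
#' @param contrast Character vector of the two condition levels to compare;
#'   the first is the reference.
#' @param metric Outcome column, default `"rbfi_median"`.
#' @return List with `estimate`, `t`, `p` for the condition effect,
#'   `model_type` (`"random_slope"` or `"random_intercept"`), and the fitted
#'   model.
#' @export
lme_contrast <- function(table, contrast = c("control_before", "test"),
                         metric = "rbfi_median") {
  conds <- unique(table$condition)
  if (length(conds) < 2) stop("need at least 2 condition levels")
  if (!all(contrast %in% conds)) stop("contrast levels missing from table")
  d <- table[table$condition %in% contrast, , drop = FALSE]
  d$condition <- factor(d$condition, levels = contrast)
  d$trial_id <- factor(d$trial_id)
  d$subject_id <- factor(d$subject_id)
  d$y <- d[[metric]]
  if (length(unique(d$subject_id)) < 2) stop("need >= 2 subjects")
  fit_one <- function(formula) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = d,
                     control = lme4::lmerControl(check.conv.singular =
                                                   lme4::.makeCC(action = "ignore", tol = 1e-4)))))
  }
  model_type <- "random_slope"
  fit <- tryCatch(fit_one(y ~ trial_id + condition + (condition | subject_id)),
                  error = function(e) NULL)
  # The per-trial fixed intercepts absorb subject-level intercepts, so a zero
  # random-intercept variance is expected and benign; fall back only when the
  # condition-slope variance itself is degenerate (or the fit failed), since
  # the slope term is what carries the repeated-measures structure.
  slope_degenerate <- function(f) {
    vc <- lme4::VarCorr(f)$subject_id
    sds <- attr(vc, "stddev")
    cor <- attr(vc, "correlation")
    sds[2] < 1e-6 * max(sds[1], stats::sd(d$y)) ||
      (is.matrix(cor) && is.finite(cor[1, 2]) && abs(cor[1, 2]) > 0.9999 &&
         sds[1] > 0)
  }
  if (is.null(fit) || slope_degenerate(fit)) {
    model_type <- "random_intercept"
    fit <- fit_one(y ~ trial_id + condition + (1 | subject_id))
    warning("random-slope fit singular or failed; ",
            "fell back to random intercept only")
  }
  cf <- stats::coef(summary(fit))
  row <- grep("^condition", rownames(cf))[1]
  if (is.na(row)) stop("condition effect not estimable (rank deficiency)")
  list(estimate = cf[row, "Estimate"], t = cf[row, "t value"],
       p = cf[row, "Pr(>|t|)"], model_type = model_type, model = fit)
}

#' Per-condition summaries and pairwise effect sizes
#'
#' Medians and quartiles of the metric per condition (midpoint convention),
#' plus pairwise mean differences and Cohen's d for every condition pair.
#' P-values elsewhere in the pipeline are reported raw (uncorrected), with
#' conventional star thresholds 0.05 / 0.01 / 0.001.
#'
#' @param table Trial table with `condition` and the metric column.
#' @param metric Column to summarize, default `"rbfi_median"`.
#' @return List with `per_condition` (n, median, q25, q75) and `pairwise`
#'   (mean differences and Cohen's d).
#' @export
condition_summary <- function(table, metric = "rbfi_median") {
  y <- table[[metric]]
  conds <- unique(table$condition)
  if (any(!table$condition %in% conds) || !length(conds))
    stop("empty condition column")
  per <- do.call(rbind, lapply(conds, function(cc) {
    v <- y[table$condition == cc]
    if (!length(v)) stop("empty condition: ", cc)
    data.frame(condition = cc, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  pairs <- utils::combn(as.character(conds), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- y[table$condition == pr[1]]; b <- y[table$condition == pr[2]]
    data.frame(a = pr[1], b = pr[2],
               mean_difference = mean(b) - mean(a),
               cohens_d = if (length(a) >= 2 && length(b) >= 2)
                 cohens_d(b, a) else NA_real_)
  }))
  list(per_condition = per, pairwise = pw)
}

#' Simulate a synthetic cohort trial table
#'
#' Generates the per-trial normalized-BFI medians of a paired study: each
#' trial contributes one row per condition, with a per-trial intercept, a
#' per-subject random condition slope, and residual noise, around a control
#' level of 100 percent. Defaults emulate the study regime (15 subjects,
#' about 2-3 trials each, and condition effects on the order of a 12 percent
#' increase for a cognitive activation or -50/-75 percent for a flow
#' suppression).
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Maximum trials per subject; each subject gets
#'   between 2 and this many (time constraints leave some subjects short).
#' @param conditions Condition labels; the first is the reference.
#' @param effects Named or positional additive condition effects (percentage
#'   points) for conditions after the first.
#' @param sd_trial SD of per-trial intercepts.
#' @param sd_slope SD of per-subject random condition slopes.
#' @param sd_resid Residual SD.
#' @param seed Integer seed.
#' @return A trial table data.frame (`subject_id`, `trial_id`, `condition`,
#'   `rbfi_median`).
#' @export
simulate_trial_table <- function(n_subjects = 15, trials_per_subject = 3,
                                 conditions = c("control_before", "test"),
                                 effects = 12,
                                 sd_trial = 6, sd_slope = 3, sd_resid = 5,
                                 seed = 1L) {
  stopifnot(length(effects) == length(conditions) - 1)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      slope <- stats::rnorm(length(effects), 0, sd_slope)
      n_tr <- sample(2:trials_per_subject, 1)
      for (tr in seq_len(n_tr)) {
        intercept <- 100 + stats::rnorm(1, 0, sd_trial)
        y <- intercept + c(0, effects + slope) +
          stats::rnorm(length(conditions), 0, sd_resid)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%02d", s),
          trial_id = sprintf("S%02d_T%d", s, tr),
          condition = conditions, rbfi_median = y)
      }
    }
    do.call(rbind, rows)
  })
}

#' Write / read a trial table CSV
#'
#' Long-format CSV with one row per trial and condition:
#' `subject_id, trial_id, condition, rbfi_median, pi, pulse_rate_hz,
#' n_bar_sp, n_bar_de` (metric columns beyond the first are optional).
#'
#' @param table Trial table data.frame.
#' @param path CSV path.
#' @export
write_trial_table <- function(table, path) {
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  as.data.frame(data.table::fread(path))
}
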