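#' Construct an interval classification rule
#'
#' A disease call requires the beta-F1/LDH-A ratio to fall inside a closed
#' interval and one additional marker to fall inside a second closed
#' interval.
#'
#' @param disease Disease the rule calls.
#' @param ratio_interval Numeric `c(lo, hi)` on `bf1_over_ldha`.
#' @param extra_marker Name of the additional marker column.
#' @param extra_interval Numeric `c(lo, hi)` on the additional marker.
#' @param printed_sensitivity Optional published sensitivity (%) carried as
#'   metadata.
#' @return Object of class `range_rule`.
#' @export
range_rule <- function(disease, ratio_interval, extra_marker, extra_interval,
                       printed_sensitivity = NA_real_) {
  chk <- function(iv, what) {
    if (length(iv) != 2L || anyNA(iv) || iv[1] > iv[2])
      stop(what, " must be c(lo, hi) with lo <= hi")
    as.numeric(iv)
  }
  structure(
    list(disease = as.character(disease),
         ratio_interval = chk(ratio_interval, "'ratio_interval'"),
         extra_marker = as.character(extra_marker),
         extra_interval = chk(extra_interval, "'extra_interval'"),
         printed_sensitivity = printed_sensitivity),
    class = "range_rule"
  )
}

#' @export
print.range_rule <- function(x, ...) {
  cat(sprintf("%s: bf1_over_ldha in [%.2g, %.2g] AND %s in [%.2g, %.2g]\n",
              x$disease, x$ratio_interval[1], x$ratio_interval[2],
              x$extra_marker, x$extra_interval[1], x$extra_interval[2]))
  invisible(x)
}

in_closed <- function(x, iv) x >= iv[1] & x <= iv[2]

#' Apply an interval rule to one sample
#'
#' @param sample Named list / one-row data frame with a `bf1_over_ldha` value
#'   and the rule's additional marker.
#' @param rule A [range_rule()].
#' @return `TRUE` if both values fall inside their closed intervals, `FALSE`
#'   otherwise, `NA` if either value is missing (the sample must then be
#'   excluded, not silently dropped).
#' @export
apply_rule <- function(sample, rule) {
  stopifnot(inherits(rule, "range_rule"))
  need <- c("bf1_over_ldha", rule$extra_marker)
  absent <- setdiff(need, names(sample))
  if (length(absent) > 0L)
    stop("sample lacks value(s): ", paste(absent, collapse = ", "))
  ratio <- sample[["bf1_over_ldha"]]
  extra <- sample[[rule$extra_marker]]
  if (is.na(ratio) || is.na(extra)) return(NA)
  in_closed(ratio, rule$ratio_interval) && in_closed(extra, rule$extra_interval)
}

#' Classification-rate sensitivity from confusion counts
#'
#' The panel's published sensitivity convention is the classification rate of
#' true positives among all rule-positive samples,
#' `100 * TP / (TP + FP)` (elsewhere called precision).  The conventional
#' recall `100 * TP / (TP + FN)` is available from [evaluate_panel()] under
#' the name `recall_percent`.
#'
#' @param counts List/data frame with integers `tp` and `fp`.
#' @return Sensitivity in percent; `NA` with a warning when no sample is
#'   rule-positive.
#' @export
rule_sensitivity <- function(counts) {
  tp <- counts$tp; fp <- counts$fp
  if (tp + fp == 0) {
    warning("no rule-positive samples: sensitivity undefined")
    return(NA_real_)
  }
  100 * tp / (tp + fp)
}

#' Evaluate interval rules against a cohort
#'
#' A sample is rule-positive when it satisfies any of the supplied rules.
#' Target-class positives count as TP, positives of any other class as FP;
#' non-matching target samples are FN and the rest TN.  Samples with missing
#' required values are excluded and tallied.
#'
#' @param expr Expression matrix (fold-of-control scale) containing
#'   `bf1_over_ldha` and the rules' additional markers.
#' @param rules A [range_rule()] or list of them (non-empty).
#' @param target_class Class treated as positive.
#' @param fp_classes Which other classes can contribute false positives:
#'   `"all"` (default) or `"controls_only"` with `control_label`.
#' @param control_label Control class label (used by `"controls_only"`).
#' @return List `counts` (`tp`, `fp`, `fn`, `tn`, `excluded`),
#'   `sensitivity_percent` (TP / (TP + FP) convention) and `recall_percent`
#'   (TP / (TP + FN)).
#' @export
evaluate_panel <- function(expr, rules, target_class,
                           fp_classes = c("all", "controls_only"),
                           control_label = "CTR") {
  fp_classes <- match.arg(fp_classes)
  if (inherits(rules, "range_rule")) rules <- list(rules)
  if (!is.list(rules) || length(rules) == 0L)
    stop("'rules' must be a non-empty list of range_rule objects")
  if (!target_class %in% expr$class_label)
    stop("target class '", target_class, "' absent from the cohort")
  if (all(expr$class_label == target_class))
    stop("cohort must contain at least one non-target class")
  keep <- if (fp_classes == "all") rep(TRUE, nrow(expr))
          else expr$class_label %in% c(target_class, control_label)
  sub <- expr[keep, , drop = FALSE]
  match_one <- vapply(seq_len(nrow(sub)), function(i) {
    hits <- vapply(rules, function(r) apply_rule(sub[i, ], r), logical(1))
    if (anyNA(hits) && !any(hits, na.rm = TRUE)) NA else any(hits, na.rm = TRUE)
  }, logical(1))
  excluded <- sum(is.na(match_one))
  ok <- !is.na(match_one)
  pos <- match_one[ok]
  is_target <- sub$class_label[ok] == target_class
  counts <- list(tp = sum(pos & is_target), fp = sum(pos & !is_target),
                 fn = sum(!pos & is_target), tn = sum(!pos & !is_target),
                 excluded = excluded)
  sens <- if (counts$tp + counts$fp > 0) 100 * counts$tp / (counts$tp + counts$fp)
          else NA_real_
  recall <- if (counts$tp + counts$fn > 0) 100 * counts$tp / (counts$tp + counts$fn)
            else NA_real_
  list(counts = counts, sensitivity_percent = sens, recall_percent = recall)
}

#' Repeated interval-rule evaluation on simulated cohorts
#'
#' Draws target-class samples uniformly inside the rule's two intervals and
#' control samples from the packaged control distribution (mean 1, SEM 0.1,
#' n = 20; per-sample SD = SEM * sqrt(n), censored at 0) for both required
#' values, evaluates the rule, and averages the TP / (TP + FP) sensitivity
#' over replicates.
#'
#' @param rule A [range_rule()]; default the DMD rule of [diagnostic_rules()].
#' @param reps Number of replicates (default 200).
#' @param seed Master seed.
#' @param n_target,n_control Samples per replicate (defaults 6 and 20).
#' @param control_mean,control_sem,control_n Parameters of the control
#'   distribution (defaults 1.0, 0.1, 20).
#' @return List `mean_sensitivity` (%), `sensitivities` (per replicate),
#'   `reps`.
#' @export
interval_rule_benchmark <- function(rule = diagnostic_rules()$DMD, reps = 200,
                                    seed = 1L, n_target = 6L, n_control = 20L,
                                    control_mean = 1.0, control_sem = 0.1,
                                    control_n = 20L) {
  stopifnot(inherits(rule, "range_rule"))
  sd0 <- sem_to_sd(control_sem, control_n)
  sims <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      ratio_t <- stats::runif(n_target, rule$ratio_interval[1],
                              rule$ratio_interval[2])
      extra_t <- stats::runif(n_target, rule$extra_interval[1],
                              rule$extra_interval[2])
      ratio_c <- pmax(stats::rnorm(n_control, control_mean, sd0), 0)
      extra_c <- pmax(stats::rnorm(n_control, control_mean, sd0), 0)
      expr <- data.frame(
        sample_id = sprintf("s%02d", seq_len(n_target + n_control)),
        class_label = rep(c(rule$disease, "CTR"), c(n_target, n_control)),
        bf1_over_ldha = c(ratio_t, ratio_c),
        stringsAsFactors = FALSE
      )
      expr[[rule$extra_marker]] <- c(extra_t, extra_c)
      evaluate_panel(expr, rule, rule$disease)$sensitivity_percent
    }, numeric(1))
  })
  list(mean_sensitivity = mean(sims), sensitivities = sims, reps = reps)
}
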