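#' Two-tailed Student's t test (pooled variance)
#'
#' Classical equal-variance t test with `df = n_x + n_y - 2`.  Degenerate
#' inputs (zero pooled variance) are resolved deterministically: equal means
#' give `t = 0, p = 1`; unequal means give `p = 0` with a degenerate flag.
#'
#' @param x,y Numeric sample vectors (>= 2 values each).
#' @return List `t_statistic`, `df`, `p_value`, `degenerate`.
#' @examples
#' student_t_two_tailed(c(1, 2, 3), c(2, 3, 4))
#' @export
student_t_two_tailed <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y))
      return(list(t_statistic = 0, df = df, p_value = 1, degenerate = FALSE))
    return(list(t_statistic = sign(mean(x) - mean(y)) * Inf, df = df,
                p_value = 0, degenerate = TRUE))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t_statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List `F`, `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (stats::var(values) == 0)
    return(list(F = 0, df1 = length(groups) - 1L,
                df2 = length(values) - length(groups), p_value = 1))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p_value = unname(fit$p.value))
}

#' Dunnett's many-to-one comparisons against a control
#'
#' Pooled-variance t statistics of each treatment group against the control,
#' with familywise-adjusted p values obtained by Monte-Carlo integration of
#' the null distribution of the maximum absolute statistic over the
#' correlated comparison family.  Simulation of the null draws group-mean
#' deviates with the observed (possibly unbalanced) group sizes and a shared
#' chi-square variance estimate, so no balanced-design table is assumed.
#'
#' @param groups Named list of treatment-group sample vectors.
#' @param control Control-group sample vector.
#' @param mc_draws Monte-Carlo draws for the adjustment (default 1e5; fewer
#'   than 1000 triggers a warning).
#' @param seed Integer seed for the Monte-Carlo draws (global RNG untouched).
#' @return Data frame with one row per treatment group: `comparison`,
#'   `t_statistic`, `df`, `p_value` (raw two-tailed), `p_adjusted`
#'   (familywise), `significance_tier` (`ns`, `p<0.05`, `p<0.001`).
#' @export
dunnett_many_to_one <- function(groups, control, mc_draws = 1e5, seed = 1L) {
  if (!is.list(groups) || length(groups) < 1L)
    stop("need at least one treatment group")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (mc_draws < 1000)
    warning("mc_draws < 1000: adjusted p values will be unstable")
  sizes <- lengths(groups); n0 <- length(control)
  if (any(sizes < 2L) || n0 < 2L) stop("every group needs >= 2 values")
  k <- length(groups)
  N <- sum(sizes) + n0
  df <- N - (k + 1L)
  if (df < 1L) stop("pooled residual degrees of freedom must be >= 1")
  all_groups <- c(groups, list(control))
  s2 <- sum(vapply(all_groups, function(g) (length(g) - 1) * stats::var(g),
                   numeric(1))) / df
  m0 <- mean(control)
  tstat <- vapply(seq_len(k), function(i) {
    (mean(groups[[i]]) - m0) / sqrt(s2 * (1 / sizes[i] + 1 / n0))
  }, numeric(1))
  p_raw <- 2 * stats::pt(-abs(tstat), df)

  # MC null: group means ~ N(0, 1/n), shared variance ~ chi2_df / df
  max_null <- withr::with_seed(seed, {
    z0 <- stats::rnorm(mc_draws) / sqrt(n0)
    v <- stats::rchisq(mc_draws, df) / df
    tmat <- vapply(seq_len(k), function(i) {
      zi <- stats::rnorm(mc_draws) / sqrt(sizes[i])
      abs(zi - z0) / sqrt(v * (1 / sizes[i] + 1 / n0))
    }, numeric(mc_draws))
    if (k == 1L) as.numeric(tmat) else apply(tmat, 1L, max)
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(max_null >= t0), numeric(1))
  p_adj <- pmax(p_adj, p_raw) # a familywise adjustment can never help
  data.frame(
    comparison = paste0(names(groups), " vs control"),
    t_statistic = tstat, df = df, p_value = p_raw, p_adjusted = p_adj,
    significance_tier = significance_tier(p_adj),
    stringsAsFactors = FALSE
  )
}

significance_tier <- function(p) {
  ifelse(p < 0.001, "p<0.001", ifelse(p < 0.05, "p<0.05", "ns"))
}

#' Per-marker group comparisons against the control class
#'
#' Runs, for every marker column, either Dunnett's many-to-one test across
#' all non-control classes (default) or plain pairwise Student's t tests.
#'
#' @param expr Expression matrix with class labels.
#' @param control_label Reference class.
#' @param method `"dunnett"` or `"t"`.  Pairwise t-test p values are reported
#'   unadjusted (`p_adjusted = p_value`).
#' @param mc_draws,seed Passed to [dunnett_many_to_one()].
#' @return Data frame with one row per marker x treatment group.
#' @export
test_markers <- function(expr, control_label = "CTR",
                         method = c("dunnett", "t"),
                         mc_draws = 2e4, seed = 1L) {
  method <- match.arg(method)
  ctrl <- expr$class_label == control_label
  if (!any(ctrl)) stop("no samples with control label '", control_label, "'")
  classes <- setdiff(unique(expr$class_label), control_label)
  if (length(classes) == 0L) stop("no treatment classes to compare")
  out <- lapply(expr_markers(expr), function(m) {
    groups <- lapply(classes, function(cl) expr[[m]][expr$class_label == cl])
    names(groups) <- classes
    if (method == "dunnett") {
      res <- dunnett_many_to_one(groups, expr[[m]][ctrl],
                                 mc_draws = mc_draws, seed = seed)
    } else {
      res <- do.call(rbind, lapply(classes, function(cl) {
        tt <- student_t_two_tailed(groups[[cl]], expr[[m]][ctrl])
        data.frame(comparison = paste0(cl, " vs control"),
                   t_statistic = tt$t_statistic, df = tt$df,
                   p_value = tt$p_value, p_adjusted = tt$p_value,
                   significance_tier = significance_tier(tt$p_value),
                   stringsAsFactors = FALSE)
      }))
    }
    cbind(marker = m, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
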