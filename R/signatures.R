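#' Normalize an expression matrix to fold of control
#'
#' Divides every marker column by the mean of the control-group samples for
#' that marker, so the control group averages exactly 1.0 per marker.
#'
#' @param expr Expression matrix (`sample_id`, `class_label`, marker columns).
#' @param control_label Class label of the reference group.
#' @return The normalized matrix, attribute `units = "fold_of_control"`.
#'   Markers whose control mean is not positive are set to `NA` and listed in
#'   the `unnormalizable` attribute.
#' @export
fold_of_control <- function(expr, control_label = "CTR") {
  ctrl <- expr$class_label == control_label
  if (!any(ctrl))
    stop("no samples with control label '", control_label, "'")
  bad <- character(0)
  for (m in expr_markers(expr)) {
    cm <- mean(expr[[m]][ctrl])
    if (is.na(cm) || cm <= 0) {
      warning("marker '", m, "' has non-positive control mean; flagged unnormalizable")
      expr[[m]] <- NA_real_
      bad <- c(bad, m)
    } else {
      expr[[m]] <- expr[[m]] / cm
    }
  }
  attr(expr, "units") <- "fold_of_control"
  attr(expr, "unnormalizable") <- bad
  expr
}

#' Log2 expression relative to the control-group mean
#'
#' Computes `log2(max(value, floor) / control mean)` per marker, the input
#' representation used for expression-profile clustering.  The floor keeps
#' truly absent markers (e.g. myophosphorylase in glycogenosis type V, fold
#' exactly 0) finite and clusterable.
#'
#' @inheritParams fold_of_control
#' @param floor Positive lower bound applied before taking logs
#'   (default 0.01 fold).
#' @return Matrix of log2 ratios, attribute `units = "log2_relative"`.
#' @export
log2_relative <- function(expr, control_label = "CTR", floor = 0.01) {
  if (floor <= 0) stop("'floor' must be positive")
  ctrl <- expr$class_label == control_label
  if (!any(ctrl))
    stop("no samples with control label '", control_label, "'")
  for (m in expr_markers(expr)) {
    cm <- mean(expr[[m]][ctrl])
    if (is.na(cm) || cm <= 0)
      stop("marker '", m, "' has non-positive control mean")
    expr[[m]] <- log2(pmax(expr[[m]], floor) / cm)
  }
  attr(expr, "units") <- "log2_relative"
  expr
}

#' Bioenergetic-signature ratios per sample
#'
#' Computes, for every sample, the BEC index `(bF1 / Hsp60) / GAPDH` (ATP
#' synthase normalized by mitochondrial mass, relative to glycolytic
#' potential), `bF1 / GAPDH`, and `bF1 / LDHA`.  Zero denominators yield `NA`
#' (missing), never infinities.
#'
#' @param expr Expression matrix containing marker columns `bF1`, `Hsp60`,
#'   `GAPDH` and `LDHA`.
#' @return Data frame `sample_id`, `class_label`, `bec_index`,
#'   `bf1_over_gapdh`, `bf1_over_ldha`.
#' @export
compute_signatures <- function(expr) {
  need <- c("bF1", "Hsp60", "GAPDH", "LDHA")
  missing_mk <- setdiff(need, names(expr))
  if (length(missing_mk) > 0L)
    stop("expression matrix lacks required marker(s): ",
         paste(missing_mk, collapse = ", "))
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  data.frame(
    sample_id      = expr$sample_id,
    class_label    = expr$class_label,
    bec_index      = safe_div(safe_div(expr$bF1, expr$Hsp60), expr$GAPDH),
    bf1_over_gapdh = safe_div(expr$bF1, expr$GAPDH),
    bf1_over_ldha  = safe_div(expr$bF1, expr$LDHA),
    stringsAsFactors = FALSE
  )
}

#' Append signature ratio columns to an expression matrix
#'
#' @inheritParams compute_signatures
#' @return `expr` with the three ratio columns of [compute_signatures()]
#'   appended; units attribute preserved.
#' @export
add_signatures <- function(expr) {
  sig <- compute_signatures(expr)
  units <- attr(expr, "units")
  out <- cbind(expr, sig[, signature_ratios()])
  attr(out, "units") <- units
  out
}
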