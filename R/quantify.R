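#' Background fluorescence of an array from its blank spots
#'
#' @param table A spot table (see [simulate_spot_table()] for the dialect).
#' @param marker Marker whose blank spots are averaged.
#' @param fallback_zero If `TRUE`, a marker without blank spots gets
#'   background 0 instead of an error.
#' @return Mean intensity of the marker's blank (BSA) spots.
#' @export
blank_level <- function(table, marker, fallback_zero = FALSE) {
  b <- table$intensity[table$marker == marker & table$content_type == "blank"]
  if (length(b) == 0L) {
    if (isTRUE(fallback_zero)) return(0)
    stop("no blank spots for marker '", marker,
         "' (set fallback_zero = TRUE to assume zero background)")
  }
  mean(b)
}

#' Aggregate replicate spot intensities
#'
#' Collapses the replicate spots of one sample into a single intensity and
#' reports the replicate coefficient of variation
#' (`scv_percent = sd * 100 / |mean|`, the array's technical-variance
#' statistic).
#'
#' @param intensities Nonnegative replicate intensities (>= 1 value).
#' @param method Aggregation statistic, `"mean"` (default) or `"median"`.
#' @return List with elements `mean` (the aggregate, whatever the method) and
#'   `scv_percent` (`NA` for a single replicate or an all-zero group, where
#'   the statistic is undefined).
#' @examples
#' aggregate_replicates(c(90, 100, 110, 100))
#' @export
aggregate_replicates <- function(intensities, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(intensities) < 1L) stop("need at least one intensity")
  m <- if (method == "mean") mean(intensities) else stats::median(intensities)
  scv <- if (length(intensities) < 2L || m == 0) NA_real_
         else stats::sd(intensities) * 100 / abs(m)
  list(mean = m, scv_percent = scv)
}

#' Fit a linear standard curve to a dilution series
#'
#' Ordinary least-squares fit (with intercept) of fluorescence intensity on
#' nominal concentration.  A non-positive slope marks the curve unusable.
#'
#' @param concentrations Nominal concentrations (>= 2 distinct values,
#'   >= 3 points in total).
#' @param intensities Observed intensities, same length.
#' @param marker Marker name carried along for diagnostics.
#' @return An object of class `standard_curve` with fields `marker`, `slope`,
#'   `intercept`, `r_squared`, `n_points`, `usable`.
#' @export
fit_standard_curve <- function(concentrations, intensities, marker = "") {
  if (length(concentrations) != length(intensities))
    stop("concentration and intensity vectors differ in length")
  if (length(concentrations) < 3L) stop("need at least 3 standard points")
  if (length(unique(concentrations)) < 2L)
    stop("singular fit: all standard concentrations are equal (marker '",
         marker, "')")
  fit <- stats::lm(intensities ~ concentrations)
  cf <- stats::coef(fit)
  ss_tot <- sum((intensities - mean(intensities))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(marker = marker, slope = unname(cf[2]), intercept = unname(cf[1]),
         r_squared = r2, n_points = length(concentrations),
         usable = unname(cf[2]) > 0),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve [%s]: intensity = %.4g * conc + %.4g (r2 = %.4f, n = %d)%s\n",
              x$marker, x$slope, x$intercept, x$r_squared, x$n_points,
              if (x$usable) "" else " [UNUSABLE: slope <= 0]"))
  invisible(x)
}

#' Convert a mean spot intensity into a calibrated protein amount
#'
#' Inverts the standard curve: `amount = (mean_intensity - intercept) / slope`.
#' The blank background cancels because the 0-concentration standard carries
#' the same background as the sample spots; `background` is accepted for
#' interface completeness and diagnostics only.  Amounts below 0 are clamped
#' to 0 and flagged as below background ("not detected").
#'
#' @param mean_intensity Aggregated spot intensity (vectorized).
#' @param curve A usable [fit_standard_curve()] result.
#' @param background Blank level, unused by the inversion (see above).
#' @return Numeric vector of amounts (arbitrary units of expressed protein
#'   per ng of total protein) with logical attribute `below_background`.
#' @export
calibrate <- function(mean_intensity, curve, background = 0) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$usable)
    stop("standard curve for marker '", curve$marker,
         "' is unusable (slope <= 0)")
  amount <- (mean_intensity - curve$intercept) / curve$slope
  below <- amount < 0
  amount[below] <- 0
  attr(amount, "below_background") <- below
  amount
}

#' Quantify a full spot table
#'
#' Per marker: estimates the blank background, fits the standard curve on the
#' dilution series, aggregates each sample's replicate spots, and calibrates
#' the aggregate intensity into a protein amount.  Also reports the
#' array-level technical variance as the mean replicate CV over all sample
#' spot groups.
#'
#' @param table A spot table.
#' @param method Replicate aggregation statistic (`"mean"` or `"median"`).
#' @param blank_fallback_zero Passed to [blank_level()].
#' @return An object of class `quantified_table`: list with `samples` (data
#'   frame `sample_id, class_label, marker, mean_intensity, scv_percent,
#'   amount, below_background`), `curves`, `blanks`, and
#'   `array_scv_percent`.
#' @export
quantify_table <- function(table, method = "mean", blank_fallback_zero = FALSE) {
  required <- c("marker", "content_type", "sample_id", "intensity")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L)
    stop("spot table lacks column(s): ", paste(missing_cols, collapse = ", "))
  empty <- data.frame(sample_id = character(), class_label = character(),
                      marker = character(), mean_intensity = numeric(),
                      scv_percent = numeric(), amount = numeric(),
                      below_background = logical(), stringsAsFactors = FALSE)
  if (nrow(table) == 0L)
    return(structure(list(samples = empty, curves = list(),
                          blanks = numeric(0), array_scv_percent = NA_real_),
                     class = "quantified_table"))
  markers <- unique(table$marker)
  curves <- list(); blanks <- numeric(0); rows <- list()
  for (m in markers) {
    sub <- table[table$marker == m, ]
    std <- sub[sub$content_type == "standard", ]
    if (nrow(std) == 0L)
      stop("no standard spots for marker '", m, "'")
    bg <- blank_level(table, m, fallback_zero = blank_fallback_zero)
    curve <- fit_standard_curve(std$nominal_concentration, std$intensity, m)
    if (!curve$usable)
      stop("unusable standard curve (slope <= 0) for marker '", m, "'")
    blanks[m] <- bg
    curves[[m]] <- curve
    smp <- sub[sub$content_type == "sample", ]
    if (nrow(smp) == 0L) next
    per_sample <- split(smp, factor(smp$sample_id, levels = unique(smp$sample_id)))
    agg <- lapply(per_sample, function(s) {
      a <- aggregate_replicates(s$intensity, method = method)
      data.frame(sample_id = s$sample_id[1], class_label = s$class_label[1],
                 marker = m, mean_intensity = a$mean,
                 scv_percent = a$scv_percent, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, c(agg, make.row.names = FALSE))
    amt <- calibrate(block$mean_intensity, curve, bg)
    block$amount <- as.numeric(amt)
    block$below_background <- attr(amt, "below_background")
    rows[[m]] <- block
  }
  samples <- if (length(rows) > 0L)
    do.call(rbind, c(rows, make.row.names = FALSE)) else empty
  structure(
    list(samples = samples, curves = curves, blanks = blanks,
         array_scv_percent = if (nrow(samples) > 0L)
           mean(samples$scv_percent, na.rm = TRUE) else NA_real_),
    class = "quantified_table"
  )
}

#' Reshape quantified samples into a wide expression matrix
#'
#' @param q A [quantify_table()] result.
#' @return Expression matrix (`sample_id`, `class_label`, one column per
#'   marker) in calibrated units.
#' @export
as_expression_matrix <- function(q) {
  stopifnot(inherits(q, "quantified_table"))
  s <- q$samples
  ids <- unique(s[, c("sample_id", "class_label")])
  markers <- unique(s$marker)
  out <- ids
  for (m in markers) {
    sub <- s[s$marker == m, ]
    out[[m]] <- sub$amount[match(ids$sample_id, sub$sample_id)]
  }
  rownames(out) <- NULL
  attr(out, "units") <- "calibrated"
  out
}
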