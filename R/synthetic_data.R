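#' Reconstruct a per-sample standard deviation from a standard error
#'
#' Published group summaries report mean +/- SEM; the per-sample spread needed
#' for simulation is SD = SEM * sqrt(n).
#'
#' @param sem Nonnegative standard error of the mean.
#' @param n Group size (>= 1).
#' @return The implied per-sample standard deviation.
#' @examples
#' sem_to_sd(0.1, 20) # 0.4472
#' @export
sem_to_sd <- function(sem, n) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(sem < 0)) stop("'sem' must be nonnegative")
  sem * sqrt(n)
}

#' Simulate a cohort expression matrix from group summary statistics
#'
#' For each group and marker, draws `n` values from a normal distribution with
#' the group mean and SD = SEM * sqrt(n), censored below at
#' `spec$value_floor`: draws falling under the floor are set to the floor
#' rather than redrawn, so a cell specified as 0 +/- 0 stays exactly 0 and the
#' moments of weakly-truncated cells stay close to their targets.
#'
#' @param spec A [cohort_spec()].
#' @param markers Optional character vector restricting the simulated columns
#'   (default: all markers of the first group).  Every group must supply
#'   parameters for every requested marker.
#' @return An expression matrix: data frame with columns `sample_id`,
#'   `class_label` and one numeric column per marker, with attribute
#'   `units = "fold_of_control"`.
#' @examples
#' spec <- cohort_spec(reference_groups(c("CTR", "GlycV")), seed = 1)
#' expr <- simulate_cohort(spec, markers = c("PYGM", "NADHs9"))
#' all(expr$PYGM[expr$class_label == "GlycV"] == 0)
#' @export
simulate_cohort <- function(spec, markers = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(markers)) markers <- spec$groups[[1]]$per_marker$marker
  withr::with_seed(spec$seed, {
    blocks <- lapply(spec$groups, function(g) {
      vals <- vapply(markers, function(m) {
        i <- match(m, g$per_marker$marker)
        if (is.na(i))
          stop("group '", g$group_name, "' supplies no parameters for marker '",
               m, "'")
        mu <- g$per_marker$mean_fold[i]
        sdv <- sem_to_sd(g$per_marker$sem[i], g$n)
        pmax(stats::rnorm(g$n, mu, sdv), spec$value_floor)
      }, numeric(g$n))
      vals <- matrix(vals, nrow = g$n,
                     dimnames = list(NULL, markers)) # guard n = 1 drop
      data.frame(
        sample_id   = sprintf("%s_%02d", g$group_name, seq_len(g$n)),
        class_label = g$group_name,
        vals,
        stringsAsFactors = FALSE, check.names = FALSE
      )
    })
    out <- do.call(rbind, c(blocks, make.row.names = FALSE))
    attr(out, "units") <- "fold_of_control"
    out
  })
}

#' Describe the geometry and noise of a printed array
#'
#' @param replicates_per_sample Spots printed per sample per marker
#'   (default 4, matching quadruplicate printing).
#' @param standard_concentrations Nominal concentrations (ug/ul) of the
#'   serial-dilution standard series; must contain 0 and its maximum.
#'   Default: six evenly spaced points on \[0, 1\].
#' @param n_blank_spots BSA negative-control spots per marker (default 4).
#' @param technical_cv_percent Coefficient of variation (%) of the
#'   multiplicative spot-level technical noise; default 8.6, the replicate
#'   variability typical of the assay.
#' @param seed Integer seed for spot-noise generation.
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(replicates_per_sample = 4L,
                         standard_concentrations = seq(0, 1, length.out = 6),
                         n_blank_spots = 4L,
                         technical_cv_percent = 8.6,
                         seed = 1L) {
  if (replicates_per_sample < 1L) stop("'replicates_per_sample' must be >= 1")
  if (technical_cv_percent < 0) stop("'technical_cv_percent' must be >= 0")
  if (any(standard_concentrations < 0))
    stop("standard concentrations must be nonnegative")
  if (!(0 %in% standard_concentrations))
    stop("standard series must contain concentration 0")
  structure(
    list(replicates_per_sample = as.integer(replicates_per_sample),
         standard_concentrations = sort(unique(standard_concentrations)),
         n_blank_spots = as.integer(n_blank_spots),
         technical_cv_percent = technical_cv_percent,
         seed = as.integer(seed)),
    class = "array_layout"
  )
}

default_curve_params <- function(markers, slope = 3e4, intercept = 500) {
  data.frame(marker = markers, slope = slope, intercept = intercept,
             stringsAsFactors = FALSE)
}

#' Simulate a raw spot-intensity table from an expression matrix
#'
#' Emits, per marker: one spot per standard concentration (expected intensity
#' `slope * conc + intercept`), `n_blank_spots` blank spots at the intercept
#' level, and `replicates_per_sample` spots per sample at
#' `slope * expression + intercept`.  Every expected intensity is perturbed by
#' multiplicative Gaussian noise with CV `technical_cv_percent` and floored
#' at 0.
#'
#' @param expr Expression matrix as produced by [simulate_cohort()].
#' @param layout An [array_layout()].
#' @param curve_params Optional data frame `marker, slope, intercept`
#'   (slopes must be positive); defaults to a common slope/intercept for all
#'   markers.
#' @return A spot table: data frame with columns `marker`, `content_type`
#'   (`sample`/`standard`/`blank`), `sample_id`, `class_label`,
#'   `replicate_index`, `nominal_concentration`, `intensity`.
#' @export
simulate_spot_table <- function(expr, layout, curve_params = NULL) {
  stopifnot(inherits(layout, "array_layout"))
  mk <- expr_markers(expr)
  if (is.null(curve_params)) curve_params <- default_curve_params(mk)
  if (any(curve_params$slope <= 0)) stop("standard-curve slopes must be > 0")
  missing_curve <- setdiff(mk, curve_params$marker)
  if (length(missing_curve) > 0L)
    stop("no curve parameters for marker(s): ",
         paste(missing_curve, collapse = ", "))

  one_marker <- function(m) {
    slope <- curve_params$slope[match(m, curve_params$marker)]
    icpt <- curve_params$intercept[match(m, curve_params$marker)]
    conc <- layout$standard_concentrations
    std <- data.frame(marker = m, content_type = "standard",
                      sample_id = NA_character_, class_label = NA_character_,
                      replicate_index = 1L, nominal_concentration = conc,
                      expected = slope * conc + icpt,
                      stringsAsFactors = FALSE)
    blk <- if (layout$n_blank_spots > 0L)
      data.frame(marker = m, content_type = "blank",
                 sample_id = NA_character_, class_label = NA_character_,
                 replicate_index = seq_len(layout$n_blank_spots),
                 nominal_concentration = NA_real_, expected = icpt,
                 stringsAsFactors = FALSE)
    rep_idx <- seq_len(layout$replicates_per_sample)
    smp <- data.frame(
      marker = m, content_type = "sample",
      sample_id = rep(expr$sample_id, each = length(rep_idx)),
      class_label = rep(expr$class_label, each = length(rep_idx)),
      replicate_index = rep(rep_idx, times = nrow(expr)),
      nominal_concentration = NA_real_,
      expected = rep(slope * expr[[m]] + icpt, each = length(rep_idx)),
      stringsAsFactors = FALSE)
    rbind(std, blk, smp)
  }
  tab <- do.call(rbind, c(lapply(mk, one_marker), make.row.names = FALSE))
  withr::with_seed(layout$seed, {
    noise <- 1 + layout$technical_cv_percent / 100 * stats::rnorm(nrow(tab))
    tab$intensity <- pmax(tab$expected * noise, 0)
  })
  tab$expected <- NULL
  tab
}

# marker columns of an expression matrix = everything but the two id columns
expr_markers <- function(expr) {
  setdiff(names(expr), c("sample_id", "class_label"))
}
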