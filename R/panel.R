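#' The default energy-metabolism marker panel
#'
#' Nineteen proteins spanning glycogenolysis, glycolysis, the electron shuttle,
#' pyruvate oxidation, fatty-acid oxidation, the Krebs cycle, the respiratory
#' chain, oxidative phosphorylation, oxidative-stress defence and structural
#' normalizers, each labelled by cellular compartment.
#'
#' @return A data frame with columns `name` and `compartment`
#'   (`"mitochondrial"` or `"cytoplasmic"`), one row per assayed protein.
#' @examples
#' marker_panel()
#' @export
marker_panel <- function() {
  tab <- reference_table()
  m <- unique(tab[tab$compartment != "ratio", c("marker", "compartment")])
  rownames(m) <- NULL
  names(m)[1] <- "name"
  stopifnot(nrow(m) == 19L, !anyDuplicated(m$name))
  m
}

#' Names of the derived bioenergetic-signature ratios
#'
#' @return Character vector: BEC index, beta-F1/GAPDH and beta-F1/LDH-A.
#' @export
signature_ratios <- function() c("bec_index", "bf1_over_gapdh", "bf1_over_ldha")

# cached read of the packaged group-parameter table
reference_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "group_fold_of_control.csv",
                          package = "bioensig", mustWork = TRUE)
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
      cache$stars[is.na(cache$stars)] <<- ""
    }
    cache
  }
})

#' Reference group parameters for the neuromuscular-disease cohort
#'
#' Published per-group mean fold-of-control and SEM for every marker and
#' derived ratio, together with the group sizes (controls n = 20, Complex I
#' deficiency n = 12, glycogenosis type V n = 7, DMD n = 6, BMD n = 6,
#' Xp21 carriers n = 4, LGMD2C n = 6, NCL n = 6, ICU myopathy n = 6).
#' These parameters drive the cohort simulator.
#'
#' @param groups Optional character vector of group names to keep (in the
#'   given order). Default: all nine groups.
#' @return A named list of [group_spec()] objects.
#' @examples
#' specs <- reference_groups(c("CTR", "GlycV"))
#' specs$GlycV$n
#' @export
reference_groups <- function(groups = NULL) {
  tab <- reference_table()
  all_groups <- unique(tab$group)
  if (is.null(groups)) groups <- all_groups
  bad <- setdiff(groups, all_groups)
  if (length(bad) > 0L)
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  out <- lapply(groups, function(g) {
    sub <- tab[tab$group == g, ]
    group_spec(
      group_name = g,
      n          = sub$n[1],
      means      = stats::setNames(sub$mean_fold, sub$marker),
      sems       = stats::setNames(sub$sem, sub$marker),
      control    = sub$control[1]
    )
  })
  stats::setNames(out, groups)
}

#' Construct a simulation spec for one sample group
#'
#' @param group_name Group label attached to simulated samples.
#' @param n Number of samples in the group (>= 1).
#' @param means Named nonnegative numeric vector of mean fold-of-control
#'   values, one per marker or ratio.
#' @param sems Named nonnegative numeric vector of standard errors of the
#'   mean, aligned with `means`.
#' @param control Logical; is this the reference (control) group?  A control
#'   group must have mean 1.0 for every marker.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(group_name, n, means, sems, control = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("group '", group_name, "': n must be >= 1")
  if (is.null(names(means)) || is.null(names(sems)) ||
      !identical(names(means), names(sems)))
    stop("'means' and 'sems' must share identical marker names")
  if (any(means < 0)) stop("group '", group_name, "': negative mean fold")
  if (any(sems < 0)) stop("group '", group_name, "': negative SEM")
  if (isTRUE(control) && any(means != 1.0))
    stop("control group '", group_name, "' must have mean fold 1.0 for every marker")
  structure(
    list(group_name = as.character(group_name), n = n,
         per_marker = data.frame(marker = names(means),
                                 mean_fold = unname(means),
                                 sem = unname(sems),
                                 stringsAsFactors = FALSE),
         control = isTRUE(control)),
    class = "group_spec"
  )
}

#' Construct a cohort simulation spec
#'
#' @param groups List of [group_spec()] objects; exactly one must be flagged
#'   as control and group names must be unique.
#' @param seed Integer seed; the simulator never touches the global RNG state.
#' @param value_floor Lower bound applied to every simulated expression value
#'   (default 0; fold-of-control values cannot be negative).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed, value_floor = 0) {
  if (!is.list(groups) || length(groups) < 1L ||
      !all(vapply(groups, inherits, logical(1), "group_spec")))
    stop("'groups' must be a non-empty list of group_spec objects")
  nm <- vapply(groups, `[[`, character(1), "group_name")
  if (anyDuplicated(nm)) stop("duplicate group names: ", nm[duplicated(nm)][1])
  if (sum(vapply(groups, `[[`, logical(1), "control")) != 1L)
    stop("exactly one group must be flagged as control")
  if (value_floor < 0) stop("'value_floor' must be nonnegative")
  structure(
    list(groups = stats::setNames(groups, nm),
         seed = as.integer(seed), value_floor = value_floor),
    class = "cohort_spec"
  )
}

#' Interval classification rules for the disease panel
#'
#' The packaged rule set pairs a closed interval on the beta-F1/LDH-A ratio
#' with a closed interval on one additional marker per disease
#' (DMD: PYGM; BMD: GAPDH; NCL: GPD1; LGMD2C: SDH).
#'
#' @return Named list of [range_rule()] objects keyed by disease.
#' @examples
#' diagnostic_rules()$DMD
#' @export
diagnostic_rules <- function() {
  path <- system.file("extdata", "diagnostic_rules.csv",
                      package = "bioensig", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    range_rule(
      disease        = tab$disease[i],
      ratio_interval = c(tab$ratio_lo[i], tab$ratio_hi[i]),
      extra_marker   = tab$extra_marker[i],
      extra_interval = c(tab$extra_lo[i], tab$extra_hi[i]),
      printed_sensitivity = tab$printed_sensitivity[i]
    )
  })
  stats::setNames(out, tab$disease)
}
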