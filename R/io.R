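#' Read and write the expression-matrix CSV dialect
#'
#' Columns: `sample_id`, `class_label`, then one numeric column per marker.
#'
#' @param path File path.
#' @param units Units attribute to attach on read (`"calibrated"`,
#'   `"fold_of_control"` or `"log2_relative"`).
#' @return `read_expression_csv()` returns an expression matrix;
#'   `write_expression_csv()` returns `path` invisibly.
#' @export
read_expression_csv <- function(path, units = "fold_of_control") {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        warning("empty expression CSV: ", path)
        data.frame(sample_id = character(), class_label = character(),
                   stringsAsFactors = FALSE)
      } else stop(e)
    })
  need <- c("sample_id", "class_label")
  absent <- setdiff(need, names(df))
  if (length(absent) > 0L)
    stop("malformed expression CSV header (line 1 of ", path,
         "): missing column(s) ", paste(absent, collapse = ", "))
  for (m in setdiff(names(df), need)) {
    if (!is.numeric(df[[m]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[m]]))) & !is.na(df[[m]]))
      stop("non-numeric value in column '", m, "' of ", path,
           if (length(bad) > 0L) paste0(" (data line ", bad[1], ")") else "")
    }
  }
  attr(df, "units") <- units
  df
}

#' @rdname read_expression_csv
#' @param expr Expression matrix to write.
#' @export
write_expression_csv <- function(expr, path) {
  utils::write.csv(expr, path, row.names = FALSE)
  invisible(path)
}

#' Read and write the spot-table CSV dialect
#'
#' Columns: `marker`, `content_type` (`sample`/`standard`/`blank`),
#' `sample_id`, `class_label`, `replicate_index`, `nominal_concentration`,
#' `intensity`.
#'
#' @param path File path.
#' @return `read_spot_csv()` returns a spot table data frame;
#'   `write_spot_csv()` returns `path` invisibly.
#' @export
read_spot_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "content_type", "sample_id", "class_label",
            "replicate_index", "nominal_concentration", "intensity")
  absent <- setdiff(need, names(df))
  if (length(absent) > 0L)
    stop("malformed spot CSV header (line 1 of ", path,
         "): missing column(s) ", paste(absent, collapse = ", "))
  if (nrow(df) > 0L) {
    if (!is.numeric(df$intensity))
      stop("non-numeric intensity in ", path)
    if (any(df$intensity < 0, na.rm = TRUE))
      stop("negative intensity in ", path, " (data line ",
           which(df$intensity < 0)[1], ")")
    bad_type <- !df$content_type %in% c("sample", "standard", "blank")
    if (any(bad_type))
      stop("unknown content_type in ", path, " (data line ",
           which(bad_type)[1], ")")
  }
  df
}

#' @rdname read_spot_csv
#' @param table Spot table to write.
#' @export
write_spot_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Export a linkage as a Newick tree
#'
#' The dendrogram is ultrametric: a leaf below a merge at height `h` sits at
#' depth `h / 2`, so the patristic distance between two leaves equals their
#' merge height; branch lengths are differences of those depths.
#'
#' @param linkage An [wpgma_linkage()] result.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(linkage, path = NULL) {
  phy <- ape::as.phylo(as_hclust(linkage))
  nwk <- ape::write.tree(phy)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
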