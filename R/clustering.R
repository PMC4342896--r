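#' Pairwise Euclidean distances over selected markers
#'
#' @param expr Expression matrix (typically in log2-relative units).
#' @param markers Marker columns to use; default all.
#' @return A `dist` object labelled by sample id.
#' @export
euclidean_distances <- function(expr, markers = NULL) {
  if (is.null(markers)) markers <- expr_markers(expr)
  missing_mk <- setdiff(markers, names(expr))
  if (length(missing_mk) > 0L)
    stop("marker(s) not in matrix: ", paste(missing_mk, collapse = ", "))
  m <- as.matrix(expr[, markers, drop = FALSE])
  if (anyNA(m)) {
    bad <- expr$sample_id[apply(is.na(m), 1L, any)]
    stop("missing values in selected markers for sample(s): ",
         paste(bad, collapse = ", "))
  }
  rownames(m) <- expr$sample_id
  stats::dist(m, method = "euclidean")
}

#' Agglomerative WPGMA (or UPGMA) linkage
#'
#' From-scratch weighted pair-group average clustering: at each step the
#' closest pair of clusters is merged and the distance from the merged
#' cluster to any other is the plain average `(d(a, c) + d(b, c)) / 2`,
#' independent of cluster sizes (WPGMA / McQuitty).  `method = "upgma"`
#' switches to the size-weighted average.  Ties are broken by the smallest
#' (left-most) pair of active cluster indices, so runs are reproducible.
#'
#' @param d A `dist` object or symmetric nonnegative matrix with zero
#'   diagonal (n >= 2 items).
#' @param method `"wpgma"` (default) or `"upgma"`.
#' @return Object of class `rpma_linkage`: `merge` (hclust-style merge
#'   matrix), `height` (merge heights), `labels`, `sizes`, `method`, `n`.
#' @examples
#' d <- dist(c(A = 0, B = 2, C = 6)) # 1-d points
#' wpgma_linkage(d)$height
#' @export
wpgma_linkage <- function(d, method = c("wpgma", "upgma")) {
  method <- match.arg(method)
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster")
  if (any(D < 0)) stop("distances must be nonnegative")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  labs <- rownames(D)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  code <- -seq_len(n)      # hclust convention: negative = leaf
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    U <- D
    U[lower.tri(U, diag = TRUE)] <- Inf
    hit <- which(U == min(U), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
    i <- hit[[1L]]; j <- hit[[2L]]
    height[s] <- D[i, j]
    merge[s, ] <- c(code[i], code[j])
    newd <- if (method == "wpgma") (D[i, ] + D[j, ]) / 2
            else (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    D <- D[-j, -j, drop = FALSE]
    code[i] <- s; size[i] <- size[i] + size[j]
    code <- code[-j]; size <- size[-j]
  }
  structure(list(merge = merge, height = height, labels = labs,
                 method = method, n = n),
            class = "rpma_linkage")
}

#' @export
print.rpma_linkage <- function(x, ...) {
  cat(sprintf("%s linkage of %d items; merge heights %s\n",
              toupper(x$method), x$n,
              paste(signif(x$height, 4), collapse = ", ")))
  invisible(x)
}

# leaves under merge node k, in dendrogram order
linkage_leaves <- function(linkage, k) {
  side <- function(v) if (v < 0) -v else linkage_leaves(linkage, v)
  c(side(linkage$merge[k, 1L]), side(linkage$merge[k, 2L]))
}

#' Convert a linkage to a base-R `hclust` object
#'
#' @param linkage An [wpgma_linkage()] result.
#' @return An object of class `hclust` (usable with [stats::cutree()],
#'   plotting, or [ape::as.phylo()]).
#' @export
as_hclust <- function(linkage) {
  stopifnot(inherits(linkage, "rpma_linkage"))
  structure(
    list(merge = linkage$merge, height = linkage$height,
         order = linkage_leaves(linkage, linkage$n - 1L),
         labels = linkage$labels,
         method = if (linkage$method == "wpgma") "mcquitty" else "average",
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Cut a linkage into k clusters
#'
#' Undoes the last `k - 1` merges; each resulting cluster is labelled by the
#' index of its smallest member, so labels do not depend on merge order.
#'
#' @param linkage An [wpgma_linkage()] result.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels named by sample label.
#' @export
cut_tree <- function(linkage, k) {
  stopifnot(inherits(linkage, "rpma_linkage"))
  n <- linkage$n
  if (k < 1L || k > n) stop("'k' must be between 1 and ", n)
  comp <- seq_len(n)
  for (s in seq_len(n - k)) {
    members <- linkage_leaves(linkage, s)
    comp[members] <- min(comp[members])
  }
  stats::setNames(comp, linkage$labels)
}

#' Classification performance of a clustering against known classes
#'
#' Assigns each cluster the majority true class among its members (ties go
#' to the class with the larger cohort, then lexicographically first), then
#' scores per-class sensitivity (fraction of the class landing in clusters
#' mapped to it), the control-class specificity, and per-class
#' `TP / (TP + FP)` rates under the same mapping.  A pooled evaluation
#' collapses all non-control classes into one "pathologic" class and repeats
#' the mapping, yielding the pooled pathologic sensitivity and control
#' specificity.
#'
#' @param labels Cluster labels (e.g. from [cut_tree()]).
#' @param truth True class labels, aligned with `labels`.
#' @param control_label Class regarded as the negative (control) class.
#' @return Object of class `cluster_performance`: `per_class` data frame
#'   (`class`, `n`, `sensitivity_percent`, `tp_fp_percent`), scalar
#'   `specificity_percent`, `pooled_sensitivity_percent`,
#'   `pooled_specificity_percent`, and the cluster-to-class `mapping`.
#' @export
cluster_performance <- function(labels, truth, control_label = "CTR") {
  if (length(labels) != length(truth))
    stop("'labels' and 'truth' differ in length")
  truth <- as.character(truth)

  majority_map <- function(labels, truth) {
    cohort <- table(truth)
    vapply(split(truth, labels), function(cls) {
      counts <- sort(table(cls), decreasing = TRUE)
      top <- names(counts)[counts == max(counts)]
      if (length(top) > 1L)
        top <- top[order(-cohort[top], top)]
      top[1L]
    }, character(1))
  }

  map <- majority_map(labels, truth)
  assigned <- unname(map[as.character(labels)])
  classes <- sort(unique(truth))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    nc <- sum(truth == cl)
    tp <- sum(truth == cl & assigned == cl)
    called <- sum(assigned == cl)
    data.frame(class = cl, n = nc,
               sensitivity_percent = 100 * tp / nc,
               tp_fp_percent = if (called > 0) 100 * tp / called else NA_real_,
               stringsAsFactors = FALSE)
  }))

  pooled <- rep("pathologic", length(truth))
  pooled[truth == control_label] <- control_label
  pmap <- majority_map(labels, pooled)
  passigned <- unname(pmap[as.character(labels)])
  pooled_sens <- if (any(pooled == "pathologic"))
    100 * mean(passigned[pooled == "pathologic"] == "pathologic") else NA_real_
  pooled_spec <- if (any(pooled == control_label))
    100 * mean(passigned[pooled == control_label] == control_label) else NA_real_

  structure(
    list(per_class = per_class,
         specificity_percent =
           if (control_label %in% classes)
             per_class$sensitivity_percent[per_class$class == control_label]
           else NA_real_,
         pooled_sensitivity_percent = pooled_sens,
         pooled_specificity_percent = pooled_spec,
         mapping = map),
    class = "cluster_performance"
  )
}

#' @export
print.cluster_performance <- function(x, ...) {
  print(x$per_class)
  cat(sprintf("control specificity: %.1f%% | pooled pathologic sensitivity: %.1f%% | pooled specificity: %.1f%%\n",
              x$specificity_percent, x$pooled_sensitivity_percent,
              x$pooled_specificity_percent))
  invisible(x)
}

#' Repeated simulated-cohort clustering experiment
#'
#' Simulates cohorts from the packaged group parameters, transforms them to
#' log2-relative expression, clusters them with Euclidean/WPGMA, cuts the
#' tree and scores classification performance, averaging over replicates.
#' This reproduces the marker-panel clustering experiments in silico.
#'
#' @param groups Character vector of group names (must include the control).
#' @param markers Marker/ratio columns used for clustering.
#' @param k Number of clusters to cut.
#' @param reps Number of seeded replicates (default 200).
#' @param seed Integer master seed; per-replicate seeds are derived from it.
#' @param control_label Control class label.
#' @param log2_floor Floor passed to [log2_relative()].
#' @return List with `per_class_sensitivity` (named mean %),
#'   `pooled_sensitivity`, `pooled_specificity`, `specificity` (control
#'   class, per-class mapping), and `reps`.
#' @export
clustering_benchmark <- function(groups, markers, k, reps = 200, seed = 1L,
                                 control_label = "CTR", log2_floor = 0.01) {
  gspecs <- reference_groups(groups)
  rep_seeds <- withr::with_seed(seed, sample.int(2147483647L, reps))
  classes <- groups
  sens <- matrix(NA_real_, reps, length(classes),
                 dimnames = list(NULL, classes))
  pooled_sens <- numeric(reps); pooled_spec <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- cohort_spec(gspecs, seed = rep_seeds[r])
    expr <- simulate_cohort(spec, markers = markers)
    lr <- log2_relative(expr, control_label, floor = log2_floor)
    lk <- wpgma_linkage(euclidean_distances(lr, markers))
    perf <- cluster_performance(cut_tree(lk, k), expr$class_label,
                                control_label)
    sens[r, perf$per_class$class] <- perf$per_class$sensitivity_percent
    pooled_sens[r] <- perf$pooled_sensitivity_percent
    pooled_spec[r] <- perf$pooled_specificity_percent
  }
  list(per_class_sensitivity = colMeans(sens),
       pooled_sensitivity = mean(pooled_sens),
       pooled_specificity = mean(pooled_spec),
       specificity = mean(sens[, control_label]),
       reps = reps)
}
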