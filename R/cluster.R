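# Unit-cell variation analysis: group partial datasets by cell similarity
# and reject datasets that deviate from their group.

#' Distance between two unit cells
#'
#' Weighted Euclidean distance over the six cell parameters, optionally
#' after dividing each parameter by a population scale.  When used inside
#' [cluster_cells()] the scales are the per-parameter standard deviations
#' across the input population (standardized Euclidean metric); on its own
#' the default is the unscaled weighted metric.
#'
#' @param c1,c2 [unit_cell()] objects.
#' @param scale length-6 positive divisors per parameter (default 1).
#' @param weights length-6 non-negative weights; the distance is
#'   `sqrt(sum(weights * ((p1 - p2) / scale)^2))`.
#' @return non-negative scalar; 0 iff the parameters are identical.
#' @export
cell_distance <- function(c1, c2, scale = rep(1, 6), weights = rep(1, 6)) {
  p1 <- as.numeric(as_unit_cell(c1))
  p2 <- as.numeric(as_unit_cell(c2))
  stopifnot(length(scale) == 6, length(weights) == 6, all(scale > 0),
            all(weights >= 0))
  sqrt(sum(weights * ((p1 - p2) / scale)^2))
}

.cell_param_matrix <- function(datasets) {
  m <- t(vapply(datasets, function(ds) as.numeric(ds$cell), numeric(6)))
  colnames(m) <- c("a", "b", "c", "alpha", "beta", "gamma")
  rownames(m) <- vapply(datasets, function(ds) ds$crystal_id, "")
  m
}

#' Group partial datasets by unit-cell variation
#'
#' Parameters are centred and divided by a common scale, the largest
#' per-parameter standard deviation across the input population, so that
#' lengths and angles become comparable while the relative magnitude of
#' variation between parameters (which carries the grouping signal) is
#' preserved; per-parameter variance standardization would whiten every
#' jittering parameter to unit noise and erase a split confined to one
#' axis.  Average-linkage agglomerative clustering is run on the
#' Euclidean distance matrix in these standardized units, and the tree is
#' cut either at `max_groups` groups or at `height` when given.  Any
#' crystal whose distance to its group centroid exceeds `reject_z`
#' standardized units is moved to the rejected set.  The procedure is
#' deterministic; ties are resolved by input (crystal id) order.
#'
#' @param datasets list of [crystal_dataset()] objects (>= 2).
#' @param max_groups maximum number of groups the tree is cut to
#'   (default 20).
#' @param reject_z rejection threshold in standardized units (default 3;
#'   `Inf` disables rejection).
#' @param angle_weight weight given to the three angle parameters relative
#'   to the lengths, applied after standardization (default 1).
#' @param height optional tree-cut height overriding `max_groups`.
#' @return object of class `"cell_grouping"`: a data.frame
#'   `(crystal_id, group, dist_to_centroid, rejected)` with attributes
#'   `heights` (merge heights), `metric` (name of the metric), and
#'   `scale` (the standardization divisors used).
#' @export
cluster_cells <- function(datasets, max_groups = 20, reject_z = 3,
                          angle_weight = 1, height = NULL) {
  if (length(datasets) < 2) stop("need at least 2 datasets to cluster")
  m <- .cell_param_matrix(datasets)
  ids <- rownames(m)
  sds <- apply(m, 2, stats::sd)
  scale <- max(sds)
  if (scale <= 1e-12) scale <- 1        # all cells identical
  z <- sweep(m, 2, colMeans(m), "-") / scale
  w <- c(1, 1, 1, rep(angle_weight, 3))
  z <- sweep(z, 2, sqrt(w), "*")

  hc <- stats::hclust(stats::dist(z), method = "average")
  groups <- if (is.null(height)) {
    stats::cutree(hc, k = min(max_groups, length(ids)))
  } else {
    stats::cutree(hc, h = height)
  }

  centroid <- apply(z, 2, function(col) stats::ave(col, groups))
  if (length(ids) == 1) centroid <- matrix(centroid, 1)
  dist_c <- sqrt(rowSums((z - centroid)^2))
  rejected <- dist_c > reject_z
  if (all(rejected))
    stop("unit-cell rejection discarded every dataset; ",
         "check reject_z (", reject_z, ") against the population spread")

  out <- data.frame(crystal_id = ids, group = as.integer(groups),
                    dist_to_centroid = dist_c, rejected = rejected,
                    row.names = NULL)
  structure(out,
            heights = hc$height,
            metric = "common-scale standardized Euclidean (average linkage)",
            scale = scale,
            class = c("cell_grouping", "data.frame"))
}

#' @export
print.cell_grouping <- function(x, ...) {
  cat(sprintf("cell grouping: %d crystals in %d groups, %d rejected (%s)\n",
              nrow(x), length(unique(x$group[!x$rejected])),
              sum(x$rejected), attr(x, "metric")))
  tab <- table(x$group[!x$rejected])
  cat("group sizes:", paste(sprintf("%s:%d", names(tab), tab),
                            collapse = " "), "\n")
  invisible(x)
}

#' Write a cell grouping as CSV
#'
#' @param grouping a [cluster_cells()] result.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_grouping_csv <- function(grouping, path) {
  utils::write.csv(as.data.frame(grouping), path, row.names = FALSE)
  invisible(path)
}
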