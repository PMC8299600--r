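# Label generation: z-scaling of valid features, hierarchical k-means
# clustering and assignment of survival semantics to the clusters.

#' Fit a z-score scaler
#'
#' Learns per-feature mean and standard deviation from a reference matrix.
#' Applying the scaler to its own reference yields column means 0 and sd 1;
#' constant columns map to 0.
#'
#' @param x Patients x features matrix.
#' @return Object of class `zscaler` with `mean`, `sd`, `features`.
#' @export
zscaler_fit <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  structure(list(mean = mu, sd = sdv, features = colnames(x)),
            class = "zscaler")
}

#' Apply a z-score scaler
#'
#' @param scaler A [zscaler_fit()] object.
#' @param x Matrix whose columns match the scaler's features (checked by
#'   name when available).
#' @return Scaled matrix; features with zero reference sd become 0.
#' @export
zscaler_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "zscaler"), ncol(x) == length(scaler$mean))
  if (!is.null(colnames(x)) && !is.null(scaler$features) &&
      !identical(colnames(x), scaler$features)) {
    stop("feature names/order differ from the scaler's reference")
  }
  sdv <- ifelse(scaler$sd > 0, scaler$sd, 1)
  z <- sweep(sweep(x, 2, scaler$mean, "-"), 2, sdv, "/")
  z[, scaler$sd == 0] <- 0
  z
}

# Masked (NA) aggregated entries sit at the reference mean after z-scoring.
impute_masked <- function(z) {
  z[!is.finite(z)] <- 0
  z
}

#' Hierarchical k-means clustering
#'
#' Ward-linkage hierarchical clustering on Euclidean distances is cut at `k`;
#' the resulting cluster means seed a Lloyd k-means run to convergence. This
#' is the standard hybrid that makes k-means deterministic given the data.
#'
#' @param x Numeric matrix (rows are patients).
#' @param k Number of clusters (default 2).
#' @return List with `cluster` (1..k per row), `centers`, `sizes`.
#' @export
hkmeans <- function(x, k = 2L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("matrix must be finite")
  if (nrow(x) < k) stop("k exceeds the number of rows")
  if (k == 1L) {
    return(list(cluster = rep(1L, nrow(x)),
                centers = matrix(colMeans(x), 1L,
                                 dimnames = list(NULL, colnames(x))),
                sizes = nrow(x)))
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(x[grp == g, , drop = FALSE])
  }))
  km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = 200L,
                                       algorithm = "Lloyd"))
  list(cluster = as.integer(km$cluster), centers = km$centers,
       sizes = as.integer(km$size))
}

#' Assign survival semantics to clusters
#'
#' The cluster with the larger median overall survival is the long-term
#' group; median ties are broken by the mean.
#'
#' @param cluster Integer cluster labels.
#' @param os_days Survival times aligned to `cluster`.
#' @return Named character vector mapping cluster id to `"long-term"` /
#'   `"short-term"` (k = 2), plus attribute `"long"` with the long-term
#'   cluster id.
#' @export
assign_cluster_semantics <- function(cluster, os_days) {
  ids <- sort(unique(cluster))
  if (length(ids) != 2L) stop("semantics are defined for exactly 2 clusters")
  med <- vapply(ids, function(g) stats::median(os_days[cluster == g]),
                numeric(1))
  mn <- vapply(ids, function(g) mean(os_days[cluster == g]), numeric(1))
  long <- if (med[1] != med[2]) ids[which.max(med)] else ids[which.max(mn)]
  out <- ifelse(ids == long, "long-term", "short-term")
  names(out) <- ids
  attr(out, "long") <- long
  out
}

#' Binary survival labels from clustering
#'
#' Convenience wrapper: cluster the (z-scored) valid-feature matrix with
#' [hkmeans()], name the clusters by survival, and return 0/1 labels with
#' 1 = long-term.
#'
#' @param z Z-scored valid-feature matrix.
#' @param os_days Survival times.
#' @param k Number of clusters (2).
#' @return List with `labels` (0/1), `cluster`, `semantics`, `hk`.
#' @export
survival_labels <- function(z, os_days, k = 2L) {
  hk <- hkmeans(z, k)
  sem <- assign_cluster_semantics(hk$cluster, os_days)
  labels <- as.integer(hk$cluster == attr(sem, "long"))
  list(labels = labels, cluster = hk$cluster, semantics = sem, hk = hk)
}
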