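#' Fit a TiME phenotype model (PCA + hierarchical clustering)
#'
#' Standardizes the ordinal grades (z-score per feature, i.e. PCA on the
#' correlation matrix — the features share the 0-3 scale), retains the
#' fewest leading principal components explaining at least
#' `variance_retained` of total variance, and applies Ward-linkage
#' hierarchical clustering on the retained scores. With `n_clusters =
#' "auto"` the cut is chosen over k = 2..6 as the partition with the
#' largest relative loss of within-cluster inertia over the preceding
#' partition, `(W(k-1) - W(k)) / W(k-1)`.
#'
#' @param table a [feature_table] with at least 4 samples, 2 features, and
#'   positive variance in every feature.
#' @param n_clusters number of clusters, or `"auto"`.
#' @param variance_retained minimum fraction of variance the retained
#'   components must explain (default 0.95).
#' @return An object of class `phenotype_model`: standardization
#'   (`feature_means`, `feature_sds`), `loadings` (features x components,
#'   orthonormal columns), `eigenvalues`, `n_retained`, `scores` (samples x
#'   retained), `cluster_of_sample`, `centroids` (clusters x retained, in
#'   PC space), and empty axis/label slots filled by
#'   [assign_phenotype_labels].
#' @export
fit_phenotype_model <- function(table, n_clusters = "auto",
                                variance_retained = 0.95) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$grades
  if (nrow(X) < 4) stop("phenotyping needs at least 4 samples")
  if (ncol(X) < 2) stop("phenotyping needs at least 2 features")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(table$feature_names[sds == 0], collapse = ", "))
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pca$sdev^2
  cum <- cumsum(eig) / sum(eig)
  n_ret <- which(cum >= variance_retained - 1e-12)[1]
  n_ret <- max(n_ret, min(2L, length(eig))) # keep >= 2 axes when available
  scores <- pca$x[, seq_len(n_ret), drop = FALSE]
  hc <- hclust(dist(scores), method = "ward.D2")
  k <- if (identical(n_clusters, "auto")) auto_cluster_count(scores, hc) else
    as.integer(n_clusters)
  if (k < 1 || k > nrow(X)) stop("invalid cluster count")
  cl <- cutree(hc, k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(scores[cl == g, , drop = FALSE])))
  structure(list(
    feature_names = table$feature_names,
    feature_means = pca$center, feature_sds = pca$scale,
    loadings = pca$rotation, eigenvalues = eig, n_retained = n_ret,
    scores = scores, cluster_of_sample = cl, centroids = centroids,
    n_clusters = k, axis_sign = rep(1, n_ret),
    vascular_axis = NA_integer_, inflammation_axis = NA_integer_,
    cluster_labels = NULL), class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf(
    "phenotype_model: %d samples, %d/%d PCs retained (%.1f%% variance), %d clusters\n",
    nrow(x$scores), x$n_retained, length(x$eigenvalues),
    100 * sum(x$eigenvalues[seq_len(x$n_retained)]) / sum(x$eigenvalues),
    x$n_clusters))
  if (!is.null(x$cluster_labels))
    cat("labels:", paste(x$cluster_labels, collapse = ", "), "\n")
  invisible(x)
}

# auto cut: k maximizing the relative loss of within-cluster inertia
# between successive partitions over k = 2..6. The within inertia of the
# k-cluster partition is read off the Ward tree as the sum of the n-k
# lowest merge heights, and the k minimizing W(k)/W(k-1) (equivalently
# maximizing the relative loss 1 - W(k)/W(k-1)) is chosen.
auto_cluster_count <- function(scores, hc, k_range = 2:6) {
  n <- nrow(scores)
  k_range <- k_range[k_range < n]
  h <- sort(hc$height)
  W <- vapply(c(k_range[1] - 1, k_range), function(k)
    sum(h[seq_len(n - k)]), numeric(1))
  rel_loss <- -diff(W) / pmax(W[-length(W)], 1e-12)
  rel_loss[!is.finite(rel_loss)] <- -Inf
  # ordinal grades produce many duplicate rows, so partitions beyond the
  # true structure exhaust the remaining inertia and would win a global
  # argmax spuriously; only consider splitting partitions that still hold
  # > 5% of the total inertia, and take the first elbow (local maximum)
  total <- sum(h)
  keep <- which(W[-length(W)] > 0.05 * total)
  if (length(keep) == 0) keep <- 1L
  rel_loss <- rel_loss[keep]
  k_range <- k_range[keep]
  up <- c(TRUE, diff(rel_loss) >= 0)
  down <- c(diff(rel_loss) < 0, TRUE)
  k_range[which(up & down)[1]]
}

within_inertia <- function(scores, cl) {
  sum(vapply(unique(cl), function(g) {
    s <- scores[cl == g, , drop = FALSE]
    sum(sweep(s, 2, colMeans(s))^2)
  }, numeric(1)))
}

#' Per-feature contribution to a principal component
#'
#' Contribution of feature j to component c is
#' `100 * loading(j, c)^2 / sum_j loading(j, c)^2`.
#'
#' @param model a [fit_phenotype_model].
#' @param component retained component index.
#' @return Named numeric vector of percentages summing to 100.
#' @export
variable_contributions <- function(model, component) {
  if (!is.numeric(component) || component < 1 || component > model$n_retained)
    stop("component must be a retained component index")
  l <- model$loadings[, component]^2
  stats::setNames(100 * l / sum(l), model$feature_names)
}

#' Name phenotype clusters on Inflam/Vasc axes
#'
#' Identifies the retained component on which the vascular features
#' contribute most (the vascular axis) and likewise for the inflammation
#' features; the two must differ. Each axis is sign-oriented so the summed
#' loadings of its defining features are positive, and a cluster is HIGH on
#' an axis when its centroid lies above 0 (the grand mean in standardized
#' space) on that oriented axis. Labels have the form
#' `Inflam^HIGH|LOW Vasc^HIGH|LOW`.
#'
#' @param model a [fit_phenotype_model].
#' @param vascular_features,inflammation_features disjoint feature-name
#'   sets present in the model.
#' @return The model with `vascular_axis`, `inflammation_axis`,
#'   `axis_sign` and `cluster_labels` filled in.
#' @export
assign_phenotype_labels <- function(model,
                                    vascular_features = c("number_of_vessels",
                                                          "dilated_vessels",
                                                          "trafficking"),
                                    inflammation_features = c("intratumor_inflammation",
                                                              "peritumor_inflammation",
                                                              "perivascular_inflammation")) {
  if (length(intersect(vascular_features, inflammation_features)) > 0)
    stop("vascular and inflammation feature sets must be disjoint")
  missing <- setdiff(c(vascular_features, inflammation_features), model$feature_names)
  if (length(missing) > 0)
    stop("features not in model: ", paste(missing, collapse = ", "))
  contrib <- vapply(seq_len(model$n_retained),
                    function(c) variable_contributions(model, c),
                    numeric(length(model$feature_names)))
  vi <- match(vascular_features, model$feature_names)
  ii <- match(inflammation_features, model$feature_names)
  vasc_axis <- which.max(colSums(contrib[vi, , drop = FALSE]))
  infl_axis <- which.max(colSums(contrib[ii, , drop = FALSE]))
  if (vasc_axis == infl_axis)
    stop("vascular and inflammation features dominate the same component; ",
         "set the axes manually")
  sign_of <- function(axis, rows) {
    s <- sum(model$loadings[rows, axis])
    if (s >= 0) 1 else -1
  }
  model$axis_sign[vasc_axis] <- sign_of(vasc_axis, vi)
  model$axis_sign[infl_axis] <- sign_of(infl_axis, ii)
  model$vascular_axis <- vasc_axis
  model$inflammation_axis <- infl_axis
  hl <- function(v) ifelse(v > 0, "HIGH", "LOW")
  model$cluster_labels <- vapply(seq_len(model$n_clusters), function(g) {
    iv <- model$centroids[g, vasc_axis] * model$axis_sign[vasc_axis]
    il <- model$centroids[g, infl_axis] * model$axis_sign[infl_axis]
    sprintf("Inflam^%s Vasc^%s", hl(il), hl(iv))
  }, character(1))
  model
}

#' Project new samples onto a fitted phenotype model
#'
#' Standardizes with the training means/sds, multiplies by the loadings,
#' and assigns each sample the nearest cluster centroid (Euclidean in
#' retained-PC space; ties broken by lowest cluster index), inheriting the
#' cluster's phenotype label when present.
#'
#' @param model a [fit_phenotype_model].
#' @param new_table a [feature_table] containing the model's features.
#' @return data.frame with `sample_id`, the retained-PC scores, `cluster`
#'   and (when labeled) `label`.
#' @export
project_samples <- function(model, new_table) {
  stopifnot(inherits(new_table, "feature_table"))
  missing <- setdiff(model$feature_names, new_table$feature_names)
  if (length(missing) > 0)
    stop("new table lacks feature(s): ", paste(missing, collapse = ", "))
  X <- new_table$grades[, model$feature_names, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_sds, "/")
  scores <- Z %*% model$loadings[, seq_len(model$n_retained), drop = FALSE]
  cl <- apply(scores, 1, function(s) {
    d2 <- rowSums(sweep(model$centroids, 2, s)^2)
    which.min(d2) # which.min takes the first (lowest index) on ties
  })
  out <- data.frame(sample_id = new_table$sample_ids, scores,
                    cluster = as.integer(cl), row.names = NULL,
                    check.names = FALSE)
  if (!is.null(model$cluster_labels)) out$label <- model$cluster_labels[cl]
  out
}
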