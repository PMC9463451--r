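#' Leave-one-out cross-validated linear response classifier
#'
#' Fits a linear probability model (ordinary least squares of the 0/1
#' response on the selected features); for each lesion the model is trained
#' on the other n-1 lesions and the held-out prediction ("out-of-bag"
#' estimate) is thresholded at `cutoff`. Sensitivity is computed over
#' responders, specificity over non-responders. The full-data fit supplies
#' the coefficients and AIC.
#'
#' @param table a [feature_table] with a binary `response`.
#' @param features feature names to use as predictors.
#' @param cutoff classification cutoff on the predicted response.
#' @return An object of class `response_model_result`: `selected_features`,
#'   `coefficients`, `oob_predictions` (per-sample predicted probability
#'   and class; `NA` for folds skipped because one class was absent),
#'   `sensitivity`, `specificity`, `accuracy`, `aic`.
#' @export
loocv_linear_classifier <- function(table, features, cutoff = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$response)) stop("table must carry a binary response")
  y <- table$response
  n <- length(y)
  if (n < 4) stop("leave-one-out modeling needs at least 4 samples")
  if (length(unique(y)) < 2) stop("both response classes must be present")
  missing <- setdiff(features, table$feature_names)
  if (length(missing) > 0)
    stop("features not in table: ", paste(missing, collapse = ", "))
  X <- table$grades[, features, drop = FALSE]
  check_singular(X, features)

  oob_prob <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) {
      warning("fold ", i, " skipped: one response class absent")
      next
    }
    df <- data.frame(y = yi, X[-i, , drop = FALSE], check.names = FALSE)
    fit <- lm(y ~ ., data = df)
    oob_prob[i] <- predict(fit, newdata = as.data.frame(X[i, , drop = FALSE]))
  }
  oob_class <- ifelse(oob_prob >= cutoff, 1L, 0L)
  ok <- !is.na(oob_class)
  tp <- sum(ok & y == 1 & oob_class == 1)
  fn <- sum(ok & y == 1 & oob_class == 0)
  tn <- sum(ok & y == 0 & oob_class == 0)
  fp <- sum(ok & y == 0 & oob_class == 1)
  full <- lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE))
  structure(list(
    selected_features = features,
    coefficients = coef(full),
    oob_predictions = data.frame(sample_id = table$sample_ids,
                                 response = y, prob = oob_prob,
                                 class = oob_class),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / sum(ok),
    aic = aic_ols(table, features)),
    class = "response_model_result")
}

#' @export
print.response_model_result <- function(x, ...) {
  cat(sprintf("response model [%s]: sens %.2f, spec %.2f, acc %.2f, AIC %.2f\n",
              paste(x$selected_features, collapse = " + "),
              x$sensitivity, x$specificity, x$accuracy, x$aic))
  invisible(x)
}

#' Gaussian AIC of the OLS response model
#'
#' Fixed convention `AIC = n * ln(RSS / n) + 2 * (p + 2)` with `p`
#' predictors (the +2 counts the intercept and the variance parameter).
#' Errors on a degenerate perfect fit (RSS = 0) or a singular design.
#'
#' @param table a [feature_table] with a binary `response`.
#' @param features predictor feature names.
#' @return The AIC value.
#' @export
aic_ols <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$response)) stop("table must carry a binary response")
  X <- table$grades[, features, drop = FALSE]
  check_singular(X, features)
  y <- table$response
  fit <- lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE))
  rss <- sum(fit$residuals^2)
  if (rss <= 1e-10)
    stop("perfect fit (RSS = 0); AIC undefined under this convention")
  n <- length(y)
  n * log(rss / n) + 2 * (length(features) + 2)
}

check_singular <- function(X, features) {
  Xc <- cbind(1, X)
  if (qr(Xc)$rank < ncol(Xc)) {
    stop("singular design; collinear features among: ",
         paste(features, collapse = ", "))
  }
  invisible(TRUE)
}

#' Greedy forward feature selection for response prediction
#'
#' Starting from the empty set, each iteration adds the candidate feature
#' whose model scores best on the out-of-bag estimates under the chosen
#' criterion: `"specificity_first"` maximizes specificity with ties broken
#' by accuracy then lower AIC; `"aic_first"` minimizes AIC with ties broken
#' by accuracy.
#'
#' @param table a [feature_table] with a binary `response`.
#' @param candidate_features features to select from.
#' @param mode selection criterion.
#' @param max_features maximum number of features to add.
#' @param cutoff classification cutoff, see [loocv_linear_classifier].
#' @return List of [loocv_linear_classifier] results, one per iteration
#'   (best 1-feature model, best 2-feature model, ...), each with a
#'   `selection_trace` attribute of all candidate scores for the iteration.
#' @export
forward_select <- function(table, candidate_features,
                           mode = c("specificity_first", "aic_first"),
                           max_features = length(candidate_features),
                           cutoff = 0.5) {
  mode <- match.arg(mode)
  if (length(candidate_features) < 1) stop("at least one candidate feature required")
  selected <- character(0)
  remaining <- candidate_features
  out <- list()
  while (length(selected) < max_features && length(remaining) > 0) {
    trace <- lapply(remaining, function(f) {
      r <- tryCatch(loocv_linear_classifier(table, c(selected, f), cutoff),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(feature = f, sensitivity = r$sensitivity,
                 specificity = r$specificity, accuracy = r$accuracy, aic = r$aic)
    })
    trace <- do.call(rbind, trace)
    if (is.null(trace) || nrow(trace) == 0) break
    ord <- if (mode == "specificity_first")
      order(-trace$specificity, -trace$accuracy, trace$aic, trace$feature)
    else
      order(trace$aic, -trace$accuracy, trace$feature)
    best <- trace$feature[ord[1]]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    res <- loocv_linear_classifier(table, selected, cutoff)
    attr(res, "selection_trace") <- trace
    out[[length(out) + 1]] <- res
  }
  out
}

#' Exact linear-separability check in 1 or 2 feature dimensions
#'
#' Reports whether a linear boundary separates responders from
#' non-responders in the chosen 1-D or 2-D feature space. In 1-D the
#' classes are separable iff their value ranges are disjoint; in 2-D iff
#' their convex hulls are disjoint (no vertex containment and no edge
#' crossing). The margin is the maximal margin of a separating line: half
#' the minimum distance between the class hulls; 0 when not separable.
#'
#' @param table a [feature_table] with a binary `response`.
#' @param feature_pair one or two feature names.
#' @return List with `separable` (logical) and `margin`.
#' @export
separability_check <- function(table, feature_pair) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$response)) stop("table must carry a binary response")
  if (!length(feature_pair) %in% 1:2) stop("feature_pair must name 1 or 2 features")
  y <- table$response
  if (length(unique(y)) < 2) stop("both response classes must be present")
  X <- table$grades[, feature_pair, drop = FALSE]
  A <- X[y == 1, , drop = FALSE]
  B <- X[y == 0, , drop = FALSE]
  if (length(feature_pair) == 1) {
    gap <- max(min(A) - max(B), min(B) - max(A))
    return(list(separable = gap > 0, margin = max(gap, 0) / 2))
  }
  sep <- !hulls_intersect(A, B)
  list(separable = sep, margin = if (sep) hull_distance(A, B) / 2 else 0)
}

# ---- internal: 2-D convex-hull geometry ------------------------------------

hull_points <- function(P) {
  P <- unique(P)
  if (nrow(P) <= 2) return(P)
  P[grDevices::chull(P[, 1], P[, 2]), , drop = FALSE]
}

hulls_intersect <- function(A, B) {
  ha <- hull_points(A); hb <- hull_points(B)
  if (any(points_in_hull(ha, hb)) || any(points_in_hull(hb, ha))) return(TRUE)
  ea <- hull_edges(ha); eb <- hull_edges(hb)
  for (i in seq_len(nrow(ea$p))) {
    for (j in seq_len(nrow(eb$p))) {
      if (segments_cross(ea$p[i, ], ea$q[i, ], eb$p[j, ], eb$q[j, ]))
        return(TRUE)
    }
  }
  FALSE
}

hull_edges <- function(h) {
  n <- nrow(h)
  if (n == 1) return(list(p = h, q = h))
  list(p = h, q = h[c(2:n, 1), , drop = FALSE])
}

points_in_hull <- function(pts, hull) {
  n <- nrow(hull)
  if (n == 1)
    return(apply(pts, 1, function(p) all(p == hull[1, ])))
  if (n == 2)
    return(apply(pts, 1, function(p) point_on_segment(p, hull[1, ], hull[2, ])))
  apply(pts, 1, function(p) {
    s <- vapply(seq_len(n), function(i) {
      a <- hull[i, ]; b <- hull[if (i == n) 1 else i + 1, ]
      cross2(b - a, p - a)
    }, numeric(1))
    all(s >= -1e-9) || all(s <= 1e-9)
  })
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

point_on_segment <- function(p, a, b) {
  if (abs(cross2(b - a, p - a)) > 1e-9) return(FALSE)
  all(p >= pmin(a, b) - 1e-9) && all(p <= pmax(a, b) + 1e-9)
}

segments_cross <- function(p1, q1, p2, q2) {
  d1 <- cross2(q2 - p2, p1 - p2)
  d2 <- cross2(q2 - p2, q1 - p2)
  d3 <- cross2(q1 - p1, p2 - p1)
  d4 <- cross2(q1 - p1, q2 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && point_on_segment(p1, p2, q2)) ||
    (d2 == 0 && point_on_segment(q1, p2, q2)) ||
    (d3 == 0 && point_on_segment(p2, p1, q1)) ||
    (d4 == 0 && point_on_segment(q2, p1, q1))
}

# minimum distance between two disjoint convex hulls
hull_distance <- function(A, B) {
  ha <- hull_points(A); hb <- hull_points(B)
  ea <- hull_edges(ha); eb <- hull_edges(hb)
  d <- Inf
  for (i in seq_len(nrow(ha)))
    for (j in seq_len(nrow(eb$p)))
      d <- min(d, point_segment_distance(ha[i, ], eb$p[j, ], eb$q[j, ]))
  for (i in seq_len(nrow(hb)))
    for (j in seq_len(nrow(ea$p)))
      d <- min(d, point_segment_distance(hb[i, ], ea$p[j, ], ea$q[j, ]))
  d
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}
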