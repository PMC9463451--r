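test_that("LOOCV classifies a cleanly separable table perfectly", {
  r <- loocv_linear_classifier(separable_table(), "til")
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
  expect_identical(nrow(r$oob_predictions), 12L)

  # metrics recomputable from the stored out-of-bag predictions
  oob <- r$oob_predictions
  ok <- !is.na(oob$class)
  expect_equal(r$accuracy, mean(oob$class[ok] == oob$response[ok]))
  n_pos <- sum(oob$response == 1); n_neg <- sum(oob$response == 0)
  expect_equal(r$accuracy,
               (r$sensitivity * n_pos + r$specificity * n_neg) / 12)
})

test_that("LOOCV validates inputs and degenerate folds", {
  small <- feature_table(cbind(f = c(0L, 1L, 2L)), response = c(0L, 1L, 0L))
  expect_error(loocv_linear_classifier(small, "f"), "at least 4")
  onecls <- feature_table(cbind(f = c(0L, 1L, 2L, 3L)),
                          response = rep(1L, 4))
  expect_error(loocv_linear_classifier(onecls, "f"), "both")
  tb <- separable_table()
  expect_error(loocv_linear_classifier(tb, "absent"), "not in table")

  # a lone member of one class makes its fold degenerate -> warning
  lone <- feature_table(cbind(f = c(3L, 0L, 1L, 0L, 2L)),
                        response = c(1L, 0L, 0L, 0L, 0L))
  expect_warning(r <- loocv_linear_classifier(lone, "f"), "skipped")
  expect_true(is.na(r$oob_predictions$class[1]))
})

test_that("a feature independent of the labels scores near chance", {
  set.seed(9)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  X <- matrix(sample(0:3, n, TRUE), ncol = 1, dimnames = list(NULL, "f"))
  r <- loocv_linear_classifier(feature_table(X, response = y), "f")
  majority <- max(mean(y), 1 - mean(y))
  expect_lt(abs(r$accuracy - majority), 0.1)
})

test_that("AIC follows the fixed Gaussian OLS convention", {
  # closed-form check on a 6-point dataset
  tb <- feature_table(cbind(f = c(0L, 1L, 2L, 3L, 2L, 0L)),
                      response = c(0L, 0L, 1L, 1L, 1L, 0L))
  fit <- lm(y ~ f, data.frame(y = tb$response, f = tb$grades[, "f"]))
  rss <- sum(residuals(fit)^2)
  expect_equal(aic_ols(tb, "f"), 6 * log(rss / 6) + 2 * (1 + 2))

  # appending an orthogonal useless predictor adds exactly 2
  y <- rep(c(1L, 0L), each = 6)
  f1 <- c(3L, 2L, 3L, 3L, 2L, 3L, 0L, 1L, 0L, 0L, 1L, 0L)
  f2 <- rep(c(0L, 3L), 6) # balanced within classes and against f1
  tb2 <- feature_table(cbind(f1 = f1, f2 = f2), response = y)
  expect_equal(aic_ols(tb2, c("f1", "f2")) - aic_ols(tb2, "f1"), 2)

  dup <- feature_table(cbind(a = f1, b = f1), response = y)
  expect_error(aic_ols(dup, c("a", "b")), "singular")
  perfect <- feature_table(cbind(f = c(0L, 0L, 1L, 1L)),
                           response = c(0L, 0L, 1L, 1L))
  expect_error(aic_ols(perfect, "f"), "RSS = 0")
})

test_that("forward selection finds planted signal and is deterministic", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 24
    y <- rep(0:1, each = n / 2)
    X <- matrix(sample(0:3, n * 6, TRUE), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    X[, 4] <- pmin(3, pmax(0, y * 2 + sample(0:1, n, TRUE)))
    tb <- feature_table(X, response = y)
    fs <- forward_select(tb, colnames(X), mode = "specificity_first",
                         max_features = 2)
    if (fs[[1]]$selected_features == "f4") hits <- hits + 1
    # deterministic given table and mode
    fs2 <- forward_select(tb, colnames(X), mode = "specificity_first",
                          max_features = 2)
    expect_identical(lapply(fs, `[[`, "selected_features"),
                     lapply(fs2, `[[`, "selected_features"))
  }
  expect_gte(hits, 9)
})

test_that("specificity-first and AIC-first modes can disagree", {
  X <- matrix(c(2, 2, 2, 2, 1, 0, 3, 0, 3, 2, 3, 3,
                3, 0, 1, 1, 3, 3, 2, 1, 0, 3, 2, 0,
                0, 2, 3, 3, 1, 0, 0, 1, 1, 1, 1, 0), 12, 3,
              dimnames = list(NULL, c("fa", "fb", "fc")))
  tb <- feature_table(X, response = rep(c(1L, 0L), each = 6))
  first_spec <- forward_select(tb, colnames(X), mode = "specificity_first",
                               max_features = 1)[[1]]$selected_features
  first_aic <- forward_select(tb, colnames(X), mode = "aic_first",
                              max_features = 1)[[1]]$selected_features
  expect_false(first_spec == first_aic)
})

test_that("forward selection results have Table-3-like shape", {
  g <- generate_feature_table(13, list(
    list(mean = c(0.5, 0.5, 0.5, 2.5, 2.5, 2.5), n = 7, response_prob = 0.9),
    list(mean = c(2.5, 2.5, 2.5, 2.5, 2.5, 2.5), n = 6, response_prob = 0.1)),
    noise_sd = 0.4, seed = 2)
  fs <- forward_select(g$table, g$table$feature_names,
                       mode = "specificity_first", max_features = 2)
  expect_lte(length(fs), 2)
  for (r in fs) {
    expect_true(all(c("selected_features", "sensitivity", "specificity",
                      "accuracy", "aic") %in% names(r)))
    expect_true(is.data.frame(attr(r, "selection_trace")))
  }
  expect_identical(length(fs[[1]]$selected_features), 1L)
  if (length(fs) == 2) expect_identical(length(fs[[2]]$selected_features), 2L)
})

test_that("linear separability is decided exactly in 1-D and 2-D", {
  oned <- feature_table(cbind(v = c(0L, 0L, 1L, 3L, 3L, 2L)),
                        response = c(0L, 0L, 0L, 1L, 1L, 1L))
  s1 <- separability_check(oned, "v")
  expect_true(s1$separable)
  expect_equal(s1$margin, 0.5)

  interleaved <- feature_table(cbind(v = c(0L, 1L, 2L, 3L)),
                               response = c(0L, 1L, 0L, 1L))
  expect_false(separability_check(interleaved, "v")$separable)

  # XOR layout is not linearly separable
  Xx <- rbind(c(0L, 0L), c(3L, 3L), c(0L, 3L), c(3L, 0L),
              c(0L, 0L), c(3L, 3L), c(0L, 3L), c(3L, 0L))
  colnames(Xx) <- c("a", "b")
  xor <- feature_table(Xx, response = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
  sx <- separability_check(xor, c("a", "b"))
  expect_false(sx$separable)
  expect_equal(sx$margin, 0)

  # separable 2-D band
  Xs <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(3L, 3L), c(2L, 3L), c(3L, 2L))
  colnames(Xs) <- c("a", "b")
  band <- feature_table(Xs, response = c(0L, 0L, 0L, 1L, 1L, 1L))
  sb <- separability_check(band, c("a", "b"))
  expect_true(sb$separable)
  expect_gt(sb$margin, 0)
})
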