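test_that("planted phenotype clusters are recovered exactly", {
  g <- generate_feature_table(27, three_cluster_spec(), noise_sd = 0.3,
                              seed = 2)
  m <- fit_phenotype_model(g$table)
  expect_identical(m$n_clusters, 3L)
  expect_equal(mclust::adjustedRandIndex(m$cluster_of_sample,
                                         g$truth$cluster_of_sample), 1)
  # loadings orthonormal, eigenvalues non-increasing, >= 95% retained
  L <- m$loadings
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-8))
  expect_gte(sum(m$eigenvalues[seq_len(m$n_retained)]) / sum(m$eigenvalues),
             0.95)
})

test_that("rank-2 tables need exactly 2 components", {
  set.seed(3)
  a <- sample(0:3, 24, TRUE); b <- sample(0:3, 24, TRUE)
  g <- feature_table(cbind(f1 = a, f2 = b, f3 = a, f4 = b))
  m <- fit_phenotype_model(g)
  expect_identical(m$n_retained, 2L)
  expect_equal(sum(m$eigenvalues[1:2]) / sum(m$eigenvalues), 1,
               tolerance = 1e-10)
})

test_that("forced cluster counts and input validation work", {
  g <- generate_feature_table(13, list(
    list(mean = c(0.2, 0.4, 0.3, 2.6, 2.8, 2.7), n = 7, response_prob = 0.8),
    list(mean = c(2.8, 2.6, 2.7, 2.6, 2.8, 2.7), n = 6, response_prob = 0.2)),
    noise_sd = 0.4, seed = 1)
  m <- fit_phenotype_model(g$table, n_clusters = 2)
  expect_identical(m$n_clusters, 2L)

  flat <- feature_table(cbind(f1 = rep(1L, 6), f2 = c(0L, 1L, 2L, 3L, 0L, 1L)))
  expect_error(fit_phenotype_model(flat), "f1")
  expect_error(fit_phenotype_model(feature_table(cbind(f1 = 0:2, f2 = 2:0))),
               "at least 4")
})

test_that("variable contributions sum to 100 and flag dominant features", {
  g <- generate_feature_table(27, three_cluster_spec(), noise_sd = 0.3,
                              seed = 4)
  m <- fit_phenotype_model(g$table)
  for (c in seq_len(m$n_retained))
    expect_equal(sum(variable_contributions(m, c)), 100)
  expect_error(variable_contributions(m, m$n_retained + 1), "retained")

  # an independent lone feature dominates one component almost entirely
  set.seed(9)
  block <- sample(0:3, 40, TRUE)
  lone <- sample(0:3, 40, TRUE)
  tab <- feature_table(cbind(b1 = block,
                             b2 = pmin(3L, pmax(0L, block + sample(c(-1L, 0L, 1L), 40, TRUE, c(.1, .8, .1)))),
                             b3 = block, lone = lone))
  mm <- fit_phenotype_model(tab, n_clusters = 2, variance_retained = 0.99)
  contr <- vapply(seq_len(mm$n_retained),
                  function(c) variable_contributions(mm, c)["lone"], numeric(1))
  expect_gt(max(contr), 90)

  # two exactly-uncorrelated equal-variance features: coordinate axes,
  # each feature carries one component entirely
  u <- rep(0:3, each = 4); v <- rep(0:3, times = 4)
  t2 <- feature_table(cbind(u = u, v = v))
  m2 <- fit_phenotype_model(t2, n_clusters = 2, variance_retained = 1)
  c1 <- variable_contributions(m2, 1)
  c2 <- variable_contributions(m2, 2)
  expect_gt(max(c1), 99)
  expect_gt(max(c2), 99)
  expect_false(names(which.max(c1)) == names(which.max(c2)))
})

test_that("Inflam/Vasc axis naming labels all four planted corners", {
  g <- generate_feature_table(32, four_corner_spec(), noise_sd = 0.3, seed = 3)
  m <- assign_phenotype_labels(fit_phenotype_model(g$table, n_clusters = 4))
  labs <- m$cluster_labels[m$cluster_of_sample[c(1, 9, 17, 25)]]
  expect_identical(labs, c("Inflam^LOW Vasc^HIGH", "Inflam^HIGH Vasc^LOW",
                           "Inflam^HIGH Vasc^HIGH", "Inflam^LOW Vasc^LOW"))
  expect_true(m$vascular_axis != m$inflammation_axis)

  expect_error(assign_phenotype_labels(m, vascular_features = "trafficking",
                                       inflammation_features = "trafficking"),
               "disjoint")
  expect_error(assign_phenotype_labels(m, vascular_features = "no_such"),
               "not in model")
})

test_that("coupled feature blocks refuse automatic axis naming", {
  # a vascular and an inflammation feature that are identical copies share
  # PC1; an independent third feature owns the other component
  set.seed(6)
  u <- sample(0:3, 24, TRUE)
  x <- sample(0:3, 24, TRUE)
  tab <- feature_table(cbind(trafficking = u, intratumor_inflammation = u,
                             mucin = x))
  m <- fit_phenotype_model(tab, n_clusters = 2)
  expect_error(
    assign_phenotype_labels(m, vascular_features = "trafficking",
                            inflammation_features = "intratumor_inflammation"),
    "same component")
})

test_that("projection reproduces training scores and nearest centroids", {
  g <- generate_feature_table(32, four_corner_spec(), noise_sd = 0.3, seed = 5)
  m <- assign_phenotype_labels(fit_phenotype_model(g$table, n_clusters = 4))
  pr <- project_samples(m, g$table)
  expect_equal(as.matrix(pr[, 2:(1 + m$n_retained)]), unname(m$scores),
               ignore_attr = TRUE)
  expect_identical(pr$cluster, unname(m$cluster_of_sample))
  expect_identical(pr$label, m$cluster_labels[m$cluster_of_sample])

  # a sample equal to a cluster's planted mean lands in that cluster
  proto <- feature_table(matrix(c(3L, 3L, 3L, 0L, 0L, 0L), 1,
                                dimnames = list("p", canonical_time_features())))
  pp <- project_samples(m, proto)
  expect_identical(pp$label, "Inflam^LOW Vasc^HIGH")

  missing <- feature_table(cbind(number_of_vessels = c(0L, 3L)))
  expect_error(project_samples(m, missing), "lacks")
})

test_that("cluster structure is invariant to row and column order", {
  g <- generate_feature_table(27, three_cluster_spec(), noise_sd = 0.3,
                              seed = 7)
  m <- fit_phenotype_model(g$table)
  set.seed(11)
  perm <- sample(27)
  cols <- sample(6)
  shuffled <- feature_table(g$table$grades[perm, cols],
                            sample_ids = g$table$sample_ids[perm])
  m2 <- fit_phenotype_model(shuffled)
  expect_identical(m2$n_clusters, m$n_clusters)
  expect_equal(mclust::adjustedRandIndex(m2$cluster_of_sample,
                                         m$cluster_of_sample[perm]), 1)
})

test_that("retained components reconstruct the standardized data", {
  g <- generate_feature_table(27, three_cluster_spec(), noise_sd = 0.3,
                              seed = 8)
  m <- fit_phenotype_model(g$table)
  Z <- scale(g$table$grades)
  recon <- m$scores %*% t(m$loadings[, seq_len(m$n_retained), drop = FALSE])
  err <- sum((Z - recon)^2)
  discarded <- sum(m$eigenvalues[-seq_len(m$n_retained)]) * (27 - 1)
  expect_lte(err, discarded + 1e-8)
})
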