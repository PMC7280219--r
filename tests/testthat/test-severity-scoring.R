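test_that("standardization yields zero mean and unit population variance", {
  s <- standardizeFeatures(cbind(a = c(1, 2, 3), b = c(10, 0, 5)))
  expect_equal(unname(s$scaled[, "a"]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(unname(colMeans(s$scaled)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(s$scaled, 2, function(x) mean(x^2))), c(1, 1),
               tolerance = 1e-10)
  # idempotence on already-standardized data
  s2 <- standardizeFeatures(s$scaled)
  expect_equal(s2$scaled, s$scaled, tolerance = 1e-10)
  # a constant column is degenerate and must be named
  expect_error(standardizeFeatures(cbind(ok = 1:4, flat = rep(2, 4))),
               "flat", class = "flim_degenerate_feature")
})

test_that("PCA satisfies its spectral identities and the eigen oracle", {
  set.seed(20)
  for (rep in 1:3) {
    x <- matrix(rnorm(10 * 8), 10, 8) %*% diag(runif(8, 0.5, 3))
    colnames(x) <- paste0("f", 1:8)
    m <- fitSeverityModel(x)
    rot <- rotationMatrix(m)
    expect_equal(crossprod(rot), diag(8), tolerance = 1e-8,
                 ignore_attr = TRUE)
    evr <- explainedVarianceRatio(m)
    expect_equal(sum(evr), 1, tolerance = 1e-8)
    expect_true(all(diff(evr) <= 1e-12))
    # brute-force covariance eigendecomposition oracle
    z <- standardizeFeatures(x)$scaled
    eig <- eigen(crossprod(z) / nrow(z), symmetric = TRUE)
    expect_equal(evr, eig$values / sum(eig$values), tolerance = 1e-8)
    for (k in 1:8)
      expect_equal(abs(sum(rot[, k] * eig$vectors[, k])), 1,
                   tolerance = 1e-6)
  }
})

test_that("correlated bivariate data gives the closed-form PC1 ratio", {
  # for a standardized pair with correlation rho, PC1 explains (1 + rho)/2
  set.seed(21)
  n <- 40000
  x <- rnorm(n)
  y <- 0.8 * x + 0.6 * rnorm(n)
  m <- fitSeverityModel(cbind(x = x, y = y))
  expect_equal(explainedVarianceRatio(m)[1], 0.9, tolerance = 0.01)

  # rank-1 case: duplicated column
  v <- rnorm(6)
  m1 <- fitSeverityModel(cbind(a = v, b = v))
  expect_equal(explainedVarianceRatio(m1)[1], 1.0)
})

test_that("PC1 orientation makes severity increase along the group order", {
  set.seed(22)
  n <- 30
  lab <- rep(c("control", "psoriasis"), each = n)
  sev <- ifelse(lab == "psoriasis", 1, 0) + rnorm(2 * n, sd = 0.3)
  tab <- data.frame(f1 = -2 * sev + rnorm(2 * n, sd = 0.1),
                    f2 = -sev + rnorm(2 * n, sd = 0.1),
                    f3 = rnorm(2 * n))
  m <- orientPC1(fitSeverityModel(tab), tab, lab)
  sc <- severityScore(m, tab)
  expect_gt(mean(sc[lab == "psoriasis"]), mean(sc[lab == "control"]))

  # sign gauge: negating all loadings then re-orienting gives identical scores
  m_neg <- m
  m_neg@rotation <- -m_neg@rotation
  m_neg <- orientPC1(m_neg, tab, lab)
  expect_equal(severityScore(m_neg, tab), sc, tolerance = 1e-10)

  # single-group labels: warning path, sign stays +1
  expect_warning(m1 <- orientPC1(fitSeverityModel(tab), tab,
                                 rep("control", 2 * n)),
                 class = "flim_no_labels")
  expect_equal(m1@pc1_sign, 1)
})

test_that("feature-loading orientation fixes the severity axis sign", {
  set.seed(23)
  tab <- data.frame(dist_SG_SB_inflamed_um = rnorm(20, 60, 5),
                    other = rnorm(20))
  tab$other <- -0.9 * tab$dist_SG_SB_inflamed_um + rnorm(20)
  m <- orientPC1ByFeature(fitSeverityModel(tab))
  expect_gte(m@pc1_sign * rotationMatrix(m)["dist_SG_SB_inflamed_um", 1], 0)
  expect_error(orientPC1ByFeature(fitSeverityModel(tab), "absent"),
               class = "flim_schema_mismatch")
})

test_that("projection is consistent, centred and schema-checked", {
  set.seed(24)
  tab <- as.data.frame(matrix(rnorm(15 * 4), 15, 4))
  colnames(tab) <- paste0("f", 1:4)
  m <- fitSeverityModel(tab)
  sc <- projectScores(m, tab)
  # the training mean vector scores exactly 0
  expect_equal(unname(projectScores(m, colMeans(tab))[1, ]), rep(0, 4),
               tolerance = 1e-10)
  # re-projection reproduces fit-time scores
  expect_equal(projectScores(m, tab), sc, tolerance = 1e-8)
  # linearity in the oriented score
  expect_equal(unname(severityScore(m, tab[3, ])), unname(sc[3, 1]),
               tolerance = 1e-10)
  expect_error(projectScores(m, tab[, 1:3]), class = "flim_schema_mismatch")
})

test_that("pearsonR matches hand-computed correlations and validates input", {
  expect_equal(pearsonR(1:10, 1:10), 1.0)
  expect_equal(pearsonR(1:10, -(1:10)), -1.0)
  expect_equal(pearsonR(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearsonR(1:5, rep(1, 5)),
               class = "flim_undefined_correlation")
  expect_error(pearsonR(1:2, 1:2), class = "flim_invalid_config")
})

test_that("group separation reflects cluster structure", {
  set.seed(25)
  n <- 20
  well <- rbind(matrix(rnorm(2 * n, 0, 0.2), ncol = 2),
                matrix(rnorm(2 * n, 5, 0.2), ncol = 2))
  lab <- rep(c("a", "b"), each = n)
  sep <- groupSeparation(well, lab)
  expect_gt(sep$mean_silhouette, 0.5)
  expect_gt(sep$pc1_gaps["b", "a"], 4)

  # identical distributions: no structure
  none <- matrix(rnorm(4 * n), ncol = 2)
  expect_lt(abs(groupSeparation(none, lab)$mean_silhouette), 0.15)

  # shuffled labels on the separated data destroy the structure
  sep_shuf <- groupSeparation(well, sample(lab))
  expect_lt(sep_shuf$mean_silhouette, sep$mean_silhouette / 2)

  expect_warning(groupSeparation(well, c("solo", lab[-1])),
                 class = "flim_singleton_group")
})
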