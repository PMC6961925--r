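test_that("rarefaction matches hand value, endpoints and monotonicity", {
  f <- incidence_freqs(c(3, 1), T = 3)
  expect_equal(rarefy_incidence(f, 2), 5 / 3)
  expect_equal(rarefy_incidence(f, 3), 2) # t = T recovers observed richness
  expect_error(rarefy_incidence(f, 4), "no extrapolation")
  set.seed(5)
  m <- random_unit_matrix(12, 20)
  fr <- freqs_of(m)
  s <- vapply(1:12, rarefy_incidence, numeric(1L), freqs = fr)
  expect_true(all(diff(s) >= -1e-12))
  expect_equal(s[12], length(fr$Y))
})

test_that("rarefaction equals the exhaustive-subset average (T <= 8)", {
  set.seed(6)
  for (i in 1:8) {
    T <- sample(3:8, 1L)
    m <- random_unit_matrix(T, sample(4:12, 1L))
    fr <- freqs_of(m)
    for (t in seq_len(T)) {
      expect_equal(rarefy_incidence(fr, t), rarefy_bruteforce(m, t),
                   tolerance = 1e-12)
    }
  }
})

test_that("Chao2 evaluates both branches and never drops below observed", {
  # no uniques: estimate equals observed richness
  expect_equal(chao2(incidence_freqs(c(2, 3, 5), T = 5)), 3)
  # classic branch: S=10, q1=4, q2=2, T=10 -> 13.6
  f <- incidence_freqs(c(rep(1, 4), rep(2, 2), rep(4, 4)), T = 10)
  expect_equal(chao2(f), 13.6)
  # bias-corrected branch: S=10, q1=3, q2=0, T=5 -> 12.4
  f <- incidence_freqs(c(rep(1, 3), rep(3, 7)), T = 5)
  expect_equal(chao2(f), 12.4)
  set.seed(8)
  for (i in 1:10) {
    m <- random_unit_matrix(sample(4:10, 1L), sample(5:15, 1L))
    fr <- freqs_of(m)
    expect_gte(chao2(fr), length(fr$Y))
  }
})

test_that("Chao2 agrees with vegan's estimator on q2 > 0 fixtures", {
  skip_if_not_installed("vegan")
  set.seed(9)
  tried <- 0L
  while (tried < 5L) {
    m <- random_unit_matrix(8, 15)
    fr <- freqs_of(m)
    if (sum(fr$Y == 2) == 0L) next
    tried <- tried + 1L
    expect_equal(chao2(fr), vegan::specpool(m)$chao, tolerance = 1e-10)
  }
})

test_that("knn spatial weights symmetrize and row-standardize", {
  W <- build_spatial_weights(cbind(c(0, 1, 2), 0), k = 1)
  expect_equal(W$W[2, ], c(0.5, 0, 0.5)) # middle site keeps both ends
  expect_equal(unname(rowSums(W$W)), rep(1, 3))
  expect_error(build_spatial_weights(cbind(c(0, 0, 1), c(0, 0, 1)), k = 1),
               "duplicate")
  # generator-scale layout: every site has at least k neighbours
  set.seed(10)
  xy <- cbind(rep(1:9, each = 4) * 2500 + runif(36, 0, 3000),
              runif(36, 0, 200))
  W <- build_spatial_weights(xy, k = 4)
  expect_true(all(colSums(W$W > 0) >= 4))
})

test_that("Moran's I reproduces the rook-line hand value and ape's statistic", {
  W <- build_spatial_weights(cbind(c(0, 1, 2), 0), k = 1)
  m <- morans_i(c(0, 0, 1), W, n_perm = 199, seed = 1)
  expect_equal(m$I, -0.25)
  expect_equal(m$expectation, -0.5)
  skip_if_not_installed("ape")
  set.seed(11)
  xy <- cbind(runif(20), runif(20))
  vals <- rnorm(20)
  W <- build_spatial_weights(xy, k = 4)
  m <- morans_i(vals, W, n_perm = 99, seed = 2)
  expect_equal(m$I, ape::Moran.I(vals, W$W)$observed, tolerance = 1e-10)
})

test_that("Moran's I permutation null centres on -1/(n-1) and detects gradients", {
  set.seed(12)
  xy <- cbind(rep(1:9, each = 4) * 2500 + runif(36, 300, 3300),
              runif(36, 0, 200))
  W <- build_spatial_weights(xy, k = 4)
  grad <- morans_i(xy[, 1] / 1000 + rnorm(36, 0, 0.5), W,
                   n_perm = 999, seed = 13)
  expect_gt(grad$I, 0)
  expect_lt(grad$p_value, 0.05)
  expect_lt(abs(grad$perm_mean - (-1 / 35)), 0.02)
  expect_error(morans_i(rep(1, 36), W), "zero variance")
})

test_that("Poisson fits recover closed forms and the GLM nests in the GLMM", {
  d <- data.frame(y = c(2, 4, 6))
  f <- fit_count_model(d, "y")
  expect_equal(unname(coef(f)), log(4), tolerance = 1e-6)
  expect_equal(f$deviance, -2 * f$loglik)
  expect_equal(f$AICc, -2 * f$loglik + 2 * f$k +
                 2 * f$k * (f$k + 1) / (f$n - f$k - 1))
  # a GLMM whose random-intercept variance collapses to zero matches the GLM
  set.seed(14)
  d <- data.frame(y = rpois(40, 8), x = rnorm(40),
                  g = rep(letters[1:8], each = 5))
  glm_fit <- fit_count_model(d, "y", "x")
  glmm_fit <- fit_count_model(d, "y", "x", random_intercept = "g")
  if (glmm_fit$random_variance < 1e-8) {
    expect_equal(unname(coef(glmm_fit)), unname(coef(glm_fit)),
                 tolerance = 1e-4)
  }
  # non-integer responses keep a finite quasi-likelihood and are flagged
  d$y <- d$y + 0.5
  q <- fit_count_model(d, "y", "x", random_intercept = "g")
  expect_true(is.finite(q$AICc))
  expect_true(any(grepl("non-integer response", q$notes)))
})

test_that("AICc converges to AIC as n grows on the same model family", {
  set.seed(15)
  gap <- vapply(c(20, 200, 2000), function(n) {
    d <- data.frame(y = rpois(n, 5), x = rnorm(n))
    f <- fit_count_model(d, "y", "x")
    f$AICc - f$AIC
  }, numeric(1L))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})

test_that("model comparison sorts by AICc and enforces comparability", {
  set.seed(16)
  mat_z <- rep(scale(9:1), each = 4)
  d <- data.frame(y = rpois(36, exp(2.5 + 0.6 * mat_z)),
                  mat = rep(seq(24, 12, by = -1.5), each = 4),
                  hab = rnorm(36),
                  band = rep(1:9, each = 4))
  f1 <- fit_count_model(d, "y", "mat", random_intercept = "band")
  f2 <- fit_count_model(d, "y", c("mat", "hab"), random_intercept = "band")
  f3 <- fit_count_model(d, "y", "hab", random_intercept = "band")
  cmp <- compare_models(climate = f1, both = f2, habitat = f3)
  expect_equal(cmp$delta_AICc[1L], 0)
  expect_true(!is.unsorted(cmp$AICc))
  # nested models: the larger model's deviance cannot exceed the smaller's
  expect_lte(f2$deviance, f1$deviance + 1e-6)
  # single model comparison is a one-row table
  expect_equal(nrow(compare_models(only = f1)), 1L)
  bad <- fit_count_model(d[1:20, ], "y", "mat")
  expect_error(compare_models(f1, bad), "sample size")
})

test_that("temperature-driven models win AICc over habitat-only models", {
  set.seed(17)
  wins <- 0L
  n_trials <- 40L
  mat <- rep(seq(24, 12, by = -1.5), each = 4)
  mat_z <- as.numeric(scale(mat))
  for (i in seq_len(n_trials)) {
    d <- data.frame(y = rpois(36, exp(2.5 + 0.6 * mat_z)),
                    mat = mat, hab = rnorm(36), band = rep(1:9, each = 4))
    f_clim <- fit_count_model(d, "y", "mat", random_intercept = "band")
    f_hab <- fit_count_model(d, "y", "hab", random_intercept = "band")
    if (f_clim$AICc < f_hab$AICc) wins <- wins + 1L
  }
  expect_gte(wins / n_trials, 0.9)
})

test_that("regressing out the elevational trend shrinks residual autocorrelation", {
  set.seed(18)
  mat <- rep(seq(24, 12, by = -1.5), each = 4)
  mat_z <- as.numeric(scale(mat))
  xy <- cbind(rep(1:9, each = 4) * 2500 + runif(36, 300, 3300),
              runif(36, 0, 200))
  W <- build_spatial_weights(xy, k = 4)
  elev <- rep(seq(600, 2200, by = 200), each = 4)
  drops <- vapply(1:10, function(i) {
    y <- rpois(36, exp(2.5 + 0.6 * mat_z))
    if (var(y) == 0) return(NA_real_)
    raw <- morans_i(y, W, n_perm = 199, seed = 100 + i)
    res <- residuals(glm(y ~ elev, family = poisson()), type = "deviance")
    red <- morans_i(res, W, n_perm = 199, seed = 200 + i)
    raw$std_deviate - red$std_deviate
  }, numeric(1L))
  expect_gt(mean(drops, na.rm = TRUE), 0)
})
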