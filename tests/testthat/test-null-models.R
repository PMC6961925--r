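test_that("placement enumeration matches hand-derived cases", {
  g <- grid5()
  # forced placement: size equals domain length
  pl <- enumerate_placements(5, null_model_spec(weighted = FALSE), g)
  expect_equal(pl$start, 1L)
  expect_equal(pl$prob, 1)
  # hard/hard uniform, size 3 on 5 bands
  pl <- enumerate_placements(3, null_model_spec(weighted = FALSE), g)
  expect_equal(pl$start, 1:3)
  expect_equal(pl$prob, rep(1 / 3, 3))
  expect_equal(placement_coverage(pl), c(1, 2, 3, 2, 1) / 3)
  # soft-low/hard-high uniform: low candidates clamp onto the edge block
  spec <- null_model_spec(weighted = FALSE,
                          boundary = boundary_policy("soft", "hard"))
  pl <- enumerate_placements(3, spec, g)
  expect_equal(pl$start, 1:3)
  expect_equal(pl$prob, c(0.5, 0.25, 0.25))
  expect_equal(placement_coverage(pl), c(0.5, 0.75, 1, 0.5, 0.25))
  # infeasible: size above a hard/hard domain
  expect_error(enumerate_placements(6, null_model_spec(weighted = FALSE), g),
               "between 1 and the domain length")
  # all-zero weights
  g0 <- grid5(weights = rep(0, 5))
  expect_error(enumerate_placements(2, null_model_spec(), g0), "weights")
})

test_that("placement probabilities normalize and conserve range length", {
  set.seed(11)
  for (pol in all_policies()) {
    for (n in c(4L, 7L)) {
      w <- stats::runif(n, 0.5, 3)
      g <- band_grid(seq(600, by = 200, length.out = n), weights = w)
      for (weighted in c(TRUE, FALSE)) {
        spec <- null_model_spec(weighted = weighted, boundary = pol)
        for (s in seq_len(n)) {
          pl <- enumerate_placements(s, spec, g)
          expect_equal(sum(pl$prob), 1)
          # every placement is geometrically feasible
          expect_true(all(pl$start >= 1L & pl$start + s - 1L <= n))
          # coverage probabilities sum to the range size (length conserved)
          expect_equal(sum(placement_coverage(pl)), s)
        }
      }
    }
  }
})

test_that("weighting multiplies candidate midpoints by their band weight", {
  g <- grid5(weights = c(4, 2, 1, 1, 2))
  pl <- enumerate_placements(3, null_model_spec(), g)
  # feasible midpoints 2,3,4 with weights 2,1,1
  expect_equal(pl$prob, c(2, 1, 1) / 4)
  # soft-low adds midpoint 1 (weight 4) clamped onto start 1
  pl <- enumerate_placements(
    3, null_model_spec(boundary = boundary_policy("soft", "hard")), g)
  expect_equal(pl$prob, c(6, 1, 1) / 8)
})

test_that("uniform hard/hard cohesion yields a symmetric unimodal mid-domain hump", {
  for (n in c(5L, 8L)) {
    g <- band_grid(seq(600, by = 200, length.out = n))
    spec <- null_model_spec(weighted = FALSE)
    sizes <- rep(1:(n - 1L), times = 2L)
    er <- as.numeric(expected_richness(NULL, spec, g, sizes = sizes))
    expect_equal(er, rev(er))
    d <- diff(er)
    expect_true(all(d[seq_len(floor((n - 1) / 2))] >= -1e-12))
    expect_true(all(d[seq.int(ceiling((n + 1) / 2), n - 1L)] <= 1e-12))
  }
})

test_that("softening the low boundary never lowers expected richness at the lowest band", {
  set.seed(21)
  for (n in c(5L, 8L)) {
    g <- band_grid(seq(600, by = 200, length.out = n))
    sizes <- sample.int(n, 30, replace = TRUE)
    hard <- expected_richness(NULL, null_model_spec(weighted = FALSE), g,
                              sizes = sizes)
    soft <- expected_richness(
      NULL, null_model_spec(weighted = FALSE,
                            boundary = boundary_policy("soft", "hard")),
      g, sizes = sizes)
    expect_gte(soft[1L], hard[1L] - 1e-12)
  }
})

test_that("cohesive draws follow the enumerated placement distribution", {
  g <- grid5(weights = c(3, 2, 1, 2, 4))
  spec <- null_model_spec(boundary = boundary_policy("soft", "hard"))
  pl <- enumerate_placements(3, spec, g)
  set.seed(31)
  n_draw <- 20000L
  starts <- vapply(seq_len(n_draw),
                   function(i) draw_placement(3, spec, g)[1L], integer(1L))
  freq <- tabulate(starts, 5L)[pl$start] / n_draw
  se <- sqrt(pl$prob * (1 - pl$prob) / n_draw)
  expect_true(all(abs(freq - pl$prob) <= 3 * se + 1e-9))
  # blocks are contiguous with the requested size
  one <- draw_placement(4, spec, g)
  expect_equal(one, one[1L]:(one[1L] + 3L))
})

test_that("scatter draws hit every band at its expected frequency", {
  g <- grid5()
  spec <- null_model_spec(cohesion = FALSE, weighted = FALSE)
  set.seed(41)
  n_draw <- 10000L
  occ <- integer(5)
  for (i in seq_len(n_draw)) {
    b <- draw_placement(3, spec, g)
    expect_equal(length(unique(b)), 3L)
    occ[b] <- occ[b] + 1L
  }
  p <- 3 / 5
  se <- sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(occ / n_draw - p) <= 3 * se))
  expect_error(draw_placement(6, spec, g), "positive weight")
})

test_that("Monte-Carlo richness converges to the exact enumeration", {
  g <- band_grid(seq(600, by = 200, length.out = 6),
                 weights = c(5, 4, 3, 2.5, 2, 1.5))
  sizes <- c(1, 1, 2, 2, 3, 4, 5, 6)
  for (pol in all_policies()) {
    spec <- null_model_spec(weighted = TRUE, boundary = pol)
    er <- as.numeric(expected_richness(NULL, spec, g, sizes = sizes))
    nr <- simulate_null(NULL, spec, g, n_reps = 4000, seed = 51,
                        sizes = sizes)
    # per-band binomial-sum standard error across species placements
    se <- sqrt(pmax(er * 1e-4, apply(
      vapply(sizes, function(s)
        placement_coverage(enumerate_placements(s, spec, g)), numeric(6L)),
      1L, function(p) sum(p * (1 - p)))) / 4000)
    expect_true(all(abs(nr$mean - er) <= 3 * se + 1e-9),
                label = paste("policy", pol$low, pol$high))
    expect_true(all(nr$q025 <= nr$mean + 1e-12 & nr$mean <= nr$q975 + 1e-12))
  }
})

test_that("simulation is deterministic under a fixed seed and trivially exact", {
  g <- grid5()
  spec <- null_model_spec(weighted = FALSE)
  a <- simulate_null(NULL, spec, g, n_reps = 50, seed = 99,
                     sizes = c(2, 3, 4))
  b <- simulate_null(NULL, spec, g, n_reps = 50, seed = 99,
                     sizes = c(4, 2, 3)) # order must not matter
  expect_equal(a$mean, b$mean)
  expect_equal(a$q025, b$q025)
  # all species spanning the whole domain: species count, zero spread
  full <- simulate_null(NULL, spec, g, n_reps = 2, seed = 1,
                        sizes = c(5, 5, 5))
  expect_equal(full$mean, rep(3, 5))
  expect_equal(full$q025, rep(3, 5))
})

test_that("fill increment measures removed discontinuity", {
  g <- grid5()
  contig <- ranges_to_incidence(
    species_ranges(c("a", "b"), c(1, 3), c(3, 5), g))
  expect_equal(fill_increment(contig), 0)
  gappy <- incidence_matrix(cbind(c(1, 0, 0, 1, 0)), g, "sp")
  expect_equal(fill_increment(gappy), 1.0)
})

test_that("the matrix-fill SES separates cohesive from scattered communities", {
  g <- grid9()
  set.seed(61)
  # cohesive raw occupancy: observed increment 0, null increment > 0
  cfg <- synth_config(seed = 61)
  cm <- gen_community(cfg, g)
  raw <- crop_to_window(cm)$raw
  s <- ses_fill(raw, n_reps = 199, seed = 62)
  expect_lt(s$ses, -2)
  expect_equal(s$observed, 0)
  expect_gt(s$null_mean, 0)
  # determinism
  s2 <- ses_fill(raw, n_reps = 199, seed = 62)
  expect_equal(s$null, s2$null)
  # degenerate null: every species occupies a single band
  singles <- incidence_matrix(diag(1L, 5L), grid5(),
                              paste0("s", 1:5))
  d <- ses_fill(singles, n_reps = 100, seed = 1)
  expect_true(d$degenerate)
  expect_true(is.na(d$ses))
})

test_that("deviance-ratio R2 has the stated fixed points and sign semantics", {
  g <- grid9()
  set.seed(71)
  cfg <- synth_config(seed = 71)
  cm <- gen_community(cfg, g)
  obs <- band_richness(cm$raw)[window_bands(cm$raw$grid)]
  m1 <- simulate_null(cm$ranges, model_preset("model1", g), g,
                      n_reps = 400, seed = 72)
  m5 <- simulate_null(cm$ranges, model_preset("model5", g), g,
                      n_reps = 400, seed = 73)
  expect_equal(model_r2(obs, m1, m1), 0)
  expect_lte(model_r2(obs, m5, m1), 1)
  # candidate identical to observations scores 1: fake a perfect fit
  perfect <- m5
  perfect$mean[window_bands(perfect$domain)] <- obs
  expect_equal(model_r2(obs, perfect, m1), 1)
  # a grossly wrong candidate scores negative
  awful <- m5
  awful$mean[window_bands(awful$domain)] <- rev(obs) * 3
  expect_lt(model_r2(obs, awful, m1), 0)
})

test_that("the model suite compares presets against the designated null", {
  g <- grid9()
  set.seed(81)
  cfg <- synth_config(seed = 81)
  cm <- gen_community(cfg, g)
  obs <- band_richness(cm$raw)[window_bands(cm$raw$grid)]
  suite <- run_model_suite(cm$ranges, g, observed = obs,
                           models = c("model1", "model5"),
                           n_reps = 500, seed = 82)
  expect_equal(nrow(suite$table), 2L)
  expect_equal(suite$table$r2_vs_null[suite$table$model == "model1"], 0)
  # a suite must contain its designated null
  expect_error(run_model_suite(cm$ranges, g, observed = obs,
                               models = c("model2", "model3"),
                               n_reps = 200, seed = 1),
               "designated null")
  # same seed reproduces the whole table
  suite2 <- run_model_suite(cm$ranges, g, observed = obs,
                            models = c("model1", "model5"),
                            n_reps = 500, seed = 82)
  expect_equal(suite$table, suite2$table)
})
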