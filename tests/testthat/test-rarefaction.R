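make_small_survey <- function(seed = 40, plots_per_combo = 2) {
  cfg <- sim_config(n_species = 15, plots_per_combo = plots_per_combo, seed = seed)
  sim <- simulate_experiment(cfg)
  sim
}

test_that("curves label rarefied/observed/extrapolated ranges correctly", {
  sim <- make_small_survey()
  cur <- estimate_diversity(sim$survey, facets = "TD", q = c(0, 2),
                            t_max = 30, step = 2, B = 0)
  T_obs <- attr(cur, "T_obs")
  for (i in seq_len(nrow(T_obs))) {
    sub <- dplyr::filter(cur, assemblage == T_obs$assemblage[i])
    expect_true(all(sub$status[sub$t < T_obs$T_obs[i]] == "rarefied"))
    expect_true(all(sub$status[sub$t == T_obs$T_obs[i]] == "observed"))
    expect_true(all(sub$status[sub$t > T_obs$T_obs[i]] == "extrapolated"))
  }
  # q = 0 TD point estimates non-decreasing over the rarefaction range
  cur |>
    dplyr::filter(q == 0, status != "extrapolated") |>
    dplyr::group_by(assemblage) |>
    dplyr::summarise(mono = all(diff(estimate) >= -1e-9)) |>
    dplyr::pull(mono) |>
    all() |>
    expect_true()
})

test_that("a degenerate assemblage of identical units gives a flat q=2 curve and zero-width CIs", {
  X <- matrix(rep(c(1, 1, 0, 1, 0), each = 5), nrow = 5)
  m <- matrix_from_X(X)
  cur <- estimate_diversity(m, facets = "TD", q = c(0, 2), t_max = 5,
                            B = 20, seed = 2)
  q2 <- dplyr::filter(cur, q == 2)
  expect_true(all(abs(q2$estimate - q2$estimate[1]) < 1e-9))
  expect_true(all(abs(cur$ci_high - cur$ci_low) < 1e-9, na.rm = TRUE))
  expect_true(all(cur$ci_low <= cur$estimate + 1e-9 &
                    cur$estimate <= cur$ci_high + 1e-9, na.rm = TRUE))
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  sim <- make_small_survey(seed = 41)
  c1 <- estimate_diversity(sim$survey, facets = "TD", q = 0, t_max = 20,
                           step = 3, B = 15, seed = 99)
  c2 <- estimate_diversity(sim$survey, facets = "TD", q = 0, t_max = 20,
                           step = 3, B = 15, seed = 99)
  expect_identical(c1$ci_low, c2$ci_low)
  expect_identical(c1$ci_high, c2$ci_high)
  c3 <- estimate_diversity(sim$survey, facets = "TD", q = 0, t_max = 20,
                           step = 3, B = 15, seed = 100)
  expect_false(identical(c1$ci_low, c3$ci_low))
})

test_that("bootstrap_ci exposes the generic unit-resampling interface", {
  X <- withr::with_seed(42, random_X(8, 10))
  m <- matrix_from_X(X)
  est <- function(Xb) td_q0(restodiv:::.freqs_from_X(Xb), 1:5)
  ci <- bootstrap_ci(est, m, B = 30, seed = 5)
  expect_equal(nrow(ci), 5)
  expect_true(all(ci$ci_low <= ci$ci_high))
  ci2 <- bootstrap_ci(est, m, B = 30, seed = 5)
  expect_identical(ci, ci2)
  expect_error(bootstrap_ci(est, m, B = 1), "B must be")
})

test_that("bootstrap intervals achieve near-nominal coverage of the sampling expectation", {
  # known occupancy model: T = 25 units, graded occupancies; the target is
  # the true expected richness at t = 10 under binomial detection
  p <- seq(0.15, 0.7, length.out = 15)
  true_s10 <- sum(1 - (1 - p)^10)
  sims <- 100
  hits <- withr::with_seed(314, {
    vapply(seq_len(sims), function(s) {
      X <- matrix(rbinom(25 * 15, 1, rep(p, each = 25)), nrow = 25)
      X <- X[, colSums(X) > 0, drop = FALSE]
      m <- matrix_from_X(X)
      est <- function(Xb) td_q0(restodiv:::.freqs_from_X(Xb), 10)
      ci <- bootstrap_ci(est, m, B = 200, seed = s)
      ci$ci_low[1] <= true_s10 && true_s10 <= ci$ci_high[1]
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95 - 0.10)
})

test_that("full three-facet estimation returns the documented structure", {
  sim <- make_small_survey(seed = 43)
  d <- gower_distance(sim$truth$traits)
  cur <- estimate_diversity(sim$survey, tree = sim$tree, dist = d,
                            t_max = 25, step = 5, B = 5, seed = 1)
  expect_s3_class(cur, "restodiv_curve")
  expect_setequal(unique(cur$facet), c("TD", "PD", "FD"))
  expect_setequal(unique(cur$q), c(0, 2))
  expect_equal(dplyr::n_distinct(cur$assemblage), 4)
  # within facet, q = 2 never exceeds q = 0 at matched t over the
  # rarefied/observed range (in extrapolation the two nearly unbiased
  # estimators may cross within estimation error once richness saturates)
  wide <- cur |>
    dplyr::filter(status != "extrapolated") |>
    dplyr::select(assemblage, facet, q, t, estimate) |>
    tidyr::pivot_wider(names_from = q, values_from = estimate,
                       names_prefix = "q") |>
    dplyr::filter(!is.na(q2))
  expect_true(all(wide$q2 <= wide$q0 + 1e-9))
  expect_error(estimate_diversity(sim$survey, facets = "PD"), "needs `tree`")
  expect_error(estimate_diversity(sim$survey, facets = "FD"), "needs `dist`")
})

test_that("autoplot methods return ggplot objects", {
  sim <- make_small_survey(seed = 44)
  cur <- estimate_diversity(sim$survey, facets = "TD", q = c(0, 2),
                            t_max = 25, step = 5, B = 5, seed = 1)
  expect_s3_class(ggplot2::autoplot(cur), "ggplot")
  sc <- scale_estimates(cur)
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
  ef <- invasion_effects(sc)
  expect_s3_class(ggplot2::autoplot(ef), "ggplot")
  expect_s3_class(glance(cur), "tbl_df")
  expect_identical(tidy(ef), tibble::as_tibble(ef))
})
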