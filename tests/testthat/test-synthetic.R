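test_that("design layout matches the experimental arithmetic", {
  cfg <- sim_config(seed = 1)
  d <- generate_design(cfg)
  expect_equal(nrow(d$units), 320) # 4 combos x 8 plots x (9 + 1) units
  expect_equal(sum(d$units$kind == "surveyed_subplot"), 288)
  cfg1 <- sim_config(plots_per_combo = 1, include_perimeter = FALSE, seed = 1)
  expect_equal(nrow(generate_design(cfg1)$units), 36) # 4 x 1 x 9
  # determinism of the layout
  expect_identical(generate_design(cfg)$units, generate_design(cfg)$units)
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(sim_config(missing_frac = 1), "missing_frac")
})

test_that("degenerate occupancies produce saturated or fixed incidences", {
  cfg <- sim_config(
    n_species = 8, plots_per_combo = 2, occupancy_base = 1,
    suppression = c("control.early" = 1, "nutrients.early" = 1,
                    "control.late" = 1, "nutrients.late" = 1),
    invader_occupancy = c("control.early" = 1, "nutrients.early" = 1,
                          "control.late" = 1, "nutrients.late" = 1),
    plot_sd = 0, seed = 5
  )
  sim <- simulate_incidence(generate_design(cfg), cfg)
  f <- to_frequencies(sim)
  # every species in every surveyed unit; walks are all-zero (nothing missed)
  expect_true(all(f$Y == 72)) # 8 plots x 9 subplots per treatment... pooled: 4x2x9
  expect_equal(td_q0(to_frequencies(sim, treatment = "control.early"), 3), 8)
})

test_that("an always-present invader is detected in every unit of its treatment", {
  cfg <- sim_config(
    n_species = 10, plots_per_combo = 2, plot_sd = 0, seed = 6,
    include_perimeter = FALSE,
    invader_occupancy = c("control.early" = 1, "nutrients.early" = 1,
                          "control.late" = 0.2, "nutrients.late" = 0.2)
  )
  sim <- simulate_incidence(generate_design(cfg), cfg)
  for (tr in c("control.early", "nutrients.early")) {
    f <- to_frequencies(sim, treatment = tr)
    expect_equal(f$Y[f$species == "invader"], attr(f, "T"))
  }
})

test_that("mean per-unit richness matches the binomial expectation", {
  # plot_sd = 0, no perimeter: E[S per unit] = sum of occupancies
  occ <- seq(0.1, 0.9, length.out = 9)
  cfg <- sim_config(
    n_species = 10, plots_per_combo = 2, include_perimeter = FALSE,
    occupancy_base = occ, plot_sd = 0,
    suppression = c("control.early" = 1, "nutrients.early" = 1,
                    "control.late" = 1, "nutrients.late" = 1),
    invader_occupancy = c("control.early" = 0.5, "nutrients.early" = 0.5,
                          "control.late" = 0.5, "nutrients.late" = 0.5),
    seed = 1
  )
  design <- generate_design(cfg)
  expected <- sum(occ) + 0.5
  n_units <- nrow(design$units)
  sims <- 200
  means <- vapply(seq_len(sims), function(s) {
    m <- simulate_incidence(design, cfg, seed = 1000 + s)
    nrow(m$detections) / n_units
  }, numeric(1))
  se <- sd(means) / sqrt(sims)
  expect_lt(abs(mean(means) - expected), 3 * se + 1e-9)
})

test_that("simulated trees are ultrametric Yule trees of depth one", {
  tree <- generate_tree(20, seed = 3)
  depths <- ape::node.depth.edgelength(tree)[1:20]
  expect_true(all(abs(depths - 1) < 1e-9))
  cherry <- generate_tree(2, seed = 4)
  expect_equal(sort(cherry$edge.length), c(1, 1))
  expect_identical(ape::write.tree(generate_tree(9, seed = 7)),
                   ape::write.tree(generate_tree(9, seed = 7)))
  expect_error(generate_tree(1), ">= 2")
})

test_that("trait simulation respects its degenerate limits and mask bounds", {
  tree <- generate_tree(12, seed = 8)
  cfg0 <- sim_config(n_species = 12, bm_sigma = 0, trait_noise_sd = 0,
                     missing_frac = 0, trait_count = 3, seed = 8)
  tr0 <- simulate_traits(tree, cfg0)
  vals <- as.matrix(tr0$traits[-1])
  expect_true(all(apply(vals, 2, function(v) diff(range(v))) < 1e-12))
  expect_false(anyNA(vals))
  cfg <- sim_config(n_species = 12, missing_frac = 0.3, trait_count = 4, seed = 9)
  tr <- simulate_traits(tree, cfg)
  m <- as.matrix(tr$traits[-1])
  expect_true(anyNA(m))
  expect_true(all(rowSums(!is.na(m)) >= 1))
  expect_true(all(colSums(!is.na(m)) >= 3))
  expect_false(anyNA(as.matrix(tr$truth[-1])))
})

test_that("closely related tips have more similar traits than distant ones", {
  tree <- generate_tree(10, seed = 11)
  pat <- ape::cophenetic.phylo(tree)
  near <- which(pat == min(pat[pat > 0]), arr.ind = TRUE)[1, ]
  far <- which(pat == max(pat), arr.ind = TRUE)[1, ]
  cfg <- sim_config(n_species = 10, trait_count = 1, trait_noise_sd = 0,
                    missing_frac = 0, seed = 1)
  diffs <- vapply(1:100, function(s) {
    v <- as.matrix(simulate_traits(tree, cfg, seed = s)$truth[-1])[, 1]
    c((v[near[1]] - v[near[2]])^2, (v[far[1]] - v[far[2]])^2)
  }, numeric(2))
  # BM variance is proportional to patristic distance
  expect_lt(mean(diffs[1, ]), mean(diffs[2, ]))
})

test_that("the whole experiment is byte-identical under a fixed seed", {
  cfg <- sim_config(n_species = 15, plots_per_combo = 2, trait_count = 3, seed = 123)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$survey$detections, s2$survey$detections)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$traits, s2$traits)
})

test_that("experiment bundles round-trip through disk", {
  cfg <- sim_config(n_species = 10, plots_per_combo = 1, trait_count = 2, seed = 2)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_experiment(sim, dir)
  survey <- read_survey(file.path(dir, "survey.csv"))
  expect_equal(
    dplyr::arrange(survey$detections, plot, unit, species),
    dplyr::arrange(sim$survey$detections, plot, unit, species)
  )
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, sim$tree$tip.label)
})
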