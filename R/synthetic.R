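# Synthetic factorial restoration experiments: occupancy-based incidence
# data with plot-level aggregation, a Yule phylogeny, and Brownian-motion
# traits with missingness. The generator gives every downstream estimator a
# fully known truth to be tested against.

#' Configuration of a synthetic restoration experiment
#'
#' Defaults emulate the structure of a 2x2 (nutrients x invasion timing)
#' factorial prairie-restoration experiment: 8 plots per combination, 9
#' surveyed subplots plus a perimeter-walk pseudo-subplot per plot, a
#' dominant focal invader whose occupancy is high under early invasion and
#' suppresses native occupancy (most strongly with nutrients), a geometric
#' rank-occupancy series for the natives (the classic grassland dominance
#' profile), and a plot-level random effect on the logit-occupancy scale
#' that induces the spatial aggregation controlling beta diversity.
#'
#' @param n_species Total species including the invader (default 60).
#' @param plots_per_combo Plots per treatment combination (default 8).
#' @param subplots_per_plot Surveyed subplots per plot (default 9).
#' @param include_perimeter Append a perimeter-walk unit per plot?
#' @param occupancy_base Native per-unit occupancy probabilities: a scalar,
#'   a vector of length `n_species - 1`, or `NULL` (default) for the
#'   geometric series `0.5 * 0.93^(rank - 1)`.
#' @param invader_occupancy Named vector of invader occupancy per treatment
#'   (`nutrient.invasion` labels).
#' @param suppression Named vector of multipliers in `[0, 1]` applied to
#'   native occupancy per treatment; early invasion suppresses natives.
#' @param plot_sd Standard deviation of the plot x species random effect on
#'   the logit-occupancy scale (default 0.8). The effect is mean-preserving:
#'   it redistributes where a species occurs without changing its marginal
#'   occupancy, so this parameter controls spatial aggregation alone.
#' @param perimeter_p Detection probability scaling of the perimeter walk
#'   (default 0.5); see [simulate_incidence()].
#' @param trait_count Number of continuous traits (default 10).
#' @param bm_sigma Brownian-motion rate of trait evolution (default 1).
#' @param trait_noise_sd Independent measurement noise SD (default 0.1).
#' @param missing_frac Fraction of trait entries masked missing completely
#'   at random (default 0.2, must be `< 1`).
#' @param seed Integer seed; everything generated from this config is
#'   byte-identical for a fixed seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 60,
                       plots_per_combo = 8,
                       subplots_per_plot = 9,
                       include_perimeter = TRUE,
                       occupancy_base = NULL,
                       invader_occupancy = c(
                         "control.early" = 0.95, "nutrients.early" = 0.90,
                         "control.late" = 0.35, "nutrients.late" = 0.30
                       ),
                       suppression = c(
                         "control.early" = 0.4, "nutrients.early" = 0.3,
                         "control.late" = 1, "nutrients.late" = 1
                       ),
                       plot_sd = 0.8,
                       perimeter_p = 0.5,
                       trait_count = 10,
                       bm_sigma = 1,
                       trait_noise_sd = 0.1,
                       missing_frac = 0.2,
                       seed = 1) {
  if (n_species < 2) abort("n_species must be >= 2")
  if (plots_per_combo < 1) abort("plots_per_combo must be >= 1")
  n_native <- n_species - 1
  if (is.null(occupancy_base)) {
    occupancy_base <- 0.5 * 0.93^(seq_len(n_native) - 1)
  } else if (length(occupancy_base) == 1) {
    occupancy_base <- rep(occupancy_base, n_native)
  } else if (length(occupancy_base) != n_native) {
    abort("occupancy_base must have length 1 or n_species - 1")
  }
  trts <- treatment_levels()$treatment
  for (nm in c("invader_occupancy", "suppression")) {
    v <- get(nm)
    if (!all(trts %in% names(v))) {
      abort(paste0(nm, " must name all four treatments: ",
                   paste(trts, collapse = ", ")))
    }
  }
  stopifnot(
    all(occupancy_base >= 0 & occupancy_base <= 1),
    all(invader_occupancy >= 0 & invader_occupancy <= 1),
    all(suppression >= 0 & suppression <= 1),
    plot_sd >= 0, perimeter_p >= 0, perimeter_p <= 1,
    missing_frac >= 0, missing_frac < 1, trait_count >= 1
  )
  structure(
    list(
      n_species = as.integer(n_species),
      species = c("invader", sprintf("native%02d", seq_len(n_native))),
      invader = "invader",
      plots_per_combo = as.integer(plots_per_combo),
      subplots_per_plot = as.integer(subplots_per_plot),
      include_perimeter = isTRUE(include_perimeter),
      occupancy_base = occupancy_base,
      invader_occupancy = invader_occupancy[trts],
      suppression = suppression[trts],
      plot_sd = plot_sd,
      perimeter_p = perimeter_p,
      trait_count = as.integer(trait_count),
      bm_sigma = bm_sigma,
      trait_noise_sd = trait_noise_sd,
      missing_frac = missing_frac,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate the sampling design of a synthetic experiment
#'
#' Lays out plots and sampling units (no detections): each treatment
#' combination receives `plots_per_combo` plots, each plot
#' `subplots_per_plot` surveyed subplots plus one perimeter-walk unit when
#' enabled. With `full_factorial = TRUE` the 2x2 design is crossed with the
#' three-level seeding-assembly factor (12 combinations), mirroring the
#' complete experiment before [filter_analysis_subset()].
#'
#' @param config A [sim_config()].
#' @param full_factorial Include the assembly factor (default `FALSE`:
#'   analysis subset only, all plots labelled `assembly = "both"`).
#' @return An `incidence_matrix` skeleton with empty detections.
#' @export
generate_design <- function(config, full_factorial = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  assembly <- if (full_factorial) .assembly_levels else "both"
  combos <- tidyr::expand_grid(
    assembly = assembly,
    nutrient = .nutrient_levels,
    invasion = .invasion_levels
  )
  plots <- combos |>
    tidyr::expand_grid(rep = seq_len(config$plots_per_combo)) |>
    mutate(plot = sprintf(
      "p_%s_%s_%s_%02d",
      substr(.data$assembly, 1, 2), .data$nutrient, .data$invasion, .data$rep
    )) |>
    select(-"rep")
  unit_ids <- sprintf("s%02d", seq_len(config$subplots_per_plot))
  units <- plots |>
    tidyr::expand_grid(unit = unit_ids) |>
    mutate(kind = "surveyed_subplot")
  if (config$include_perimeter) {
    units <- bind_rows(
      units,
      plots |> mutate(unit = "perimeter", kind = "perimeter_walk")
    )
  }
  units <- arrange(units, .data$plot, .data$kind, .data$unit)
  incidence_matrix(units, tibble(plot = character(), unit = character(),
                                 species = character()))
}

# intercept a(pi, sigma) such that E_z[plogis(a + sigma z)] = pi, so the
# plot random effect redistributes occupancy across plots without changing
# a species' marginal (across-plot) occupancy; quadrature over z
.centered_logit <- function(pi, sigma, z = qnorm((seq_len(400) - 0.5) / 400)) {
  if (sigma == 0 || pi <= 0 || pi >= 1) {
    return(qlogis(pmin(pmax(pi, 1e-12), 1 - 1e-12)))
  }
  stats::uniroot(function(a) mean(plogis(a + sigma * z)) - pi,
                 c(-50, 50), tol = 1e-10)$root
}

# latent per-plot, per-species occupancy probabilities. The plot x species
# effect is Normal(0, plot_sd^2) on the logit scale with a mean-preserving
# intercept: plot_sd therefore controls spatial aggregation (which plots a
# species concentrates in) without inflating its marginal occupancy.
.plot_occupancy <- function(config, plot_tbl) {
  trts <- .treatment_label(plot_tbl$nutrient, plot_tbl$invasion)
  base <- matrix(
    rep(config$occupancy_base, each = nrow(plot_tbl)),
    nrow = nrow(plot_tbl)
  )
  base <- sweep(base, 1, config$suppression[trts], "*")
  pi <- cbind(invader = config$invader_occupancy[trts], base)
  colnames(pi) <- config$species
  vals <- sort(unique(as.vector(pi)))
  a_of <- vapply(vals, .centered_logit, numeric(1), sigma = config$plot_sd)
  a <- matrix(a_of[match(pi, vals)], nrow = nrow(pi))
  b <- matrix(rnorm(length(pi), 0, config$plot_sd), nrow = nrow(pi))
  out <- plogis(a + b)
  out[pi == 0] <- 0
  out[pi == 1] <- 1
  dimnames(out) <- list(plot_tbl$plot, config$species)
  out
}

#' Simulate species detections on a design
#'
#' Detection of species `s` in a surveyed subplot of plot `p` is Bernoulli
#' with probability `plogis(a(pi, plot_sd) + b[p, s])`, where the plot x
#' species effect `b ~ Normal(0, plot_sd^2)` is shared by all units of the
#' plot and the intercept `a` is solved so that the marginal (across-plot)
#' occupancy stays exactly `pi[s, treatment]`. Raising `plot_sd` therefore
#' concentrates a species into fewer plots (spatial aggregation, the
#' driver of beta diversity) without changing how often it is detected
#' overall. The perimeter walk then
#' detects each species missed by the plot's subplots with probability
#' `perimeter_p * (1 - (1 - pi_ps)^subplots_per_plot)`: the walk can only
#' recover species plausibly present somewhere in the plot, with the
#' plot-presence probability implied by the species' plot-level occupancy.
#'
#' @param design An `incidence_matrix` skeleton from [generate_design()].
#' @param config The [sim_config()] used for the design.
#' @param seed Seed (defaults to `config$seed`).
#' @return An `incidence_matrix` with simulated detections; the latent
#'   plot x species occupancy matrix is attached as attribute `occupancy`.
#' @export
simulate_incidence <- function(design, config, seed = config$seed) {
  stopifnot(inherits(design, "incidence_matrix"), inherits(config, "sim_config"))
  withr::with_seed(seed, {
    plot_tbl <- design$units |>
      distinct(dplyr::across(dplyr::all_of(
        intersect(c("plot", "nutrient", "invasion", "assembly"),
                  names(design$units))
      ))) |>
      arrange(.data$plot)
    occ <- .plot_occupancy(config, plot_tbl)
    surveyed <- design$units |>
      filter(.data$kind == "surveyed_subplot") |>
      arrange(.data$plot, .data$unit)
    # surveyed-subplot detections
    p_mat <- occ[surveyed$plot, , drop = FALSE]
    det <- matrix(
      rbinom(length(p_mat), 1, p_mat) == 1,
      nrow = nrow(p_mat), dimnames = list(NULL, config$species)
    )
    detections <- tibble(
      plot = rep(surveyed$plot, times = ncol(det)),
      unit = rep(surveyed$unit, times = ncol(det)),
      species = rep(colnames(det), each = nrow(det))
    )[as.vector(det), ]
    # perimeter walk: species present in the plot pool but missed above
    if (config$include_perimeter) {
      seen <- detections |> distinct(.data$plot, .data$species)
      pool <- tidyr::expand_grid(plot = plot_tbl$plot, species = config$species) |>
        anti_join(seen, by = c("plot", "species"))
      pi_ps <- occ[cbind(pool$plot, pool$species)]
      p_walk <- config$perimeter_p * (1 - (1 - pi_ps)^config$subplots_per_plot)
      hit <- rbinom(nrow(pool), 1, p_walk) == 1
      walk_det <- pool[hit, ] |> mutate(unit = "perimeter")
      detections <- bind_rows(detections,
                              walk_det |> select("plot", "unit", "species"))
    }
    out <- incidence_matrix(design$units, detections)
    attr(out, "occupancy") <- occ
    out
  })
}

#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth topology (`ape::rphylo`) with branch lengths rescaled so the
#' tree is ultrametric with depth exactly 1.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @param tip_labels Optional tip names (default `t1 ... tn` from ape).
#' @return A `phylo` object of depth 1.
#' @export
generate_tree <- function(n_species, seed = 1, tip_labels = NULL) {
  if (n_species < 2) abort("n_species must be >= 2")
  tree <- withr::with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length / tree_depth(tree)
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_species)
    tree$tip.label <- tip_labels
  }
  tree
}

#' Simulate Brownian-motion traits on a tree, with missingness
#'
#' Each trait evolves by Brownian motion (rate `bm_sigma`) along the tree,
#' plus independent `Normal(0, trait_noise_sd^2)` measurement noise, and is
#' then masked missing completely at random with probability
#' `missing_frac`. The mask is repaired minimally so that every species
#' keeps at least one observed value and every trait at least three (the
#' preconditions of [impute_traits()]); the unmasked truth is returned
#' alongside.
#'
#' @param tree A `phylo` whose tips are the species.
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A list with `traits` (tibble with NAs), `truth` (complete
#'   tibble) and `mask` (logical matrix of masked entries).
#' @export
simulate_traits <- function(tree, config, seed = config$seed) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  withr::with_seed(seed, {
    n <- ape::Ntip(tree)
    k <- config$trait_count
    vals <- vapply(
      seq_len(k),
      function(j) {
        ape::rTraitCont(tree, model = "BM", sigma = config$bm_sigma) +
          rnorm(n, 0, config$trait_noise_sd)
      },
      numeric(n)
    )
    dimnames(vals) <- list(tree$tip.label, sprintf("trait_%02d", seq_len(k)))
    mask <- matrix(rbinom(length(vals), 1, config$missing_frac) == 1,
                   nrow = n, dimnames = dimnames(vals))
    # repair: keep imputation preconditions satisfiable
    for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(k, 1)] <- FALSE
    for (j in which(colSums(!mask) < 3)) {
      need <- 3 - sum(!mask[, j])
      mask[sample(which(mask[, j]), need), j] <- FALSE
    }
    observed <- vals
    observed[mask] <- NA_real_
    list(
      traits = as_tibble(observed) |> mutate(species = rownames(vals), .before = 1),
      truth = as_tibble(vals) |> mutate(species = rownames(vals), .before = 1),
      mask = mask
    )
  })
}

#' Simulate a complete synthetic experiment
#'
#' Design + incidence + phylogeny + traits in one reproducible bundle.
#'
#' @param config A [sim_config()].
#' @param full_factorial Passed to [generate_design()].
#' @return A list of class `sim_experiment` with elements `survey`
#'   (incidence matrix), `tree`, `traits` (with missingness), `truth`
#'   (trait truth, occupancy matrix, seed) and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), full_factorial = FALSE) {
  design <- generate_design(config, full_factorial = full_factorial)
  survey <- simulate_incidence(design, config, seed = config$seed)
  tree <- generate_tree(config$n_species, seed = config$seed + 1,
                        tip_labels = config$species)
  tr <- simulate_traits(tree, config, seed = config$seed + 2)
  structure(
    list(
      survey = survey, tree = tree, traits = tr$traits,
      truth = list(traits = tr$truth, mask = tr$mask,
                   occupancy = attr(survey, "occupancy"), seed = config$seed),
      config = config
    ),
    class = "sim_experiment"
  )
}

#' Write a synthetic experiment to disk
#'
#' Writes the survey CSV dialect of [read_survey()], a Newick tree file and
#' a traits CSV (`species, trait_01, ...`), plus the trait truth for
#' recovery tests.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survey(sim$survey, file.path(dir, "survey.csv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(sim$traits, file.path(dir, "traits.csv"), progress = FALSE)
  readr::write_csv(sim$truth$traits, file.path(dir, "traits_truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
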