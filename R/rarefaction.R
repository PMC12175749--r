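# Sample-based rarefaction / extrapolation curves with bootstrap CIs for
# the three diversity facets, per assemblage (treatment combination).

.freqs_from_X <- function(X) {
  Y <- colSums(X)
  f <- new_incidence_freq(Y[Y > 0], names(Y)[Y > 0], T_units = nrow(X))
  attr(f, "X") <- X[, f$species, drop = FALSE]
  attr(f, "cooc") <- crossprod(X[, f$species, drop = FALSE])
  f
}

# point estimates over a t grid for one assemblage, all requested
# facet x order combinations; X is the unit x species logical matrix
.curve_point <- function(X, t_grid, facets, q_orders,
                         tree_struct = NULL, depth = NULL,
                         dist = NULL, tau = NULL) {
  freqs <- .freqs_from_X(X)
  bf <- NULL
  if ("PD" %in% facets) {
    bf <- .branch_stats(tree_struct, X)
    attr(bf, "T") <- nrow(X)
    attr(bf, "depth") <- depth
    class(bf) <- c("branch_freq", class(bf))
  }
  purrr::map_dfr(facets, function(fc) {
    purrr::map_dfr(q_orders, function(qq) {
      tt <- if (qq == 2) t_grid[t_grid >= 2] else t_grid
      est <- if (nrow(freqs) == 0) {
        rep(0, length(tt))
      } else if (fc == "TD") {
        if (qq == 0) td_q0(freqs, tt) else td_q2(freqs, tt)
      } else if (fc == "PD") {
        pd_hill(bf, q = qq, t = tt)
      } else {
        fd_hill(freqs, dist, q = qq, t = tt, tau = tau)
      }
      tibble(facet = fc, q = qq, t = tt, estimate = est)
    })
  })
}

#' Bootstrap confidence intervals for a sampling-unit statistic
#'
#' Nonparametric bootstrap over sampling units: the T units of the selected
#' assemblage are resampled with replacement `B` times, the statistic is
#' recomputed for every replicate, and a percentile interval is formed
#' element-wise. Assumption-free, but intervals in the extrapolated range
#' can undercover because unseen species are never resampled; this caveat
#' travels with the result as the `method` attribute.
#'
#' @param estimator Function taking a unit x species logical matrix and
#'   returning a numeric vector (e.g. a curve over a t grid).
#' @param x An `incidence_matrix`.
#' @inheritParams to_frequencies
#' @param B Number of bootstrap replicates (default 50, must be >= 2).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @return A tibble with columns `index`, `ci_low`, `ci_high` and attribute
#'   `replicates` (B x length matrix of replicate statistics).
#' @export
bootstrap_ci <- function(estimator, x, treatment = NULL, plots = NULL,
                         units = NULL, B = 50, level = 0.95, seed = 1) {
  if (B < 2) abort("B must be >= 2")
  X <- .incidence_logical(x, treatment = treatment, plots = plots, units = units)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      estimator(X[sample.int(nrow(X), replace = TRUE), , drop = FALSE])
    }, estimator(X) * 0)
  })
  reps <- matrix(reps, ncol = B)
  alpha <- (1 - level) / 2
  out <- tibble(
    index = seq_len(nrow(reps)),
    ci_low = apply(reps, 1, quantile, probs = alpha, names = FALSE),
    ci_high = apply(reps, 1, quantile, probs = 1 - alpha, names = FALSE)
  )
  attr(out, "replicates") <- t(reps)
  attr(out, "method") <- "percentile bootstrap over sampling units"
  out
}

#' Rarefaction / extrapolation curves for all facets and orders
#'
#' The package's central estimator: for every assemblage (by default every
#' treatment combination present in the survey) computes sample-based
#' rarefied, observed and extrapolated diversity over a grid of sampling
#' units, for taxonomic (TD), phylogenetic (PD, mean effective lineages)
#' and functional (FD, tau-threshold) facets at Hill orders q = 0 and
#' q = 2, with percentile bootstrap confidence intervals from `B` unit
#' resamples. The functional threshold tau is fixed per assemblage at the
#' pooled observed sample (see [fd_tau()]) and held constant along the
#' curve and across bootstrap replicates.
#'
#' @param x An `incidence_matrix` (the analysis subset).
#' @param tree Rooted ultrametric `phylo`, required for facet `"PD"`.
#' @param dist Species distance matrix, required for facet `"FD"`.
#' @param facets Subset of `c("TD", "PD", "FD")`.
#' @param q Hill orders, subset of `c(0, 2)`.
#' @param t_max Largest number of sampling units on the grid (default 120;
#'   extrapolation past the observed T is flagged, and a request beyond
#'   `2 * T` is allowed but warned about).
#' @param step Grid spacing (default 1; `t = 2` and `t = T` are always
#'   included).
#' @param B Bootstrap replicates (default 50); `B = 0` skips the bootstrap.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble of class `restodiv_curve` with columns `assemblage`,
#'   `facet`, `q`, `t`, `status` (rarefied/observed/extrapolated),
#'   `estimate`, `ci_low`, `ci_high`; bootstrap replicate curves are kept
#'   in the `replicates` attribute for the scale/effect stage.
#' @export
estimate_diversity <- function(x, tree = NULL, dist = NULL,
                               facets = c("TD", "PD", "FD"),
                               q = c(0, 2), t_max = 120, step = 1,
                               B = 50, level = 0.95, seed = 1) {
  stopifnot(inherits(x, "incidence_matrix"))
  facets <- match.arg(facets, c("TD", "PD", "FD"), several.ok = TRUE)
  if (!all(q %in% c(0, 2))) abort("q must be a subset of c(0, 2)")
  if ("PD" %in% facets && is.null(tree)) abort("facet PD needs `tree`")
  if ("FD" %in% facets && is.null(dist)) abort("facet FD needs `dist`")
  tree_struct <- NULL
  depth <- NULL
  if ("PD" %in% facets) {
    .check_ultrametric(tree)
    tree_struct <- .branch_structure(tree)
    depth <- tree_depth(tree)
  }
  assemblages <- x$units |>
    distinct(.data$nutrient, .data$invasion) |>
    mutate(assemblage = .treatment_label(.data$nutrient, .data$invasion)) |>
    arrange(.data$assemblage)

  results <- purrr::map(seq_len(nrow(assemblages)), function(i) {
    tr <- assemblages$assemblage[i]
    X <- .incidence_logical(x, treatment = tr)
    T_obs <- nrow(X)
    if (t_max > 2 * T_obs) {
      warn(paste0("t_max = ", t_max, " exceeds twice the observed units (",
                  T_obs, ") for ", tr, "; long-range extrapolation is unreliable"))
    }
    t_grid <- sort(unique(c(2, seq(2, t_max, by = step), T_obs, t_max)))
    t_grid <- t_grid[t_grid >= 1]
    freqs <- .freqs_from_X(X)
    tau <- if ("FD" %in% facets && nrow(freqs) > 0) fd_tau(freqs, dist) else NULL
    point <- .curve_point(X, t_grid, facets, q, tree_struct, depth, dist, tau) |>
      mutate(assemblage = tr, .before = 1)
    reps <- NULL
    if (B >= 2) {
      reps <- withr::with_seed(seed + i, {
        purrr::map_dfr(seq_len(B), function(b) {
          Xb <- X[sample.int(T_obs, replace = TRUE), , drop = FALSE]
          .curve_point(Xb, t_grid, facets, q, tree_struct, depth, dist, tau) |>
            mutate(assemblage = tr, b = b)
        })
      })
      alpha <- (1 - level) / 2
      cis <- reps |>
        group_by(.data$assemblage, .data$facet, .data$q, .data$t) |>
        summarise(
          ci_low = quantile(.data$estimate, alpha, names = FALSE),
          ci_high = quantile(.data$estimate, 1 - alpha, names = FALSE),
          .groups = "drop"
        )
      point <- left_join(point, cis, by = c("assemblage", "facet", "q", "t"))
    } else {
      point <- point |> mutate(ci_low = NA_real_, ci_high = NA_real_)
    }
    list(
      curve = point |>
        mutate(status = dplyr::case_when(
          .data$t < T_obs ~ "rarefied",
          .data$t == T_obs ~ "observed",
          TRUE ~ "extrapolated"
        )) |>
        select("assemblage", "facet", "q", "t", "status",
               "estimate", "ci_low", "ci_high"),
      replicates = reps,
      T_obs = tibble(assemblage = tr, T_obs = T_obs),
      tau = tibble(assemblage = tr, tau = tau %||% NA_real_)
    )
  })

  out <- purrr::map_dfr(results, "curve")
  attr(out, "replicates") <- purrr::map_dfr(results, "replicates")
  attr(out, "T_obs") <- purrr::map_dfr(results, "T_obs")
  attr(out, "tau") <- purrr::map_dfr(results, "tau")
  attr(out, "level") <- level
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "method") <- paste(
    "percentile bootstrap over sampling units;",
    "extrapolated-range CIs may undercover (unseen species not resampled)"
  )
  class(out) <- c("restodiv_curve", class(out))
  out
}

#' @export
print.restodiv_curve <- function(x, ...) {
  cat("<restodiv_curve> ",
      dplyr::n_distinct(x$assemblage), " assemblages x ",
      dplyr::n_distinct(x$facet), " facets x ",
      dplyr::n_distinct(x$q), " orders; t in [",
      min(x$t), ", ", max(x$t), "]; B = ", attr(x, "B"), "\n", sep = "")
  NextMethod()
}
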