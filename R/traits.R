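# Trait pipeline: Gower dissimilarities and phylogeny-informed iterative
# random-forest imputation with out-of-bag restart selection.

.trait_matrix <- function(traits) {
  traits <- as_tibble(traits)
  if (!"species" %in% names(traits)) abort("traits table needs a `species` column")
  m <- as.matrix(traits[setdiff(names(traits), "species")])
  if (!is.numeric(m)) abort("all traits must be numeric (continuous)")
  rownames(m) <- traits$species
  m
}

#' Gower dissimilarity between species
#'
#' Range-normalized mean absolute trait difference:
#' `d_ij = mean over traits observed in both species of |x_it - x_jt| / range_t`,
#' bounded in `[0, 1]`. Traits with zero range carry no information and
#' contribute 0 (they are reported via the `zero_range` attribute). Missing
#' entries are tolerated pairwise; a species pair sharing no observed trait
#' is an error (run [impute_traits()] first).
#'
#' @param traits Tibble with a `species` column and numeric trait columns
#'   (missing values allowed).
#' @return A symmetric species x species matrix in `[0, 1]` with zero
#'   diagonal and attribute `zero_range` naming uninformative traits.
#' @export
gower_distance <- function(traits) {
  m <- .trait_matrix(traits)
  rng <- apply(m, 2, function(v) diff(range(v, na.rm = TRUE)))
  zero_range <- colnames(m)[rng == 0 | !is.finite(rng)]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  scaled <- sweep(m, 2, ifelse(rng > 0, rng, 1), "/")
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq.int(i + 1, n)) {
      shared <- !is.na(scaled[i, ]) & !is.na(scaled[j, ])
      if (!any(shared)) {
        abort(paste0("species pair (", rownames(m)[i], ", ", rownames(m)[j],
                     ") shares no observed trait"))
      }
      diffs <- abs(scaled[i, shared] - scaled[j, shared])
      diffs[colnames(m)[shared] %in% zero_range] <- 0
      d[i, j] <- d[j, i] <- mean(diffs)
    }
  }
  attr(d, "zero_range") <- zero_range
  d
}

# one pass of chained random-forest imputation over all traits with missing
# values, in increasing-missingness order; returns the filled matrix and the
# per-trait OOB mean-squared errors of this pass
.rf_impute_pass <- function(filled, miss_idx, predictors, n_trees) {
  order_traits <- names(sort(vapply(miss_idx, length, integer(1))))
  oob <- setNames(rep(NA_real_, length(order_traits)), order_traits)
  for (tr in order_traits) {
    mis <- miss_idx[[tr]]
    xmat <- cbind(filled[, setdiff(colnames(filled), tr), drop = FALSE], predictors)
    obs <- setdiff(seq_len(nrow(filled)), mis)
    # near-constant responses trigger a spurious regression warning
    fit <- suppressWarnings(randomForest::randomForest(
      x = xmat[obs, , drop = FALSE], y = filled[obs, tr],
      ntree = n_trees
    ))
    oob[tr] <- fit$mse[n_trees]
    if (length(mis) > 0) {
      filled[mis, tr] <- predict(fit, xmat[mis, , drop = FALSE])
    }
  }
  list(filled = filled, oob = oob)
}

#' Impute missing trait values with phylogenetic random forests
#'
#' Chained (variable-wise) random-forest imputation of a continuous trait
#' table, with phylogenetic Moran eigenvectors as additional predictors.
#' Missing entries are initialized at trait means; traits are then visited
#' in increasing-missingness order, each regressed on all other traits plus
#' the first `k` eigenvectors, and its missing entries re-predicted. The
#' iteration stops when the total change in imputed values increases
#' (classic stopping rule) or after `max_iter` passes. The whole procedure
#' is restarted `n_restarts` times, varying both the random seed and the
#' number of eigenvector columns over `k_grid`; per trait, the imputed
#' values from the restart with minimal out-of-bag (OOB) error — normalized
#' RMSE, `sqrt(OOB MSE)/sd(observed)` — are retained.
#'
#' @param traits Tibble with a `species` column and numeric trait columns;
#'   missing values allowed, but every trait needs >= 3 observed values and
#'   no species may be entirely unobserved.
#' @param eigenvectors Species x k matrix from [moran_eigenvectors()]
#'   (rows matched to species by name when named).
#' @param n_trees Trees per random forest (default 100).
#' @param n_restarts Number of restarts (default 25).
#' @param k_grid Eigenvector counts cycled over across restarts (default
#'   `seq(5, 30, by = 5)`, capped at the available columns).
#' @param max_iter Maximum chained passes per restart.
#' @param seed Integer seed; the run is fully deterministic given it.
#' @return A list with `traits` (completed tibble), `oob` (tibble of the
#'   selected restart's normalized RMSE per trait, with the eigenvector
#'   count used) and `restarts` (per restart x trait OOB log).
#' @export
impute_traits <- function(traits, eigenvectors, n_trees = 100, n_restarts = 25,
                          k_grid = seq(5, 30, by = 5), max_iter = 10,
                          seed = 1) {
  m <- .trait_matrix(traits)
  if (any(colSums(!is.na(m)) < 3)) {
    bad <- colnames(m)[colSums(!is.na(m)) < 3]
    abort(paste0("trait(s) with < 3 observed values: ", paste(bad, collapse = ", ")))
  }
  if (any(rowSums(!is.na(m)) == 0)) {
    abort("species with no observed trait value cannot be imputed")
  }
  ev <- as.matrix(eigenvectors)
  if (!is.null(rownames(ev))) {
    missing_sp <- setdiff(rownames(m), rownames(ev))
    if (length(missing_sp) > 0) {
      abort(paste0("eigenvectors missing species: ", paste(missing_sp, collapse = ", ")))
    }
    ev <- ev[rownames(m), , drop = FALSE]
  } else if (nrow(ev) != nrow(m)) {
    abort("eigenvector rows must match the species of the trait table")
  }
  k_grid <- unique(pmin(k_grid, ncol(ev)))
  miss_idx <- lapply(colnames(m), function(tr) which(is.na(m[, tr])))
  names(miss_idx) <- colnames(m)
  miss_traits <- names(miss_idx)[vapply(miss_idx, length, integer(1)) > 0]
  obs_sd <- apply(m, 2, sd, na.rm = TRUE)

  run_restart <- function(r) {
    k <- k_grid[((r - 1) %% length(k_grid)) + 1]
    withr::with_seed(seed + r, {
      filled <- m
      for (tr in colnames(m)) {
        filled[miss_idx[[tr]], tr] <- mean(m[, tr], na.rm = TRUE)
      }
      preds <- ev[, seq_len(k), drop = FALSE]
      best <- filled
      oob <- NULL
      prev_change <- Inf
      for (iter in seq_len(max_iter)) {
        pass <- .rf_impute_pass(filled, miss_idx, preds, n_trees)
        change <- sum((pass$filled - filled)^2)
        if (iter > 1 && change > prev_change) break # classic stopping rule
        filled <- pass$filled
        best <- filled
        oob <- pass$oob
        prev_change <- change
        if (change == 0) break
      }
      list(k = k, filled = best,
           oob = sqrt(oob)[colnames(m)] / ifelse(obs_sd > 0, obs_sd, 1))
    })
  }

  restarts <- lapply(seq_len(n_restarts), run_restart)
  log_tbl <- purrr::map_dfr(seq_along(restarts), function(r) {
    tibble(restart = r, k_eigen = restarts[[r]]$k,
           trait = colnames(m), oob_nrmse = unname(restarts[[r]]$oob))
  })
  completed <- m
  chosen <- tibble(trait = colnames(m), k_eigen = NA_integer_,
                   restart = NA_integer_, oob_nrmse = NA_real_)
  for (tr in colnames(m)) {
    errs <- vapply(restarts, function(rs) rs$oob[[tr]], numeric(1))
    best_r <- which.min(errs)
    completed[miss_idx[[tr]], tr] <- restarts[[best_r]]$filled[miss_idx[[tr]], tr]
    chosen[chosen$trait == tr, c("k_eigen", "restart", "oob_nrmse")] <-
      tibble(restarts[[best_r]]$k, best_r, errs[best_r])
  }
  out <- as_tibble(completed) |> mutate(species = rownames(m), .before = 1)
  list(traits = out, oob = chosen, restarts = log_tbl)
}
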