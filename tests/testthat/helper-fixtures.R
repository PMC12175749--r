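# Shared fixtures and independent brute-force oracles.

# incidence matrix from a unit x species 0/1 matrix (single plot/treatment)
matrix_from_X <- function(X, nutrient = "control", invasion = "early",
                          plot = "p1") {
  n_u <- nrow(X)
  sp <- colnames(X) %||% paste0("sp", seq_len(ncol(X)))
  colnames(X) <- sp
  units <- tibble::tibble(
    plot = plot, unit = sprintf("u%02d", seq_len(n_u)),
    kind = "surveyed_subplot", nutrient = nutrient, invasion = invasion
  )
  idx <- which(X == 1, arr.ind = TRUE)
  det <- tibble::tibble(
    plot = plot, unit = units$unit[idx[, 1]], species = sp[idx[, 2]]
  )
  incidence_matrix(units, det)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random incidence assemblage: T units, S species, heterogeneous occupancy
random_X <- function(T_units, S, min_occ = 0.1, max_occ = 0.9) {
  p <- runif(S, min_occ, max_occ)
  X <- matrix(rbinom(T_units * S, 1, rep(p, each = T_units)), nrow = T_units)
  # keep at least one detection so the assemblage is non-degenerate
  if (all(X == 0)) X[1, 1] <- 1
  X[, colSums(X) > 0, drop = FALSE]
}

# --- exhaustive oracles (enumeration over all size-t unit subsets) --------

# expected richness in t of T units
oracle_richness <- function(X, t) {
  subsets <- utils::combn(nrow(X), t, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    sum(colSums(X[s, , drop = FALSE]) > 0)
  }, numeric(1)))
}

# expected total incidence E[U(t)] and expected pair sum E[sum Y(Y-1)]
oracle_q2_moments <- function(X, t) {
  subsets <- utils::combn(nrow(X), t, simplify = FALSE)
  u <- vapply(subsets, function(s) sum(X[s, , drop = FALSE]), numeric(1))
  pr <- vapply(subsets, function(s) {
    y <- colSums(X[s, , drop = FALSE])
    sum(y * (y - 1))
  }, numeric(1))
  c(U = mean(u), pairs = mean(pr))
}

# the moment components the estimator uses
estimator_q2_moments <- function(freqs, t) {
  T_units <- attr(freqs, "T")
  c(
    U = t * attr(freqs, "U") / T_units,
    pairs = t * (t - 1) / (T_units * (T_units - 1)) * sum(freqs$Y * (freqs$Y - 1))
  )
}

# small reference trees
tree_abc <- function() ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")

star_tree <- function(labels, depth = 1) {
  n <- length(labels)
  txt <- paste0("(", paste0(labels, ":", depth, collapse = ","), ");")
  ape::read.tree(text = txt)
}
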