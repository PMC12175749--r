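# Phylogenetic Hill numbers (mean-PD): effective number of equally
# divergent lineages = effective total branch length / tree depth.

#' Phylogenetic diversity (mean-PD) at orders q = 0 and q = 2
#'
#' Incidence-based phylogenetic Hill diversity expressed as an effective
#' number of equally divergent lineages: effective total branch length
#' divided by the tree depth.
#'
#' For `q = 0` and `t <= T` the estimate is the exact subsampling
#' expectation `(1/depth) * sum_b L_b * [1 - choose(T - Y_b, t)/choose(T, t)]`;
#' for `t > T` a Chao2-type correction on branch-level unique/duplicate
#' branch lengths extrapolates the undetected branch length.
#'
#' For `q = 2` the ratio-of-moments estimator is applied to branch
#' "abundances" (sums of descendant tip incidences) with branch weights
#' `L_b / depth`; on an ultrametric tree the weighted branch abundances sum
#' to the total tip incidence, so a single lineage yields exactly 1 and a
#' star tree with equal branch lengths reduces exactly to [td_q2()].
#'
#' @param branch_freqs A [branch_frequencies()] table.
#' @param q Hill order, 0 or 2.
#' @param t Integer vector of sampling-unit counts (`t >= 2` when `q = 2`).
#' @return Numeric vector of effective lineage numbers.
#' @export
pd_hill <- function(branch_freqs, q, t) {
  stopifnot(inherits(branch_freqs, "branch_freq"))
  if (!q %in% c(0, 2)) abort("q must be 0 or 2")
  T_units <- attr(branch_freqs, "T")
  depth <- attr(branch_freqs, "depth")
  b <- branch_freqs[branch_freqs$Y > 0, , drop = FALSE]
  if (nrow(b) == 0) return(rep(0, length(t)))

  if (q == 0) {
    t <- as.integer(t)
    if (any(t < 1)) abort("t must be >= 1")
    vapply(t, function(ti) {
      if (ti <= T_units) {
        sum(b$length * .detect_prob(b$Y, T_units, ti)) / depth
      } else {
        pd_obs <- sum(b$length)
        R1 <- sum(b$length[b$Y == 1])
        R2 <- sum(b$length[b$Y == 2])
        B1 <- sum(b$Y == 1)
        k <- (T_units - 1) / T_units
        # Chao2-type undetected branch length; when no duplicate branches
        # exist, treat the B1 unique branches as exchangeable (mean length
        # R1/B1) and apply the count fallback.
        L0 <- if (R2 > 0) k * R1^2 / (2 * R2) else k * R1 * max(B1 - 1, 0) / 2
        (pd_obs + L0 * .extrap_gain(R1, L0, T_units, ti)) / depth
      }
    }, numeric(1))
  } else {
    t <- as.numeric(t)
    if (any(t < 2)) abort("t must be >= 2 for q = 2")
    if (T_units < 2) abort("q = 2 requires at least two sampling units observed")
    w <- b$length / depth
    vapply(t, function(ti) {
      m1 <- ti * b$Z / T_units
      m2 <- (ti / T_units) * b$sumsq +
        ti * (ti - 1) / (T_units * (T_units - 1)) * (b$Z^2 - b$sumsq)
      sum(w * m1)^2 / sum(w * m2)
    }, numeric(1))
  }
}
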