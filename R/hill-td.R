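# Taxonomic Hill numbers from incidence frequencies.
#
# Rarefaction (t <= T) uses exact hypergeometric expectations; richness
# extrapolation (t > T) uses the Chao2 lower bound on undetected species.

# P(species with incidence Y is detected in a random subset of t of T units)
# = 1 - choose(T - Y, t) / choose(T, t), computed on the log scale.
.detect_prob <- function(Y, T_units, t) {
  out <- rep(1, length(Y))
  idx <- (T_units - Y) >= t
  if (any(idx)) {
    out[idx] <- -expm1(lchoose(T_units - Y[idx], t) - lchoose(T_units, t))
  }
  out
}

# Chao2-type estimate of the number of undetected species
chao2_q0hat <- function(freqs) {
  T_units <- attr(freqs, "T")
  Q1 <- attr(freqs, "Q1")
  Q2 <- attr(freqs, "Q2")
  if (T_units < 2) return(0)
  k <- (T_units - 1) / T_units
  if (Q2 > 0) k * Q1^2 / (2 * Q2) else k * Q1 * (Q1 - 1) / 2
}

# extrapolation multiplier 1 - (1 - Q1/(Q1 + T*Q0))^(t - T), shared by the
# TD and PD q = 0 extrapolations
.extrap_gain <- function(Q1, Q0, T_units, t) {
  if (Q0 <= 0 || Q1 <= 0) return(rep(0, length(t)))
  1 - (1 - Q1 / (Q1 + T_units * Q0))^(t - T_units)
}

#' Taxonomic diversity of order q = 0 (species richness)
#'
#' Expected species richness in `t` sampling units. For `t <= T` this is the
#' exact sample-based rarefaction expectation
#' `S(t) = sum_i [1 - choose(T - Y_i, t) / choose(T, t)]`; for `t > T` the
#' curve is extrapolated with the Chao2 estimate of undetected richness.
#'
#' @param freqs An [incidence_freq()] object.
#' @param t Integer vector of sampling-unit counts (`t >= 1`).
#' @return Numeric vector of richness estimates, one per `t`.
#' @export
#' @examples
#' f <- incidence_freq(c(4, 2, 1), T_units = 4)
#' td_q0(f, t = 2) # 7/3
td_q0 <- function(freqs, t) {
  stopifnot(inherits(freqs, "incidence_freq"))
  t <- as.integer(t)
  if (any(t < 1)) abort("t must be >= 1 for q = 0")
  T_units <- attr(freqs, "T")
  if (nrow(freqs) == 0) return(rep(0, length(t)))
  vapply(t, function(ti) {
    if (ti <= T_units) {
      sum(.detect_prob(freqs$Y, T_units, ti))
    } else {
      Q0 <- chao2_q0hat(freqs)
      attr(freqs, "S_obs") +
        Q0 * .extrap_gain(attr(freqs, "Q1"), Q0, T_units, ti)
    }
  }, numeric(1))
}

#' Taxonomic diversity of order q = 2 (effective number of dominant species)
#'
#' Incidence-based Simpson (Hill q = 2) diversity at `t` sampling units,
#' using the ratio-of-expected-moments estimator
#' `(tU/T)^2 / [tU/T + t(t-1)/(T(T-1)) * sum_i Y_i (Y_i - 1)]`,
#' which is valid across rarefaction, the observed point and extrapolation.
#'
#' @inheritParams td_q0
#' @param t Integer vector of sampling-unit counts (`t >= 2`; incidence
#'   abundance needs at least two samples).
#' @return Numeric vector of effective species numbers.
#' @export
#' @examples
#' f <- incidence_freq(c(4, 2), T_units = 4)
#' td_q2(f, t = 2) # 1.6875
td_q2 <- function(freqs, t) {
  stopifnot(inherits(freqs, "incidence_freq"))
  t <- as.numeric(t)
  if (any(t < 2)) abort("t must be >= 2 for q = 2")
  T_units <- attr(freqs, "T")
  U <- attr(freqs, "U")
  if (U == 0) abort("no detections in the selected assemblage")
  if (T_units < 2) abort("q = 2 requires at least two sampling units observed")
  pair_sum <- sum(freqs$Y * (freqs$Y - 1))
  m1 <- t * U / T_units
  m2 <- t * (t - 1) / (T_units * (T_units - 1)) * pair_sum
  m1^2 / (m1 + m2)
}
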