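# Functional Hill numbers under a distinctness threshold tau: species
# closer than tau are partially pooled into "virtual functional groups".

.nu_matrix <- function(dist, species, tau) {
  missing_sp <- setdiff(species, rownames(dist))
  if (length(missing_sp) > 0) {
    abort(paste0("species missing from distance matrix: ",
                 paste(missing_sp, collapse = ", ")))
  }
  d <- as.matrix(dist)[species, species, drop = FALSE]
  1 - pmin(d, tau) / tau
}

#' Threshold tau from the pooled assemblage
#'
#' The default functional-distinctness threshold: the mean distance between
#' two individuals drawn at random from the pooled assemblage (Rao's
#' quadratic entropy), `tau = sum_ij p_i p_j d_ij` with incidence-based
#' relative abundances `p_i = Y_i / U`.
#'
#' @param freqs An [incidence_freq()] object.
#' @param dist Species distance matrix (e.g. [gower_distance()]).
#' @return A single nonnegative number.
#' @export
fd_tau <- function(freqs, dist) {
  stopifnot(inherits(freqs, "incidence_freq"))
  p <- freqs$Y / attr(freqs, "U")
  d <- as.matrix(dist)
  missing_sp <- setdiff(freqs$species, rownames(d))
  if (length(missing_sp) > 0) {
    abort(paste0("species missing from distance matrix: ",
                 paste(missing_sp, collapse = ", ")))
  }
  d <- d[freqs$species, freqs$species, drop = FALSE]
  as.numeric(t(p) %*% d %*% p)
}

#' Functional diversity at orders q = 0 and q = 2
#'
#' Attribute (tau-threshold) functional Hill diversity from incidence data.
#' With truncated distances `d_ij(tau) = min(d_ij, tau)` and pooled
#' incidence-based relative abundances `p_i = Y_i/U`, each species carries a
#' functional-group abundance `a_i = sum_j (1 - d_ij(tau)/tau) p_j` and
#' weight `v_i = p_i / a_i`.
#'
#' At `q = 0` the estimate is the expected weighted count of detected
#' groups, `FD0(t) = sum_i v_i * pi_i^g(t)`, where `pi_i^g(t)` is the exact
#' subsampling detection probability of the *group* around species i — a
#' group counts as present in a unit whenever any species within `tau` of
#' its anchor is detected there, since such a species carries part of the
#' group's attribute mass. Extrapolation beyond `T` adds the Chao2
#' unseen-species estimate weighted by the mean `v` of unique species. At `q = 2` the ratio-of-moments estimator of [td_q2()] is
#' applied to group abundances accumulated per sampling unit, which
#' requires the species co-occurrence counts that [to_frequencies()]
#' attaches. When all interspecific distances reach `tau` the estimator
#' reduces exactly to the taxonomic one at every `t`; when all distances
#' are zero the assemblage is a single functional group and the estimate is
#' 1 at the observed sample size.
#'
#' @inheritParams fd_tau
#' @param q Hill order, 0 or 2.
#' @param t Integer vector of sampling-unit counts (`t >= 2` when `q = 2`).
#' @param tau Distinctness threshold in `(0, ...]`; `NULL` (default) uses
#'   [fd_tau()] on the pooled assemblage.
#' @return Numeric vector of effective functional-group numbers.
#' @export
fd_hill <- function(freqs, dist, q, t, tau = NULL) {
  stopifnot(inherits(freqs, "incidence_freq"))
  if (!q %in% c(0, 2)) abort("q must be 0 or 2")
  if (is.null(tau)) tau <- fd_tau(freqs, dist)
  if (!is.finite(tau) || tau <= 0) abort("tau must be > 0")
  T_units <- attr(freqs, "T")
  U <- attr(freqs, "U")
  if (nrow(freqs) == 0) return(rep(0, length(t)))
  nu <- .nu_matrix(dist, freqs$species, tau)
  Z <- as.numeric(nu %*% freqs$Y) # group "incidence abundance" per species
  v <- freqs$Y / Z

  if (q == 0) {
    t <- as.integer(t)
    if (any(t < 1)) abort("t must be >= 1")
    # group-level incidence: units where any species within tau of the
    # anchor occurs; needs the unit-level detections when available
    X <- attr(freqs, "X")
    Yg <- if (!is.null(X)) {
      hits <- (X[, freqs$species, drop = FALSE] %*% (nu > 0)) > 0
      as.integer(colSums(hits))
    } else {
      freqs$Y # raw frequencies: fall back to species-level detection
    }
    vapply(t, function(ti) {
      if (ti <= T_units) {
        sum(v * .detect_prob(Yg, T_units, ti))
      } else {
        Q0 <- chao2_q0hat(freqs)
        v_unseen <- if (attr(freqs, "Q1") > 0) mean(v[freqs$Y == 1]) else 1
        sum(v) + v_unseen * Q0 *
          .extrap_gain(attr(freqs, "Q1"), Q0, T_units, ti)
      }
    }, numeric(1))
  } else {
    t <- as.numeric(t)
    if (any(t < 2)) abort("t must be >= 2 for q = 2")
    if (T_units < 2) abort("q = 2 requires at least two sampling units observed")
    cooc <- attr(freqs, "cooc")
    if (is.null(cooc)) {
      abort(paste0(
        "q = 2 functional diversity needs unit-level co-occurrence counts; ",
        "build `freqs` with to_frequencies()"
      ))
    }
    cooc <- cooc[freqs$species, freqs$species, drop = FALSE]
    # sum over units of squared per-unit group abundance:
    # sum_u A_iu^2 = nu_i' C nu_i with C the co-occurrence count matrix
    sumsq <- rowSums((nu %*% cooc) * nu)
    vapply(t, function(ti) {
      m1 <- ti * Z / T_units
      m2 <- (ti / T_units) * sumsq +
        ti * (ti - 1) / (T_units * (T_units - 1)) * (Z^2 - sumsq)
      sum(v * m1)^2 / sum(v * m2)
    }, numeric(1))
  }
}
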