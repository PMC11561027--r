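#' Inner-region perturbation term of the dispersion relation
#'
#' When the rim of a radially symmetric tumor is perturbed by a cosine mode of
#' wavenumber `k`, the induced perturbations of the interior (quiescent and
#' necrotic) interfaces feed back on the rim velocity through the oxygen
#' field. Writing `theta_n = r_n^2 / r_p^2` and `theta_q = r_q^2 / r_p^2`,
#' that feedback enters the dispersion relation through the combined term
#' \deqn{\frac{1 - r_p^{2k}}{1 - \theta_n^k r_p^{2k}}\left(\mu_{death}
#'   \theta_n^k + \frac{\theta_q^k - \theta_n^k}{\theta_q - \theta_n}
#'   \frac{\theta_q}{k}\right),}
#' which is nonnegative (it is subtracted inside the dispersion relation, so
#' it always damps) and vanishes as `k` grows whenever `r_p < 1`.
#'
#' @param k perturbation mode, integer `>= 1`.
#' @param theta_n,theta_q squared interior radii relative to `r_p^2`, with
#'   `0 <= theta_n <= theta_q <= 1` (equalities handled as limits).
#' @param r_p rim radius in `(0, 1)`.
#' @param mu_death death rate.
#' @return The (nonnegative) damping term.
#' @export
inner_term <- function(k, theta_n, theta_q, r_p, mu_death) {
  stopifnot(k >= 1, k == round(k), theta_n >= 0, theta_q >= theta_n,
            theta_q <= 1, r_p > 0, r_p < 1, mu_death >= 0)
  dq <- if (theta_q == theta_n) {
    # limit of the difference quotient: d(theta^k)/dtheta
    if (theta_n == 0 && k == 1) 1 else k * theta_n^(k - 1)
  } else (theta_q^k - theta_n^k) / (theta_q - theta_n)
  (1 - r_p^(2 * k)) / (1 - theta_n^k * r_p^(2 * k)) *
    (mu_death * theta_n^k + dq * theta_q / k)
}

#' Relative rim velocity (growth-phase discriminant)
#'
#' `Delta_theta = r_p' / r_p`, the relative velocity of the tumor rim,
#' discriminates the growth phases that control morphological stability:
#' it equals exactly 1/2 in the nutrient-rich phase (`r_n = r_q = 0`,
#' exponential growth), decreases towards 0 as starvation sets in, and is 0
#' at the stationary state.
#'
#' @param state a [radial_state()].
#' @param mu_death death rate.
#' @return `r_p' / r_p` (1/time).
#' @export
growth_phase_discriminant <- function(state, mu_death) {
  radial_rhs(state, mu_death) / (2 * state$r_p^2)
}

#' Linear-stability dispersion relation for rim perturbations
#'
#' Growth rate `Lambda(k)` of a small cosine perturbation of mode `k >= 1` of
#' the rim of a radially symmetric tumor. The rate decomposes into a
#' Saffman-Taylor contribution (viscous fingering, controlled by the external
#' Darcy ratio `D_ext` and the rim velocity), an inner-region perturbation
#' contribution (oxygen-mediated damping from the displaced interior
#' interfaces, see [inner_term()]), and a surface-tension contribution
#' `-sigma k (k^2 - 1) / r_p^3` that stabilizes all modes `k >= 2`. `D_ext`
#' may be `Inf` (free-flowing external medium, the most stabilizing
#' Saffman-Taylor case) and the prefactors are then evaluated as their limits.
#'
#' @param k perturbation mode, integer `>= 1` (vectorized).
#' @param state a [radial_state()].
#' @param mu_death death rate.
#' @param D_ext external Darcy ratio in `(0, Inf]`.
#' @param sigma surface tension.
#' @return A data frame of class `"dispersion_result"` with columns `k`,
#'   `Lambda` and the three components `saffman_taylor` (which also carries
#'   the baseline destabilizing rate of the starved phase),
#'   `inner_perturbation` and `surface_tension`; the components sum to
#'   `Lambda`.
#' @export
#' @examples
#' st <- find_stationary(preset("table2_pde"))
#' dispersion(1:8, st, mu_death = 1.35, D_ext = Inf, sigma = 1e-4)
dispersion <- function(k, state, mu_death, D_ext = Inf, sigma = 0) {
  stopifnot(inherits(state, "radial_state"), all(k >= 1), all(k == round(k)),
            mu_death >= 0, D_ext > 0, sigma >= 0)
  rp <- state$r_p
  th_n <- state$r_n^2 / rp^2
  th_q <- state$r_q^2 / rp^2
  delta <- growth_phase_discriminant(state, mu_death)
  stratio <- if (is.infinite(D_ext)) -1 else (1 - D_ext) / (1 + D_ext)
  w <- if (is.infinite(D_ext)) 1 else D_ext / (1 + D_ext)
  A <- vapply(k, inner_term, numeric(1), theta_n = th_n, theta_q = th_q,
              r_p = rp, mu_death = mu_death)
  st_term <- delta * (stratio * k - 1) + w
  in_term <- -w * A
  sig_term <- -w * sigma * k * (k^2 - 1) / rp^3
  out <- data.frame(k = k, Lambda = st_term + in_term + sig_term,
                    saffman_taylor = st_term, inner_perturbation = in_term,
                    surface_tension = sig_term)
  class(out) <- c("dispersion_result", class(out))
  out
}

#' Growth rate of the creeping mode (k = 1)
#'
#' The first cosine mode translates the tumor's center of mass, so the tumor
#' "creeps" towards the oxygen source. Its closed-form rate
#' \deqn{\Lambda(1) = \frac{D_{ext}}{1 + D_{ext}}
#'   \frac{\mu_{death} r_n^2 + r_q^2}{r_p^2}
#'   \frac{r_p^2 - r_n^2}{1 - r_n^2} \ge 0}
#' is never negative and is independent of surface tension, so creeping
#' can only be avoided if neither a quiescent nor a necrotic region exists.
#'
#' @param state a [radial_state()].
#' @param mu_death death rate.
#' @param D_ext external Darcy ratio in `(0, Inf]`.
#' @return `Lambda(1)` (1/time).
#' @export
creeping_rate <- function(state, mu_death, D_ext = Inf) {
  stopifnot(inherits(state, "radial_state"), mu_death >= 0, D_ext > 0)
  w <- if (is.infinite(D_ext)) 1 else D_ext / (1 + D_ext)
  rn <- state$r_n; rq <- state$r_q; rp <- state$r_p
  w * (mu_death * rn^2 + rq^2) / rp^2 * (rp^2 - rn^2) / (1 - rn^2)
}

#' Surface tension required to stabilize mode k
#'
#' The dispersion relation is affine in `sigma`, so the threshold surface
#' tension at which `Lambda(k) = 0` has a closed form. At a stationary state
#' the threshold is bounded above by `r_p^3 / (k (k^2 - 1))` (see
#' [sigma_bound()]); stabilizing all modes `k >= 2` is therefore guaranteed
#' by `sigma = r_p^3 / 6`.
#'
#' @param k perturbation mode, integer `>= 2` (mode 1 is unaffected by
#'   surface tension).
#' @param state a [radial_state()], normally stationary.
#' @param mu_death death rate.
#' @param D_ext external Darcy ratio in `(0, Inf]`.
#' @return The threshold value of `sigma`.
#' @export
#' @examples
#' st <- find_stationary(preset("table2_pde"))
#' sigma_stable(2, st, mu_death = 1.35)   # approx 3.1e-3
sigma_stable <- function(k, state, mu_death, D_ext = Inf) {
  stopifnot(all(k == round(k)))
  if (any(k < 2))
    stop("mode k = 1 (creeping) is unaffected by surface tension; k >= 2 required",
         call. = FALSE)
  d0 <- dispersion(k, state, mu_death, D_ext = D_ext, sigma = 0)
  w <- if (is.infinite(D_ext)) 1 else D_ext / (1 + D_ext)
  # Lambda(k; sigma) = Lambda(k; 0) - w * sigma * k (k^2 - 1) / r_p^3
  d0$Lambda * state$r_p^3 / (w * k * (k^2 - 1))
}

#' Upper bound on the stabilizing surface tension at stationarity
#'
#' At a stationary state the inner-region perturbation term only damps, so
#' the surface tension needed to stabilize mode `k` never exceeds
#' `r_p^3 / (k (k^2 - 1))`.
#'
#' @param k perturbation mode, integer `>= 2`.
#' @param r_p rim radius.
#' @return The bound.
#' @export
sigma_bound <- function(k, r_p) {
  stopifnot(all(k == round(k)), r_p > 0)
  if (any(k < 2)) stop("k >= 2 required", call. = FALSE)
  r_p^3 / (k * (k^2 - 1))
}
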