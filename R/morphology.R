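#' Isoperimetric roundness of a contour
#'
#' `4 pi Area / Perimeter^2`, which is 1 for a circle and smaller for any
#' other shape (isoperimetric inequality). The perimeter of lattice-extracted
#' contours is measured on a lightly vertex-smoothed polygon, since raw
#' marching-squares staircases systematically inflate the perimeter and bias
#' roundness low (a 5-point span calibrates a lattice disc at `h = 0.01` to
#' within 1% of perfect roundness); area and perimeter come from the same
#' smoothed polygon, so the isoperimetric bound is never violated.
#'
#' @param contour a [extract_boundary()] contour.
#' @param smooth vertex-smoothing span (odd; 1 disables).
#' @return Roundness in `(0, 1]`.
#' @seealso [roundness_ratio()] to apply the formula to analytic area and
#'   perimeter values.
#' @export
roundness <- function(contour, smooth = 5) {
  stopifnot(inherits(contour, "boundary_contour"))
  poly <- smoothed_polygon(contour, smooth)
  roundness_ratio(poly$area, poly$perimeter)
}

#' @rdname roundness
#' @param area,perimeter enclosed area and perimeter of a closed curve.
#' @export
roundness_ratio <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive", call. = FALSE)
  4 * pi * area / perimeter^2
}

#' Areas of the proliferative, quiescent and necrotic regions
#'
#' Classifies the tumor by the local oxygen level and measures each class
#' area. For a lattice population the area is `h^2` times the voxel count:
#' proliferative (living, `c >= kappa_prol`), quiescent (living below the
#' proliferation threshold, including starved voxels that have not yet died)
#' and necrotic (`u = -1`). For a mean-field density the classes come from
#' the same labels the solver uses (necrotic = the starved contact region of
#' the conditional oxygen solve). Note these are disjoint class areas; see
#' [cumulative_volumes()] for the nested discs convention used when
#' comparing against the radially symmetric solution.
#'
#' @param state a `population_state` or `density_state`.
#' @param c oxygen `scalar_field` for this state.
#' @param params a [model_params()].
#' @return Named numeric vector `c(V_p, V_q, V_n)`.
#' @export
region_volumes <- function(state, c, params) {
  params <- as_model_params(params)
  h2 <- state$grid$h^2
  cv <- c$values
  if (inherits(state, "population_state")) {
    u <- state$u
    living <- u >= 1L
    c(V_p = h2 * sum(living & cv >= params$kappa_prol),
      V_q = h2 * sum(living & cv < params$kappa_prol),
      V_n = h2 * sum(u == -1L))
  } else if (inherits(state, "density_state")) {
    lab <- .density_labels(state, c, params)
    c(V_p = h2 * sum(lab$prolif),
      V_q = h2 * sum(lab$quiescent),
      V_n = h2 * sum(lab$necrotic))
  } else stop("state must be a population_state or density_state", call. = FALSE)
}

#' Nested-disc volumes from class areas
#'
#' The radially symmetric analysis reports `V_p = pi r_p^2`,
#' `V_q = pi r_q^2`, `V_n = pi r_n^2` — nested discs, not annuli. This
#' converts the disjoint class areas of [region_volumes()] (or a trajectory
#' containing such columns) to that convention.
#'
#' @param v named vector with `V_p`, `V_q`, `V_n` class areas, or a data
#'   frame with those columns.
#' @return Same shape with `V_n` unchanged, `V_q = V_q + V_n` and
#'   `V_p` the total area.
#' @export
cumulative_volumes <- function(v) {
  if (is.data.frame(v)) {
    out <- v
    out$V_q <- v$V_q + v$V_n
    out$V_p <- v$V_p + v$V_q + v$V_n
    out
  } else {
    c(V_p = unname(v["V_p"] + v["V_q"] + v["V_n"]),
      V_q = unname(v["V_q"] + v["V_n"]),
      V_n = unname(v["V_n"]))
  }
}

#' Fourier amplitudes of boundary perturbation modes
#'
#' Resamples the contour's radial function `r(theta)` about a center onto a
#' uniform angular grid and returns the magnitude of each cosine/sine pair,
#' so a boundary `r0 + a cos(k (theta - phase))` yields `alpha_k ~ a`
#' regardless of phase. Requires the contour to be star-shaped about the
#' center (the radial function single-valued); mode analysis on contours
#' that fail this (e.g. after tumor splitting) is unreliable and raises an
#' error.
#'
#' @param contour a [extract_boundary()] contour.
#' @param k_max largest mode to report.
#' @param center length-2 center; defaults to the contour's area centroid.
#' @param n_theta angular resample resolution.
#' @return Numeric vector `alpha_1 .. alpha_k_max`, with the mean radius in
#'   attribute `r0`.
#' @export
boundary_modes <- function(contour, k_max = 8, center = NULL, n_theta = 256) {
  stopifnot(inherits(contour, "boundary_contour"), k_max >= 1)
  if (is.null(center)) center <- .contour_centroid(contour)
  x <- contour$x - center[1]; y <- contour$y - center[2]
  th <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  # star-shape check: theta must wind monotonically once around the center
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi
  wind <- sum(dth) + ((th[1] - th[length(th)] + pi) %% (2 * pi) - pi)
  if (abs(abs(wind) - 2 * pi) > 0.1 || sum(sign(dth) != sign(wind)) > length(dth) * 0.2)
    stop("contour is not star-shaped about the center; mode analysis unreliable",
         call. = FALSE)
  o <- order(th)
  th <- th[o]; r <- r[o]
  thg <- seq(-pi, pi, length.out = n_theta + 1)[-(n_theta + 1)]
  rg <- stats::approx(c(th - 2 * pi, th, th + 2 * pi), rep(r, 3), xout = thg,
                      rule = 2)$y
  X <- stats::fft(rg)
  alpha <- 2 * Mod(X[2:(k_max + 1)]) / n_theta
  names(alpha) <- paste0("alpha_", seq_len(k_max))
  attr(alpha, "r0") <- mean(rg)
  alpha
}

.contour_centroid <- function(contour) {
  x <- contour$x; y <- contour$y
  n <- length(x); j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * A)
}

#' Fit an exponential growth rate to a mode-amplitude series
#'
#' Least-squares slope of `log(alpha)` against time, the standard way to
#' measure a perturbation growth rate for comparison against the dispersion
#' relation. Non-positive amplitudes are dropped (flagged via the
#' `n_dropped` attribute).
#'
#' @param t times (>= 5 usable samples required).
#' @param alpha amplitudes at `t`.
#' @return List with `rate`, `se` (standard error of the slope) and `n`.
#' @export
fit_mode_growth <- function(t, alpha) {
  stopifnot(length(t) == length(alpha))
  ok <- is.finite(alpha) & alpha > 0 & is.finite(t)
  if (sum(ok) < 5)
    stop("need at least 5 positive amplitude samples", call. = FALSE)
  fit <- stats::lm(log(alpha[ok]) ~ t[ok])
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(list(rate = unname(sm[2, 1]), se = unname(sm[2, 2]), n = sum(ok)),
            n_dropped = sum(!ok))
}

#' Moving-window standard deviation of a trajectory column
#'
#' Used to quantify fluctuation of the roundness signal over time.
#'
#' @param t times.
#' @param x values.
#' @param window window width in time units.
#' @return Vector of windowed standard deviations at each `t`.
#' @export
moving_sd <- function(t, x, window = 1) {
  vapply(t, function(tc) {
    sel <- abs(t - tc) <= window / 2 & is.finite(x)
    if (sum(sel) >= 2) stats::sd(x[sel]) else NA_real_
  }, numeric(1))
}
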