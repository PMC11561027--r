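#' Nondimensional model parameters
#'
#' Bundles the nondimensional parameter set shared by the stochastic lattice
#' (DLCM) model, the mean-field PDE model and the analytical reductions.
#' Units are fixed by the nondimensionalization `R = mu_prol = c_out = D = 1`:
#' lengths are fractions of the oxygen-source radius, time is measured in
#' proliferation times, and oxygen in units of the far-field concentration.
#'
#' @param mu_death death rate of oxygen-starved cells (per proliferation time).
#' @param mu_deg degradation rate of necrotic material (lattice model only).
#' @param kappa_prol oxygen threshold above which cells proliferate.
#' @param kappa_death oxygen threshold below which cells die; must satisfy
#'   `kappa_death <= kappa_prol <= 1`.
#' @param lambda ratio of oxygen consumption to diffusion rate.
#' @param sigma surface-tension coefficient of the Young-Laplace rim condition.
#' @param p_ext ambient pressure outside the tumor.
#' @param D_ext Darcy coefficient of the external medium relative to the tumor
#'   tissue; `Inf` (the default) means the external medium offers no
#'   resistance, the regime used by the 2D solvers.
#' @param D1 rate conversion factor for moves into empty voxels.
#' @param D2 rate conversion factor for moves from doubly- into singly-occupied
#'   voxels.
#'
#' @return An object of class `"model_params"`: a named list of the above.
#' @seealso [preset()] for the published parameter sets.
#' @export
#' @examples
#' model_params(mu_death = 1.35, lambda = 1.15)
model_params <- function(mu_death = 0.5, mu_deg = 0.05, kappa_prol = 0.94,
                         kappa_death = 0.93, lambda = 1, sigma = 0,
                         p_ext = 0, D_ext = Inf, D1 = 1, D2 = 25) {
  p <- list(mu_death = mu_death, mu_deg = mu_deg, kappa_prol = kappa_prol,
            kappa_death = kappa_death, lambda = lambda, sigma = sigma,
            p_ext = p_ext, D_ext = D_ext, D1 = D1, D2 = D2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter '", nm, "' must be a single number", call. = FALSE)
    if (v < 0) stop("parameter '", nm, "' must be nonnegative", call. = FALSE)
  }
  if (p$kappa_death > p$kappa_prol)
    stop("kappa_death must not exceed kappa_prol", call. = FALSE)
  if (p$kappa_prol > 1)
    stop("kappa_prol must not exceed the far-field oxygen level 1", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Nondimensional tumor model parameters (R = mu_prol = c_out = D = 1):\n")
  vals <- vapply(unclass(x), function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", format(names(vals), width = 12), " ", vals, collapse = "\n"), "\n")
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x)) return(do.call(model_params, x))
  stop("cannot interpret 'params'; see ?model_params", call. = FALSE)
}
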