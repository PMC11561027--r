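#' Perturbed-disc initial conditions
#'
#' Builds the standard initial tumor: voxels whose center lies inside
#' `r0 (1 + eps cos(k (theta - phase)))` are singly occupied (lattice model)
#' or at unit density (mean-field model), all living. `k = 0` or `eps = 0`
#' gives an unperturbed disc; a single cosine mode seeds the perturbations
#' whose growth rates the dispersion relation predicts.
#'
#' @param grid a [build_lattice()] grid.
#' @param r0 base radius; must satisfy `h < r0` and `r0 (1 + eps) < 1`.
#' @param eps relative perturbation amplitude (warn above 0.1, error above
#'   0.2: the linear analysis assumes small perturbations).
#' @param k perturbation mode (integer >= 0).
#' @param phase perturbation phase (radians).
#' @return List with `population` (a [population_state()]) and `density`
#'   (a [density_state()]).
#' @export
#' @examples
#' g <- build_lattice(0.02)
#' init <- make_initial_disc(g, r0 = 0.25, eps = 0.05, k = 4)
make_initial_disc <- function(grid, r0, eps = 0, k = 0, phase = 0) {
  stopifnot(inherits(grid, "lattice_grid"), k >= 0, k == round(k))
  if (r0 <= grid$h) stop("r0 must exceed the lattice spacing", call. = FALSE)
  if (abs(eps) > 0.2) stop("|eps| > 0.2 is outside the small-perturbation regime",
                           call. = FALSE)
  if (abs(eps) > 0.1) warning("|eps| > 0.1 stretches the small-perturbation assumption")
  if (r0 * (1 + abs(eps)) >= 1)
    stop("perturbed disc must stay inside the unit domain", call. = FALSE)
  th <- atan2(grid$y, grid$x)
  rb <- r0 * (1 + eps * cos(k * (th - phase)))
  inside <- grid$r <= rb
  u <- integer(grid$n^2)
  u[inside] <- 1L
  list(population = population_state(grid, u),
       density = density_state(grid, as.numeric(inside)))
}

#' Published parameter presets
#'
#' The standard parameter sets used in the reference experiments:
#' `"table2_dlcm"` and `"table2_pde"` are the standard lattice parameters
#' and their effective mean-field counterparts (`mu_death` 0.5 vs 1.35,
#' `lambda` 1 vs 1.15, thresholds 0.94/0.93, `D_ext = Inf`, `D2 = 25`);
#' the `"fig10_*"` variants lower the death threshold to 0.92 for a thinner
#' proliferating rim (effective `mu_death = 1.0`, `lambda = 1.1`).
#' Surface tension is experiment-specific and left at 0; set it explicitly.
#'
#' @param name one of `"table2_dlcm"`, `"table2_pde"`, `"fig10_dlcm"`,
#'   `"fig10_pde"`.
#' @return A [model_params()].
#' @export
#' @examples
#' preset("table2_pde")$mu_death   # 1.35
preset <- function(name) {
  presets <- list(
    table2_dlcm = model_params(mu_death = 0.5, mu_deg = 0.05,
                               kappa_prol = 0.94, kappa_death = 0.93,
                               lambda = 1, p_ext = 0, D_ext = Inf, D2 = 25),
    table2_pde  = model_params(mu_death = 1.35, mu_deg = 0,
                               kappa_prol = 0.94, kappa_death = 0.93,
                               lambda = 1.15, p_ext = 0, D_ext = Inf),
    fig10_dlcm  = model_params(mu_death = 0.5, mu_deg = 0.05,
                               kappa_prol = 0.94, kappa_death = 0.92,
                               lambda = 1, p_ext = 0, D_ext = Inf, D2 = 25),
    fig10_pde   = model_params(mu_death = 1.0, mu_deg = 0,
                               kappa_prol = 0.94, kappa_death = 0.92,
                               lambda = 1.1, p_ext = 0, D_ext = Inf))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

# derive per-replicate seeds from a master seed (counter-based, 32-bit safe)
replicate_seeds <- function(master, n) {
  vapply(seq_len(n), function(i) {
    s <- (as.numeric(master) * 48271 + i * 16807) %% 2147483647
    as.integer(max(s, 1))
  }, integer(1))
}

#' Run a configured experiment
#'
#' Dispatches a structured configuration to the appropriate model driver
#' (stochastic lattice, mean-field PDE, radially symmetric ODE, or
#' dispersion-relation table), loops over replicates with derived seeds, and
#' optionally writes trajectory tables plus a manifest. The configuration
#' mirrors the YAML schema read by [read_experiment_config()]:
#'
#' * `model`: `"dlcm"`, `"pde"`, `"radial"` or `"stability"`.
#' * `preset` or `params`: parameter source; `sigma` may override.
#' * `grid`: list with `h`.
#' * `init`: list with `r0`, `eps`, `mode_k`, `phase`.
#' * `run`: list with `t_end`, `seed`, `replicates`, `dt_fields`,
#'   `noise_amp`, `output_times`, `modes` (stability).
#'
#' @param config named list (or a [model_params()]-compatible subset).
#' @param out_dir optional output directory; trajectories are written as
#'   tab-separated tables plus a `manifest.yaml` echoing the configuration,
#'   package version and per-replicate seeds.
#' @return List with `results` (one trajectory per replicate, or the table
#'   for the deterministic models) and `seeds`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), !is.null(config$model))
  params <- if (!is.null(config$preset)) preset(config$preset)
            else as_model_params(config$params)
  if (!is.null(config$sigma)) params$sigma <- config$sigma
  run <- config$run %||% list()
  t_end <- run$t_end %||% 10
  master_seed <- run$seed %||% 1L
  nrep <- run$replicates %||% 1L
  seeds <- replicate_seeds(master_seed, nrep)
  model <- match.arg(config$model, c("dlcm", "pde", "radial", "stability"))
  results <- switch(model,
    dlcm = {
      grid <- build_lattice(config$grid$h %||% 0.02)
      init <- with_defaults_init(config$init)
      st0 <- make_initial_disc(grid, init$r0, init$eps, init$mode_k,
                               init$phase)$population
      lapply(seeds, function(s)
        simulate_dlcm(st0, params, t_end, seed = s,
                      dt_fields = run$dt_fields %||% 0.05,
                      output_times = run$output_times))
    },
    pde = {
      grid <- build_lattice(config$grid$h %||% 0.02)
      init <- with_defaults_init(config$init)
      st0 <- make_initial_disc(grid, init$r0, init$eps, init$mode_k,
                               init$phase)$density
      lapply(seeds, function(s)
        run_pde(st0, params, t_end, seed = s,
                noise_amp = run$noise_amp %||% 1e-3,
                output_times = run$output_times))
    },
    radial = {
      init <- with_defaults_init(config$init)
      list(integrate_radial(init$r0, params, t_end))
    },
    stability = {
      st <- find_stationary(params)
      modes <- run$modes %||% 1:8
      list(dispersion(modes, st, params$mu_death, params$D_ext, params$sigma))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(results))
      utils::write.table(results[[i]],
                         file.path(out_dir, sprintf("%s_rep%02d.tsv", model, i)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- list(config = config,
                     package_version = as.character(utils::packageVersion("avtumor")),
                     seeds = seeds,
                     wall_clock = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(results = results, seeds = seeds)
}

with_defaults_init <- function(init) {
  init <- init %||% list()
  list(r0 = init$r0 %||% 0.25, eps = init$eps %||% 0,
       mode_k = init$mode_k %||% 0, phase = init$phase %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment configuration file
#'
#' @param path YAML configuration path.
#' @return The configuration list (see [run_experiment()]).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Render a lattice state as an image
#'
#' @param x a `population_state` or `density_state`.
#' @param ... passed to [graphics::image()].
#' @export
plot.population_state <- function(x, ...) {
  cols <- c("gray20", "white", "forestgreen", "firebrick")
  graphics::image(x$grid$axis, x$grid$axis, matrix(x$u, x$grid$n, x$grid$n),
                  col = cols, breaks = c(-1.5, -0.5, 0.5, 1.5, 2.5),
                  asp = 1, xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' @rdname plot.population_state
#' @export
plot.density_state <- function(x, ...) {
  graphics::image(x$grid$axis, x$grid$axis, matrix(x$rho, x$grid$n, x$grid$n),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  asp = 1, xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Write a lattice snapshot as an integer raster (PNG or text)
#'
#' @param state a `population_state`.
#' @param file output path; `.png` requires the `png` package, any other
#'   extension writes a delimited integer matrix.
#' @return The file path, invisibly.
#' @export
write_snapshot <- function(state, file) {
  m <- matrix(state$u, state$grid$n, state$grid$n)
  if (grepl("\\.png$", file)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required for PNG output", call. = FALSE)
    png::writePNG((t(m[, rev(seq_len(ncol(m)))]) + 1) / 3, file)
  } else {
    utils::write.table(m, file, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
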