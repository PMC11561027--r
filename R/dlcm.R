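#' Lattice cell population state
#'
#' The stochastic model tracks an integer occupancy per voxel:
#' `-1` necrotic, `0` empty, `1` singly occupied (relaxed), `2` doubly
#' occupied (above carrying capacity, a pressure source). The tumor domain is
#' the set of voxels with `u != 0`.
#'
#' @param grid a [build_lattice()] grid.
#' @param u integer occupancy vector over all lattice nodes.
#' @param t simulation time.
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(grid, u, t = 0) {
  stopifnot(inherits(grid, "lattice_grid"), length(u) == grid$n^2)
  if (!all(u %in% c(-1L, 0L, 1L, 2L)))
    stop("occupancies must lie in {-1, 0, 1, 2}", call. = FALSE)
  structure(list(grid = grid, u = as.integer(u), t = t),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(paste0("population state at t = %.4g: %d living cells ",
                     "(%d single, %d double), %d necrotic voxels\n"),
              x$t, sum(pmax(x$u, 0)), sum(x$u == 1), sum(x$u == 2),
              sum(x$u == -1)))
  invisible(x)
}

#' Pressure-driven movement event rates
#'
#' Converts the current pressure field into Poisson rates for cell moves.
#' The edge flux `I = p_i - p_j` (see [edge_flux()]) is the pressure gradient
#' integrated over the shared voxel edge, i.e. an area flux; moving one cell
#' transports the voxel area `h^2`, so a cell moves from voxel `i` to an
#' adjacent voxel `j` at rate `D1 * max(I, 0) / h^2` when `j` is empty, and
#' at rate `D2 * max(I, 0) / h^2` when `i` is doubly and `j` singly
#' occupied. This per-cell conversion makes the realized boundary speed
#' match the Darcy velocity `-D grad p` independently of the lattice
#' resolution, so the stochastic and mean-field models share one clock.
#' When surface tension is active (`sigma > 0`), moves between neighboring
#' singly occupied voxels on the tumor rim are also offered at the `D1`
#' rate: these moves are how the Young-Laplace rim pressure smooths the
#' boundary.
#' Negative fluxes offer no event, and necrotic voxels neither move nor
#' accept movers.
#'
#' @param state a [population_state()].
#' @param p pressure `scalar_field` from [solve_pressure()] for this state.
#' @param params a [model_params()].
#' @return An event schedule: data frame with columns `kind`
#'   (`"move_to_empty"` / `"move_to_single"`), `i`, `j`, `rate`, containing
#'   only strictly positive rates (possibly zero rows).
#' @export
movement_rates <- function(state, p, params) {
  params <- as_model_params(params)
  stopifnot(inherits(state, "population_state"), inherits(p, "scalar_field"))
  core <- .movement_rates_core(state$grid, state$u, p$values, params)
  data.frame(kind = .KIND[core$kind], i = core$i, j = core$j, rate = core$rate)
}

#' Oxygen-driven cell event rates
#'
#' Phenotypes follow the local oxygen level instantaneously: a singly
#' occupied voxel with `c >= kappa_prol` divides at the (unit) proliferation
#' rate; any living voxel with `c < kappa_death` loses cells at rate
#' `mu_death` per cell; necrotic voxels degrade at rate `mu_deg`, freeing
#' the voxel. Voxels at intermediate oxygen are quiescent and fire no event.
#' Doubly occupied voxels are above carrying capacity and do not divide
#' further.
#'
#' @param state a [population_state()].
#' @param c oxygen `scalar_field` from [solve_oxygen()] for this state.
#' @param params a [model_params()].
#' @return Event schedule data frame with columns `kind` (`"proliferate"` /
#'   `"die"` / `"degrade"`), `i`, `j` (`NA`), `rate`; positive rates only.
#' @export
cell_event_rates <- function(state, c, params) {
  params <- as_model_params(params)
  stopifnot(inherits(state, "population_state"))
  core <- .cell_rates_core(state$u, c$values, params,
                           c("proliferate", "die", "degrade"))
  data.frame(kind = .KIND[core$kind], i = core$i, j = core$j, rate = core$rate)
}

#' Apply a single event to a population state
#'
#' Moves decrement the source voxel and increment the target; proliferation
#' fills a singly occupied voxel (`1 -> 2`); death removes one cell, turning
#' a singly occupied voxel necrotic (`1 -> -1`) or relaxing a doubly occupied
#' one (`2 -> 1`); degradation frees a necrotic voxel (`-1 -> 0`).
#'
#' @param state a [population_state()].
#' @param event one row of an event schedule (list or single-row data frame
#'   with `kind`, `i`, `j`).
#' @return The updated `population_state` (time unchanged).
#' @export
apply_event <- function(state, event) {
  u <- state$u
  i <- as.integer(event$i)
  kind <- as.character(event$kind)
  bad <- function() stop("event '", kind, "' inconsistent with state at voxel ",
                         i, " (stale schedule?)", call. = FALSE)
  if (kind %in% c("move_to_empty", "move_to_single")) {
    j <- as.integer(event$j)
    if (!j %in% state$grid$nbr[i, ]) bad()
    if (u[i] < 1L) bad()
    if (kind == "move_to_empty" && u[j] != 0L) bad()
    if (kind == "move_to_single" && u[j] != 1L) bad()
    u[i] <- u[i] - 1L
    u[j] <- u[j] + 1L
  } else if (kind == "proliferate") {
    if (u[i] != 1L) bad()
    u[i] <- 2L
  } else if (kind == "die") {
    if (u[i] == 1L) u[i] <- -1L
    else if (u[i] == 2L) u[i] <- 1L
    else bad()
  } else if (kind == "degrade") {
    if (u[i] != -1L) bad()
    u[i] <- 0L
  } else stop("unknown event kind '", kind, "'", call. = FALSE)
  population_state(state$grid, u, state$t)
}

#' Simulate the stochastic lattice tumor model
#'
#' Exact continuous-time Markov chain simulation (Gillespie's direct method)
#' of the lattice tumor: at each step the total event rate sets an
#' exponential waiting time and one channel fires, after which the pressure
#' field is re-solved (every event changes the pressure sources or the tumor
#' domain). The oxygen field and the rim curvature used by the Young-Laplace
#' condition are refreshed on a coarser cadence `dt_fields`, which is
#' legitimate because oxygen is quasi-stationary and evolves on the (slow)
#' growth timescale; set `dt_fields` to a very small value to approach
#' per-event refreshing.
#'
#' @param initial a [population_state()].
#' @param params a [model_params()].
#' @param t_end final time.
#' @param seed integer seed fixing the random stream (identical seeds give
#'   identical trajectories).
#' @param dt_fields oxygen/curvature refresh interval (proliferation times).
#' @param output_times times at which to record summaries (defaults to
#'   `dt_fields` multiples up to `t_end`).
#' @param channels subset of `c("move", "proliferate", "die", "degrade")` to
#'   simulate; restricting channels is useful for validating the chain
#'   against master-equation solutions on small systems.
#' @param record_states if `TRUE`, keep the full occupancy vector at each
#'   output time (in `attr(, "states")`).
#' @param summaries if `FALSE`, skip the per-output-time morphology summaries
#'   (the trajectory then only carries `t`); useful for large replicate
#'   ensembles where only the final state matters.
#' @param curvature_window passed to [estimate_curvature()].
#' @return A data frame trajectory with columns `t`, `N_living`,
#'   `N_necrotic`, `V_p`, `V_q`, `V_n` (class areas, see
#'   [region_volumes()]), `roundness`, `com_x`, `com_y`. Attribute `frozen`
#'   is `TRUE` if the chain became absorbing before `t_end`; attribute
#'   `final` holds the final `population_state`.
#' @export
simulate_dlcm <- function(initial, params, t_end, seed,
                          dt_fields = 0.05, output_times = NULL,
                          channels = c("move", "proliferate", "die", "degrade"),
                          record_states = FALSE, summaries = TRUE,
                          curvature_window = NULL) {
  params <- as_model_params(params)
  stopifnot(inherits(initial, "population_state"), t_end > initial$t)
  set.seed(as.integer(seed))
  grid <- initial$grid
  n2 <- grid$n^2
  u <- initial$u
  t <- initial$t
  do_move <- "move" %in% channels
  if (is.null(output_times))
    output_times <- seq(initial$t, t_end, by = max(dt_fields, (t_end - initial$t) / 200))
  output_times <- sort(unique(c(output_times, t_end)))
  recs <- vector("list", length(output_times))
  states <- if (record_states) vector("list", length(output_times)) else NULL
  next_out <- 1L
  frozen <- FALSE
  epochs <- unique(c(seq(initial$t, t_end, by = dt_fields), t_end, output_times))
  epochs <- sort(epochs[epochs > initial$t + 1e-12])
  for (ep in epochs) {
    # refresh the slow fields: oxygen, contour, rim curvature
    oxy_vals <- .oxygen_or_flat(population_state(grid, u, t), params)$values
    contour <- curv <- NULL
    if (params$sigma > 0 && any(u != 0L)) {
      contour <- tryCatch(extract_boundary(grid, as.numeric(u != 0L)),
                          error = function(e) NULL)
      if (!is.null(contour) && length(contour$x) >= 3)
        curv <- estimate_curvature(contour, curvature_window)
      else contour <- NULL
    }
    sigC <- rep(NA_real_, n2)       # per-epoch cache of sigma * C per rim node
    bc_fun <- function(nodes) {
      if (params$sigma <= 0 || is.null(contour))
        return(rep(params$p_ext, length(nodes)))
      miss <- nodes[is.na(sigC[nodes])]
      if (length(miss))
        sigC[miss] <<- params$sigma * .nearest_curvature(grid, miss, contour, curv)
      params$p_ext + sigC[nodes]
    }
    pr <- NULL
    stale_pressure <- TRUE
    repeat {
      if (!any(u != 0L)) { frozen <- TRUE; t <- ep; break }
      if (do_move && stale_pressure) {
        pr <- .pressure_core(grid, u, params, bc_fun)
        stale_pressure <- FALSE
      }
      mv <- if (do_move) .movement_rates_core(grid, u, pr$values, params)
            else list(i = integer(0), j = integer(0), rate = numeric(0),
                      kind = integer(0))
      cl <- .cell_rates_core(u, oxy_vals, params, channels)
      rates <- c(mv$rate, cl$rate)
      Rtot <- sum(rates)
      if (Rtot <= 0) { t <- ep; break }
      dt <- stats::rexp(1, Rtot)
      if (t + dt > ep) { t <- ep; break }
      t <- t + dt
      pick <- findInterval(stats::runif(1) * Rtot, cumsum(rates),
                           rightmost.closed = TRUE) + 1L
      pick <- min(pick, length(rates))
      nmv <- length(mv$rate)
      if (pick <= nmv) {
        i <- mv$i[pick]; j <- mv$j[pick]
        u[i] <- u[i] - 1L
        u[j] <- u[j] + 1L
        stale_pressure <- TRUE
      } else {
        q <- pick - nmv
        i <- cl$i[q]
        kind <- cl$kind[q]
        if (kind == 3L) {           # proliferate: new pressure source
          u[i] <- 2L
          stale_pressure <- TRUE
        } else if (kind == 4L) {    # die
          if (u[i] == 2L) { u[i] <- 1L; stale_pressure <- TRUE }
          else u[i] <- -1L          # domain and sources unchanged
        } else {                    # degrade: voxel freed, domain shrinks
          u[i] <- 0L
          stale_pressure <- TRUE
        }
      }
    }
    while (next_out <= length(output_times) && output_times[next_out] <= t + 1e-12) {
      recs[[next_out]] <- if (summaries) {
        st_rec <- population_state(grid, u, output_times[next_out])
        .dlcm_summary(st_rec, .oxygen_or_flat(st_rec, params), params,
                      output_times[next_out])
      } else data.frame(t = output_times[next_out])
      if (record_states) states[[next_out]] <- u
      next_out <- next_out + 1L
    }
    if (frozen && all(u == 0L)) break
  }
  final <- population_state(grid, u, t)
  while (next_out <= length(output_times)) {
    recs[[next_out]] <- if (summaries)
      .dlcm_summary(final, .oxygen_or_flat(final, params), params,
                    output_times[next_out])
    else data.frame(t = output_times[next_out])
    if (record_states) states[[next_out]] <- u
    next_out <- next_out + 1L
  }
  out <- do.call(rbind, recs)
  attr(out, "frozen") <- frozen
  attr(out, "final") <- final
  if (record_states) attr(out, "states") <- states
  out
}

.oxygen_or_flat <- function(state, params) {
  if (any(state$u > 0L) && params$lambda > 0) solve_oxygen(state, params)
  else {
    vals <- rep(1, state$grid$n^2)
    scalar_field(state$grid, vals, seq_along(vals),
                 list(nodes = integer(), values = numeric()), 0)
  }
}

.dlcm_summary <- function(state, oxy, params, t) {
  vols <- region_volumes(state, oxy, params)
  rnd <- NA_real_
  cont <- tryCatch(extract_boundary(state$grid, as.numeric(state$u != 0L)),
                   error = function(e) NULL)
  if (!is.null(cont)) rnd <- tryCatch(roundness(cont), error = function(e) NA_real_)
  w <- pmax(state$u, 0) + as.numeric(state$u == -1L)
  com <- if (sum(w) > 0)
    c(sum(state$grid$x * w), sum(state$grid$y * w)) / sum(w) else c(NA_real_, NA_real_)
  data.frame(t = t, N_living = sum(pmax(state$u, 0)),
             N_necrotic = sum(state$u == -1L),
             V_p = vols[["V_p"]], V_q = vols[["V_q"]], V_n = vols[["V_n"]],
             roundness = rnd, com_x = com[1], com_y = com[2])
}
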