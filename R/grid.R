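#' Build a Cartesian lattice covering a disc
#'
#' Nodes sit at `(i h, j h)` on the square bounding the disc of the given
#' radius (the computational domain whose boundary carries the oxygen
#' source). Adjacency is 4-connected; the discrete Laplacian is the standard
#' 5-point stencil.
#'
#' @param h lattice spacing (nondimensional length), `0 < h < radius`.
#' @param radius domain radius (default 1, the oxygen-source circle).
#' @return An object of class `"lattice_grid"`: a list with spacing `h`,
#'   per-axis node count `n`, node coordinates `x`, `y` (length `n^2`,
#'   column-major with x varying fastest), logical `mask` of nodes inside the
#'   disc, radii `r`, and an `n^2 x 4` integer matrix `nbr` of neighbor
#'   indices (`NA` off-lattice, order W/E/S/N).
#' @export
#' @examples
#' g <- build_lattice(0.05, 1)
#' g$n        # 41 nodes per axis
build_lattice <- function(h, radius = 1) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be a positive number", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive number", call. = FALSE)
  if (h >= radius) stop("h must be smaller than radius", call. = FALSE)
  m <- ceiling(radius / h - 1e-9)
  ax <- seq(-m, m) * h
  n <- length(ax)
  x <- rep(ax, times = n)
  y <- rep(ax, each = n)
  idx <- matrix(seq_len(n * n), n, n)
  pad <- function(M, side) {
    # neighbor index in each direction, NA at the lattice edge
    out <- matrix(NA_integer_, n, n)
    switch(side,
           W = out[-1, ] <- idx[-n, ],
           E = out[-n, ] <- idx[-1, ],
           S = out[, -1] <- idx[, -n],
           N = out[, -n] <- idx[, -1])
    as.integer(out)
  }
  nbr <- cbind(W = pad(idx, "W"), E = pad(idx, "E"),
               S = pad(idx, "S"), N = pad(idx, "N"))
  r <- sqrt(x^2 + y^2)
  structure(list(h = h, radius = radius, n = n, axis = ax, x = x, y = y,
                 r = r, mask = r <= radius + 1e-12, nbr = nbr,
                 cache = new.env(parent = emptyenv())),
            class = "lattice_grid")
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat(sprintf("lattice: %d x %d nodes, h = %g, disc radius %g (%d nodes inside)\n",
              x$n, x$n, x$h, x$radius, sum(x$mask)))
  invisible(x)
}

#' Assemble the masked 5-point Laplace system
#'
#' Builds the sparse symmetric positive-definite system for
#' `-Laplacian(u) = s` on an active node set, with Dirichlet values on
#' neighboring nodes eliminated into the right-hand side. The stencil is
#' restricted to neighbors that are either active or Dirichlet; neighbors in
#' neither set are dropped (zero-flux), a situation that does not arise in
#' the solvers because every active node's neighbors are classified.
#'
#' @param grid a [build_lattice()] grid.
#' @param active integer indices of unknown nodes.
#' @param dirichlet list with integer `nodes` and numeric `values` (recycled).
#' @return List with sparse matrix `A` (`length(active)` square, units
#'   `1/h^2`), right-hand-side contribution `b` from the Dirichlet data,
#'   `active`, and `local` (a full-lattice vector mapping node index to row).
#' @export
assemble_laplacian <- function(grid, active, dirichlet = list(nodes = integer(), values = numeric())) {
  stopifnot(inherits(grid, "lattice_grid"))
  active <- as.integer(active)
  if (!length(active)) stop("active node set is empty", call. = FALSE)
  h2 <- grid$h^2
  nn <- grid$n^2
  local <- integer(nn)
  local[active] <- seq_along(active)
  dval <- numeric(nn)
  isdir <- logical(nn)
  if (length(dirichlet$nodes)) {
    isdir[dirichlet$nodes] <- TRUE
    dval[dirichlet$nodes] <- rep_len(dirichlet$values, length(dirichlet$nodes))
    if (any(local[dirichlet$nodes] > 0))
      stop("a node cannot be both active and Dirichlet", call. = FALSE)
  }
  nb <- grid$nbr[active, , drop = FALSE]
  onA <- !is.na(nb) & matrix(local[ifelse(is.na(nb), 1L, nb)] > 0, nrow(nb))
  onD <- !is.na(nb) & matrix(isdir[ifelse(is.na(nb), 1L, nb)], nrow(nb))
  deg <- rowSums(onA | onD)
  ii <- rep(seq_along(active), 4)[onA]
  jj <- local[nb[onA]]
  A <- Matrix::sparseMatrix(i = c(seq_along(active), ii),
                            j = c(seq_along(active), jj),
                            x = c(deg, rep(-1, length(ii))) / h2,
                            dims = c(length(active), length(active)))
  b <- rowSums(matrix(ifelse(onD, dval[ifelse(is.na(nb), 1L, nb)], 0), nrow(nb))) / h2
  list(A = A, b = b, active = active, local = local)
}

# solve the assembled system; checks connectivity errors via solver failure
solve_masked_poisson <- function(sys, source) {
  rhs <- source + sys$b
  sol <- tryCatch(Matrix::solve(sys$A, rhs),
                  error = function(e) stop("singular Laplace system (node with no ",
                                           "path to a Dirichlet node?): ",
                                           conditionMessage(e), call. = FALSE))
  sol <- as.numeric(sol)
  res <- sqrt(sum((as.numeric(sys$A %*% sol) - rhs)^2))
  if (!all(is.finite(sol)) || res > 1e-8 * max(1, sqrt(sum(rhs^2))))
    stop("Laplace solve did not converge (residual ", format(res), ")", call. = FALSE)
  attr(sol, "residual") <- res
  sol
}

#' Extract the tumor boundary contour
#'
#' Traces the 0.5-level contour of a node-centered occupancy (or density)
#' indicator by marching squares, oriented counterclockwise. With several
#' disjoint components (detached cell clusters), the largest by enclosed area
#' is returned and the rest are flagged via the `n_components` attribute.
#'
#' @param grid a [build_lattice()] grid.
#' @param indicator numeric vector over all lattice nodes (e.g. 1 inside the
#'   tumor, 0 outside, or a cell density).
#' @param level contour level (default 0.5).
#' @return An object of class `"boundary_contour"`: list with open vertex
#'   rings `x`, `y` (first vertex not repeated), `area` (enclosed, shoelace)
#'   and `perimeter` (raw polygon length).
#' @export
extract_boundary <- function(grid, indicator, level = 0.5) {
  stopifnot(inherits(grid, "lattice_grid"), length(indicator) == grid$n^2)
  if (!any(indicator > level)) stop("empty domain: no nodes above the contour level",
                                    call. = FALSE)
  z <- matrix(indicator, grid$n, grid$n)
  cl <- grDevices::contourLines(grid$axis, grid$axis, z, levels = level)
  if (!length(cl)) stop("empty domain: no closed contour found", call. = FALSE)
  polys <- lapply(cl, function(p) {
    x <- p$x; y <- p$y
    if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
      x <- x[-length(x)]; y <- y[-length(y)]
    }
    list(x = x, y = y, area = .shoelace(x, y))
  })
  # drop degenerate open fragments (grazing contacts yield 2-point segments)
  nvert <- vapply(polys, function(p) length(p$x), integer(1))
  polys <- polys[nvert >= 3]
  if (!length(polys)) stop("empty domain: no closed contour found", call. = FALSE)
  areas <- vapply(polys, function(p) p$area, numeric(1))
  keep <- which.max(abs(areas))
  p <- polys[[keep]]
  if (p$area < 0) { p$x <- rev(p$x); p$y <- rev(p$y); p$area <- -p$area }
  per <- sum(sqrt(diff(c(p$x, p$x[1]))^2 + diff(c(p$y, p$y[1]))^2))
  structure(list(x = p$x, y = p$y, area = p$area, perimeter = per),
            class = "boundary_contour",
            n_components = sum(abs(areas) > .Machine$double.eps))
}

.shoelace <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' @export
print.boundary_contour <- function(x, ...) {
  cat(sprintf("boundary contour: %d vertices, area %.5g, perimeter %.5g",
              length(x$x), x$area, x$perimeter))
  nc <- attr(x, "n_components")
  if (!is.null(nc) && nc > 1) cat(sprintf(" (largest of %d components)", nc))
  cat("\n")
  invisible(x)
}

#' @export
plot.boundary_contour <- function(x, ..., asp = 1) {
  graphics::plot(c(x$x, x$x[1]), c(x$y, x$y[1]), type = "l", asp = asp,
                 xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Per-vertex curvature of a closed contour
#'
#' Estimates signed curvature at every vertex from the circle through the
#' vertices `i - w, i, i + w` (`w = floor(window / 2)` steps along the ring),
#' followed by a moving average of width `window`. For a counterclockwise
#' contour, locally convex arcs have positive curvature, so the Young-Laplace
#' rim condition `p = p_ext - sigma C` lowers the pressure on bulges.
#' Collinear triples give curvature 0.
#'
#' @param contour a [extract_boundary()] contour.
#' @param window odd integer `>= 3`; controls both the chord length and the
#'   smoothing span. The default (`NULL`) adapts to the contour resolution
#'   (about a twelfth of the vertex count, clamped to `[5, 41]`), which keeps
#'   the chord long relative to the voxel staircase while still resolving
#'   low-order shape modes.
#' @return Numeric vector of curvatures (1/length), one per vertex.
#' @export
estimate_curvature <- function(contour, window = NULL) {
  stopifnot(inherits(contour, "boundary_contour"))
  x <- contour$x; y <- contour$y
  n <- length(x)
  if (n < 3) stop("contour must have at least 3 vertices", call. = FALSE)
  if (is.null(window)) {
    window <- max(5L, min(41L, as.integer(round(n / 12))))
    if (window %% 2L == 0L) window <- window + 1L
  }
  stopifnot(window >= 3, window %% 2 == 1)
  w <- min(floor(window / 2), floor((n - 1) / 2))
  im <- ((seq_len(n) - 1 - w) %% n) + 1
  ip <- ((seq_len(n) - 1 + w) %% n) + 1
  # turn from the incoming to the outgoing chord: positive = left = convex (CCW)
  ax <- x - x[im]; ay <- y - y[im]
  bx <- x[ip] - x; by <- y[ip] - y
  cross <- ax * by - ay * bx
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2
  cx <- x[ip] - x[im]; cy <- y[ip] - y[im]
  c2 <- cx^2 + cy^2
  denom <- sqrt(a2 * b2 * c2)
  kap <- ifelse(denom > 0, 2 * cross / denom, 0)   # signed: + for left turns (CCW convex)
  # periodic moving average over `window` vertices
  if (n > window) {
    kk <- c(kap[(n - floor(window / 2) + 1):n], kap, kap[1:floor(window / 2)])
    kap <- stats::filter(kk, rep(1 / window, window), sides = 2)
    kap <- as.numeric(kap[(floor(window / 2) + 1):(floor(window / 2) + n)])
  }
  kap
}

# periodic moving average of a vertex ring
.smooth_ring <- function(x, smooth) {
  n <- length(x)
  if (smooth <= 1 || n <= smooth) return(x)
  w <- floor(smooth / 2)
  xx <- c(x[(n - w + 1):n], x, x[1:w])
  as.numeric(stats::filter(xx, rep(1 / smooth, smooth), sides = 2))[(w + 1):(w + n)]
}

# vertex-smoothed polygon (raw marching-squares staircases bias the
# perimeter high); area and perimeter are measured on the same polygon so
# the isoperimetric bound is preserved
smoothed_polygon <- function(contour, smooth = 3) {
  x <- .smooth_ring(contour$x, smooth)
  y <- .smooth_ring(contour$y, smooth)
  list(x = x, y = y, area = abs(.shoelace(x, y)),
       perimeter = sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)))
}

contour_perimeter <- function(contour, smooth = 5) {
  if (length(contour$x) < 3) return(contour$perimeter)
  smoothed_polygon(contour, smooth)$perimeter
}
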