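# Two-dimensional Gaussian dispersal kernels with a sticky coastal boundary,
# and the recruitment metrics derived from them.
#
# Grid convention: cells are dx = 1 km alongshore by dy = 5 km cross-shore
# (5 km^2 pixels).  The coastal row of cells is CENTERED on the shoreline,
# spanning y in [-dy/2, +dy/2]; all probability mass south of its lower edge
# (y < -dy/2, i.e. inland) is folded into the coastal cell of the same
# alongshore column.  Cell masses are exact Gaussian CDF differences on the
# cell edges, with open-ended outermost cells so total mass is exactly 1.

#' Gaussian dispersal density
#'
#' One-dimensional probability density of larval displacement `d` for an
#' advective length scale `LA` (the mean displacement) and stochastic
#' length scale `LS` (the spread):
#' `(1 / (sqrt(2 pi) LS)) * exp(-(d - LA)^2 / (2 LS^2))`.
#'
#' @param d Displacement, km (vectorised).
#' @param LA Advective length scale, km.
#' @param LS Stochastic length scale, km (> 0).
#' @return Probability density, km^-1.
#' @export
gaussian_density <- function(d, LA, LS) {
  if (any(LS <= 0)) stop("gaussian_density: LS must be > 0")
  stats::dnorm(d, mean = LA, sd = LS)
}

#' Specify the dispersal-kernel grid
#'
#' @param dx Alongshore cell width, km (default 1).
#' @param dy Cross-shore cell width, km (default 5; cells are 5 km^2).
#' @param x_range Optional length-2 alongshore extent, km.  `NULL` sizes
#'   the grid automatically to hold > 99.99% of each event's mass.
#' @param y_max Optional offshore extent, km (`NULL` = automatic).
#' @return A list of class `kernel_grid_spec`.
#' @export
kernel_grid_spec <- function(dx = 1, dy = 5, x_range = NULL, y_max = NULL) {
  if (dx <= 0 || dy <= 0) stop("kernel_grid_spec: dx and dy must be > 0")
  structure(list(dx = dx, dy = dy, x_range = x_range, y_max = y_max),
            class = "kernel_grid_spec")
}

# pull LA/LS out of an event_length_scales row, list, or season summary
.as_scales <- function(event) {
  if (inherits(event, "season_length_scales")) {
    s <- event$summary
    event <- as.list(stats::setNames(s$mean, s$metric))
  }
  if (is.data.frame(event)) {
    if (nrow(event) != 1) stop("expected a single event")
    event <- as.list(event)
  }
  need <- c("LA_x", "LS_x", "LA_y", "LS_y")
  if (!all(need %in% names(event)))
    stop("event must carry LA_x, LS_x, LA_y, LS_y")
  if (event$LS_x < 0 || event$LS_y < 0) stop("LS must be >= 0")
  event[need]
}

.resolve_grid <- function(spec, LA_x, LS_x, LA_y, LS_y) {
  dx <- spec$dx; dy <- spec$dy
  if (is.null(spec$x_range)) {
    pad <- 8 * max(LS_x, dx)
    xr <- c(min(LA_x) - pad, max(LA_x) + pad)
  } else xr <- spec$x_range
  x <- dx * (floor(xr[1] / dx):ceiling(xr[2] / dx))
  if (is.null(spec$y_max)) {
    ym <- max(max(LA_y + 8 * LS_y), 2 * dy)
  } else ym <- spec$y_max
  y <- dy * (0:max(1, ceiling(ym / dy)))
  list(x = x, y = y, dx = dx, dy = dy)
}

# cell masses of a 1-D Gaussian on centers with open-ended end cells;
# `fold_low = TRUE` additionally absorbs all mass below the first cell's
# upper edge into the first cell (the sticky coastal boundary on y)
.cell_masses <- function(centers, h, LA, LS) {
  breaks <- c(-Inf, centers[-length(centers)] + h / 2, Inf)
  if (LS == 0) {
    p <- numeric(length(centers))
    i <- findInterval(LA, breaks[-1], left.open = FALSE) + 1L
    p[min(max(i, 1L), length(centers))] <- 1
    return(p)
  }
  diff(stats::pnorm(breaks, mean = LA, sd = LS))
}

#' Dispersal kernel for a single release event
#'
#' Builds the 2-D settlement-probability field of one release event from
#' its advective and stochastic length scales.  Alongshore (x) and
#' cross-shore (y) marginal cell masses are exact Gaussian CDF differences
#' on the cell edges; the 2-D cell mass is their product (the two axes are
#' uncorrelated).  The coast is a sticky boundary: all mass below the
#' coastal row's lower edge is retained in the coastal cell of the same
#' alongshore column, so the kernel integrates to exactly 1 with no inland
#' mass.
#'
#' @param event Length scales: a one-row [event_length_scales()] data
#'   frame, a named list with `LA_x`, `LS_x`, `LA_y`, `LS_y` (km), or a
#'   [season_length_scales()] object (its season means are used).
#' @param grid A [kernel_grid_spec()].
#' @return Object of class `dispersal_kernel`: list with `x`, `y` (cell
#'   centres, km; `y[1] = 0` is the coastal row), `dx`, `dy`, `prob`
#'   (matrix `length(x)` by `length(y)` of cell masses) and `n_events`.
#' @export
event_kernel <- function(event, grid = kernel_grid_spec()) {
  sc <- .as_scales(event)
  g <- .resolve_grid(grid, sc$LA_x, sc$LS_x, sc$LA_y, sc$LS_y)
  px <- .cell_masses(g$x, g$dx, sc$LA_x, sc$LS_x)
  py <- .cell_masses(g$y, g$dy, sc$LA_y, sc$LS_y)
  structure(list(x = g$x, y = g$y, dx = g$dx, dy = g$dy,
                 prob = outer(px, py), n_events = 1L),
            class = "dispersal_kernel")
}

#' Ensemble dispersal kernel over many release events
#'
#' Unweighted average of the per-event kernels of all valid events on a
#' common grid (every release contributes the same number of larvae).
#' Mass 1 is preserved exactly.
#'
#' @param events Data frame of per-event length scales (e.g. the `events`
#'   element of [season_length_scales()]); rows with `valid = FALSE` or
#'   non-finite scales are dropped.
#' @param grid A [kernel_grid_spec()].
#' @return A `dispersal_kernel` with `n_events` set to the number of
#'   events averaged.
#' @export
ensemble_kernel <- function(events, grid = kernel_grid_spec()) {
  if (inherits(events, "season_length_scales")) events <- events$events
  if ("valid" %in% names(events)) events <- events[events$valid, , drop = FALSE]
  events <- events[stats::complete.cases(
    events[, c("LA_x", "LS_x", "LA_y", "LS_y")]), , drop = FALSE]
  n <- nrow(events)
  if (n < 1) stop("ensemble_kernel: need at least one valid event")
  g <- .resolve_grid(grid, events$LA_x, max(events$LS_x),
                     events$LA_y, events$LS_y)
  mx <- vapply(seq_len(n), function(i)
    .cell_masses(g$x, g$dx, events$LA_x[i], events$LS_x[i]),
    numeric(length(g$x)))
  my <- vapply(seq_len(n), function(i)
    .cell_masses(g$y, g$dy, events$LA_y[i], events$LS_y[i]),
    numeric(length(g$y)))
  # mean over events of the per-event outer products, as one matrix product
  prob <- (mx %*% t(my)) / n
  structure(list(x = g$x, y = g$y, dx = g$dx, dy = g$dy,
                 prob = prob, n_events = n),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("<dispersal_kernel>", length(x$x), "x", length(x$y), "cells (",
      x$dx, "km x", x$dy, "km ),", x$n_events, "event(s)\n")
  cat(sprintf("  total mass %.9f, coastal-row mass %.4f\n",
              sum(x$prob), recruitment_success(x)))
  invisible(x)
}

#' @export
as.data.frame.dispersal_kernel <- function(x, ...) {
  data.frame(x_km = rep(x$x, times = length(x$y)),
             y_km = rep(x$y, each = length(x$x)),
             prob = as.vector(x$prob),
             density_per_km2 = as.vector(x$prob) / (x$dx * x$dy))
}

#' Write a dispersal kernel to CSV
#'
#' Long format: `x_km`, `y_km`, `prob`, `density_per_km2`.
#'
#' @param kernel A `dispersal_kernel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  utils::write.csv(as.data.frame(kernel), path, row.names = FALSE)
  invisible(path)
}

#' Theoretical recruitment success
#'
#' Total probability mass retained in the coastal row of cells: the
#' fraction of settlement-competent larvae that end their pelagic phase at
#' the coast.  For a single event this equals
#' `pnorm((dy/2 - LA_y) / LS_y)`.
#'
#' @param kernel A `dispersal_kernel`.
#' @return Fraction in `[0, 1]`.
#' @export
recruitment_success <- function(kernel) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  sum(kernel$prob[, 1])
}

#' Location and density of peak coastal recruitment
#'
#' The coastal cell with maximum probability density.  Density is cell
#' mass divided by cell area (km^-2); the offset is the cell's alongshore
#' centre (negative = west of the emission point).  Ties are broken toward
#' the emission point.
#'
#' @param kernel A `dispersal_kernel`.
#' @return List with `offset_km` and `density_per_km2`.
#' @export
peak_recruitment <- function(kernel) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  coastal <- kernel$prob[, 1]
  best <- which(coastal == max(coastal))
  if (length(best) > 1) best <- best[which.min(abs(kernel$x[best]))]
  list(offset_km = kernel$x[best],
       density_per_km2 = coastal[best] / (kernel$dx * kernel$dy))
}

#' Maximum kernel density
#'
#' Maximum probability density over the whole kernel, the coastal row
#' only, or the offshore cells only (y > 0).
#'
#' @param kernel A `dispersal_kernel`.
#' @param where One of `"anywhere"`, `"coastal"`, `"offshore"`.
#' @return List with `x_km`, `y_km`, `density_per_km2`.
#' @export
max_density <- function(kernel,
                        where = c("anywhere", "coastal", "offshore")) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  where <- match.arg(where)
  p <- kernel$prob
  if (where == "coastal") p[, -1] <- -Inf
  if (where == "offshore") p[, 1] <- -Inf
  ij <- arrayInd(which.max(p), dim(p))
  list(x_km = kernel$x[ij[1]], y_km = kernel$y[ij[2]],
       density_per_km2 = kernel$prob[ij] / (kernel$dx * kernel$dy))
}

#' Monte-Carlo particle oracle for the analytic kernel
#'
#' Independent check of [event_kernel()]: displaces `n_particles` larvae
#' by Gaussian draws with the event's length scales on each axis, applies
#' the sticky coastal boundary, and bins them on the same grid.
#'
#' @param event As in [event_kernel()].
#' @param n_particles Number of particles (>= 1000).
#' @param seed Integer seed, or `NULL`.
#' @param grid A `kernel_grid_spec`, or a `dispersal_kernel` whose grid is
#'   reused (so the histogram is directly comparable).
#' @return A `dispersal_kernel` holding the empirical cell frequencies.
#' @export
particle_oracle <- function(event, n_particles = 1e6, seed = NULL,
                            grid = kernel_grid_spec()) {
  sc <- .as_scales(event)
  if (n_particles < 1000) stop("particle_oracle: n_particles must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(grid, "dispersal_kernel")) {
    g <- list(x = grid$x, y = grid$y, dx = grid$dx, dy = grid$dy)
  } else {
    g <- .resolve_grid(grid, sc$LA_x, sc$LS_x, sc$LA_y, sc$LS_y)
  }
  draw <- function(mu, sd) if (sd == 0) rep(mu, n_particles) else
    stats::rnorm(n_particles, mu, sd)
  px <- draw(sc$LA_x, sc$LS_x)
  py <- draw(sc$LA_y, sc$LS_y)
  bx <- c(-Inf, g$x[-length(g$x)] + g$dx / 2, Inf)
  by <- c(-Inf, g$y[-length(g$y)] + g$dy / 2, Inf)  # first bin = coast + inland
  ix <- findInterval(px, bx[-1], left.open = FALSE) + 1L
  iy <- findInterval(py, by[-1], left.open = FALSE) + 1L
  ix <- pmin(ix, length(g$x)); iy <- pmin(iy, length(g$y))
  counts <- tabulate(ix + (iy - 1L) * length(g$x),
                     nbins = length(g$x) * length(g$y))
  structure(list(x = g$x, y = g$y, dx = g$dx, dy = g$dy,
                 prob = matrix(counts / n_particles,
                               length(g$x), length(g$y)),
                 n_events = 1L),
            class = "dispersal_kernel")
}

#' Total-variation distance between two kernels
#'
#' `0.5 * sum(|p1 - p2|)` over cells; the kernels must share a grid.
#'
#' @param a,b `dispersal_kernel` objects on identical grids.
#' @return Numeric in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  stopifnot(inherits(a, "dispersal_kernel"), inherits(b, "dispersal_kernel"))
  if (!identical(a$x, b$x) || !identical(a$y, b$y))
    stop("tv_distance: kernels are on different grids")
  0.5 * sum(abs(a$prob - b$prob))
}
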