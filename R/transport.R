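# Lagrangian particle tracing on a solved flow field, and trap/bypass
# transmission statistics.
#
# Tracers are massless (Stokes number << 1 at the device Reynolds numbers,
# see reynolds_number()): they follow streamlines of the depth-averaged
# field.  Finite particle size enters through the seeding band and the
# region a particle centre may occupy (wall exclusion by one radius), not
# through resolved particle-wall hydrodynamics.

# bilinear interpolation on a regular grid of values `G` whose [1,1] entry
# sits at (ox, oy), spacing dx; queries outside return 0
bilinear <- function(G, ox, oy, dx, px, py) {
  gx <- (px - ox) / dx; gy <- (py - oy) / dx
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  n1 <- nrow(G); n2 <- ncol(G)
  gv <- function(ii, jj) {
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    out <- numeric(length(ii))
    out[ok] <- G[cbind(ii[ok], jj[ok])]
    out
  }
  i0 <- i0 + 1L; j0 <- j0 + 1L   # to 1-based
  gv(i0, j0) * (1 - fx) * (1 - fy) + gv(i0 + 1L, j0) * fx * (1 - fy) +
    gv(i0, j0 + 1L) * (1 - fx) * fy + gv(i0 + 1L, j0 + 1L) * fx * fy
}

# velocity sampler on the staggered field (face-centred bilinear)
field_velocity <- function(field, px, py) {
  d <- field$domain; dx <- d$dx
  u <- bilinear(field$u_faces, d$x0, d$y0 + dx / 2, dx, px, py)
  v <- bilinear(field$v_faces, d$x0 + dx / 2, d$y0, dx, px, py)
  list(u = u, v = v)
}

# distance-to-wall grid (um) for the solve mask, used for seeding bands
# and finite-size wall exclusion during tracing
wall_distance_grid <- function(field) {
  mask_wall_distance(field$mask, field$dx)
}

#' Trace tracer particles through a solved flow field
#'
#' Seeds particles across the inlet and advects them along the
#' depth-averaged velocity field with adaptive fourth-order (RK4) stepping
#' (per-particle CFL-limited steps) until they cross a junction gate, exit
#' the domain, or stall.  Fates are assigned at the first gate crossing:
#' `trap` (Path-1 gate), `bypass` (bypass gate), `exit` (outlet reached in a
#' gateless domain), or `stuck`.
#'
#' @param field a [solve_field()] result.
#' @param n number of tracers.
#' @param diameter_um particle diameter; the seeding band and accessible
#'   region are shrunk by one radius.
#' @param seeding `"uniform"` (stratified-uniform positions across the
#'   accessible inlet width) or `"flux"` (positions drawn from the inlet
#'   velocity profile, so each tracer carries equal flux).
#' @param seed RNG seed (recorded in the result).
#' @param store_paths keep trajectories (thinned) for plotting.
#' @param cfl step-length fraction of a cell.
#' @param max_time_factor advection-time budget in units of
#'   (domain length / inlet velocity).
#' @return Object of class `particle_trace`: `$fates` tibble (particle,
#'   y0, fate, time, steps) and optionally `$paths`.
#' @export
trace_particles <- function(field, n = 100, diameter_um = 0,
                            seeding = c("uniform", "flux"), seed = 1L,
                            store_paths = FALSE, cfl = 0.4,
                            max_time_factor = 200) {
  seeding <- match.arg(seeding)
  d <- field$domain; dx <- d$dx
  r <- diameter_um / 2
  u_in <- field$inlet_velocity
  wd <- wall_distance_grid(field)
  r_eff <- max(r, dx * 0.51)   # keep centres off the wall cells
  set.seed(seed)

  # seeding band: accessible inlet width, one cell in from the boundary
  x_seed <- d$x0 + 2 * dx
  ys <- d$yc[field$mask[2, ]]
  wd_col <- wd[2, field$mask[2, ]]
  ys <- ys[wd_col > r_eff]
  lo <- min(ys) - dx / 2; hi <- max(ys) + dx / 2
  if (seeding == "uniform") {
    # deterministic uniform spacing (stratum midpoints) across the band
    y0 <- lo + (seq_len(n) - 0.5) / n * (hi - lo)
  } else {
    yy <- seq(lo, hi, length.out = 512)
    uu <- pmax(field_velocity(field, rep(x_seed, 512), yy)$u, 0)
    cdf <- cumsum(uu); cdf <- cdf / cdf[length(cdf)]
    q <- (seq_len(n) - stats::runif(n)) / n
    y0 <- stats::approx(cdf, yy, xout = q, ties = "ordered", rule = 2)$y
  }

  px <- rep(x_seed, n); py <- y0
  fate <- rep(NA_character_, n)
  t_now <- numeric(n); steps <- integer(n); stall <- integer(n)
  alive <- rep(TRUE, n)
  gates <- d$gates
  x_out <- d$x0 + (d$nx - 1) * dx
  t_max <- max_time_factor * (d$nx * dx) / u_in
  stall_speed <- 1e-5 * u_in
  paths <- if (store_paths) list(tibble::tibble(
    particle = seq_len(n), t = 0, x = px, y = py)) else NULL

  it <- 0L
  while (any(alive)) {
    it <- it + 1L
    ia <- which(alive)
    x1 <- px[ia]; y1 <- py[ia]
    vel <- field_velocity(field, x1, y1)
    sp <- sqrt(vel$u^2 + vel$v^2)
    dt <- cfl * dx / pmax(sp, stall_speed)
    # RK4
    k1u <- vel$u; k1v <- vel$v
    v2 <- field_velocity(field, x1 + dt / 2 * k1u, y1 + dt / 2 * k1v)
    v3 <- field_velocity(field, x1 + dt / 2 * v2$u, y1 + dt / 2 * v2$v)
    v4 <- field_velocity(field, x1 + dt * v3$u, y1 + dt * v3$v)
    nx_ <- x1 + dt / 6 * (k1u + 2 * v2$u + 2 * v3$u + v4$u)
    ny_ <- y1 + dt / 6 * (k1v + 2 * v2$v + 2 * v3$v + v4$v)
    # wall handling: halve the step while the endpoint is outside the
    # accessible region (distance to wall below the particle radius)
    for (half in 1:6) {
      bad <- bilinear(wd, d$x0 + dx / 2, d$y0 + dx / 2, dx, nx_, ny_) < r_eff
      if (!any(bad)) break
      nx_[bad] <- (x1[bad] + nx_[bad]) / 2
      ny_[bad] <- (y1[bad] + ny_[bad]) / 2
    }
    moved2 <- (nx_ - x1)^2 + (ny_ - y1)^2
    stall[ia] <- ifelse(sp < stall_speed | moved2 < (1e-4 * dx)^2,
                        stall[ia] + 1L, 0L)
    t_now[ia] <- t_now[ia] + dt
    steps[ia] <- steps[ia] + 1L
    px[ia] <- nx_; py[ia] <- ny_

    f <- rep(NA_character_, length(ia))
    if (!is.null(gates$gap)) {
      g <- gates$gap
      # transmitted into the trapping path: crossed the gap plane...
      f[is.na(f) & x1 < g$x & nx_ >= g$x & ny_ > g$y[1] & ny_ < g$y[2]] <- "trap"
      b <- gates$bypass
      f[is.na(f) & y1 < b$y & ny_ >= b$y & nx_ > b$x[1] & nx_ < b$x[2]] <- "bypass"
      # ...or wedged (steric arrest) in the trap pocket before the gap
      p1 <- gates$path1
      wedged <- is.na(f) & stall[ia] > 500L & nx_ > p1$x & nx_ < g$x &
        ny_ > g$y[1] & ny_ < g$y[2]
      f[wedged] <- "trap"
    }
    f[is.na(f) & nx_ >= x_out] <- "exit"
    f[is.na(f) & stall[ia] > 500L] <- "stuck"
    f[is.na(f) & t_now[ia] > t_max] <- "stuck"
    fate[ia[!is.na(f)]] <- f[!is.na(f)]
    alive[ia[!is.na(f)]] <- FALSE
    if (store_paths && it %% 10L == 0L) {
      paths[[length(paths) + 1L]] <-
        tibble::tibble(particle = ia, t = t_now[ia], x = px[ia], y = py[ia])
    }
  }

  fates <- tibble::tibble(particle = seq_len(n), y0 = y0, fate = fate,
                          time_s = t_now, steps = steps)
  structure(list(
    fates = fates,
    paths = if (store_paths) dplyr::arrange(purrr::list_rbind(paths),
                                            .data$particle, .data$t) else NULL,
    seeding = seeding, seed = seed, n = n, diameter_um = diameter_um,
    valve_on = field$valve_on
  ), class = "particle_trace")
}

#' @export
print.particle_trace <- function(x, ...) {
  tab <- table(x$fates$fate)
  cat(sprintf("<particle_trace> %d tracers (%s seeding, seed %d): %s\n",
              x$n, x$seeding, x$seed,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @method tidy particle_trace
#' @export
tidy.particle_trace <- function(x, ...) x$fates

#' Transmission probabilities from a traced ensemble
#'
#' Fractions of tracers whose first gate crossing was the trapping path vs
#' the bypass loop; fates partition the ensemble.
#'
#' @param trace a [trace_particles()] result.
#' @return Object of class `transmission_result`.
#' @export
transmission <- function(trace) {
  f <- trace$fates$fate
  if (anyNA(f)) {
    rlang::abort("unresolved particle fates", class = "traploop_invalid_argument")
  }
  n <- length(f)
  structure(list(
    n = n,
    counts = c(trap = sum(f == "trap"), bypass = sum(f == "bypass"),
               exit = sum(f == "exit"), stuck = sum(f == "stuck")),
    p_trap = sum(f == "trap") / n,
    p_bypass = sum(f == "bypass") / n,
    p_stuck = sum(f == "stuck" | f == "exit") / n,
    seed = trace$seed, seeding = trace$seeding
  ), class = "transmission_result")
}

#' @export
print.transmission_result <- function(x, ...) {
  cat(sprintf("<transmission> n = %d: trap %.1f%%, bypass %.1f%%, other %.1f%% (seed %d)\n",
              x$n, 100 * x$p_trap, 100 * x$p_bypass, 100 * x$p_stuck, x$seed))
  invisible(x)
}

#' @method tidy transmission_result
#' @export
tidy.transmission_result <- function(x, ...) {
  tibble::tibble(fate = names(x$counts), count = as.integer(x$counts),
                 fraction = as.integer(x$counts) / x$n)
}

#' @method glance transmission_result
#' @export
glance.transmission_result <- function(x, ...) {
  tibble::tibble(n = x$n, p_trap = x$p_trap, p_bypass = x$p_bypass,
                 p_stuck = x$p_stuck, seed = x$seed, seeding = x$seeding)
}

#' One-call transmission study on a trap unit
#'
#' Rasterizes, solves the field and traces tracers: the desk-scale analogue
#' of the finite-element trap-unit study (100 tracers released at the
#' inlet, 100 um/s mean inlet velocity, 0 Pa outlet, no-slip walls).
#'
#' @param unit a [trap_unit()].
#' @param dx grid spacing (um).
#' @param valve_on seal the valve chamber.
#' @param n tracers.
#' @param diameter_um particle diameter (um).
#' @param inlet_velocity_um_s mean inlet velocity.
#' @param seeding,seed passed to [trace_particles()].
#' @param fluid a [fluid_spec()].
#' @return A `transmission_result` with the field attached as
#'   `attr(, "field")`.
#' @export
transmission_study <- function(unit, dx = 0.5, valve_on = FALSE, n = 100,
                               diameter_um = 10, inlet_velocity_um_s = 100,
                               seeding = "uniform", seed = 1L,
                               fluid = fluid_water()) {
  dom <- rasterize(unit, dx = dx)
  fld <- solve_field(dom, fluid = fluid,
                     inlet_velocity_um_s = inlet_velocity_um_s,
                     valve_on = valve_on)
  tr <- trace_particles(fld, n = n, diameter_um = diameter_um,
                        seeding = seeding, seed = seed)
  out <- transmission(tr)
  attr(out, "field") <- fld
  attr(out, "trace") <- tr
  out
}
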