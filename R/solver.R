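# Depth-averaged 2-D flow solver.
#
# Model: steady Stokes flow between two plates a distance H apart,
# depth-averaged (Hele-Shaw) with the in-plane viscous term retained
# (Stokes-Brinkman):
#
#     mu lap(u) - (12 mu / H^2) u = grad p,   div(u) = 0
#
# The (12 mu/H^2) u drag is the out-of-plane Poiseuille friction; the
# in-plane Laplacian restores no-slip at the side walls, which dominates the
# resistance of the narrow trapping gaps.  Discretized on a staggered (MAC)
# grid, assembled sparse, solved directly.  Lengths um, velocities um/s,
# pressures Pa.

#' Solve the depth-averaged flow field on a rasterized domain
#'
#' Boundary conditions follow the usual trap-unit simulation setup: uniform
#' (plug) inflow at the stated mean velocity on the inlet strip, zero
#' pressure on the outlet strip, no-slip walls.  `valve_on` removes the
#' valve-chamber cells from the fluid mask, sealing Path 1.
#'
#' @param domain a [rasterize()]d domain (or [straight_channel_domain()]).
#' @param fluid a [fluid_spec()].
#' @param inlet_velocity_um_s mean inlet velocity (um/s).
#' @param valve_on logical; seal the valve chamber.
#' @param tol admissible mass-balance residual (max cell divergence over
#'   inlet divergence scale).
#' @return An object of class `flow_field`: cell-centred `u`, `v` (um/s) and
#'   `p` (Pa) matrices, face-centred arrays for advection, the solve mask,
#'   and the mass-balance residual.
#' @export
solve_field <- function(domain, fluid = fluid_water(),
                        inlet_velocity_um_s = 100, valve_on = FALSE,
                        tol = 1e-8) {
  mu <- fluid$viscosity
  H <- domain$unit$height %||% domain$height
  dx <- domain$dx
  nx <- domain$nx; ny <- domain$ny
  u_in <- inlet_velocity_um_s

  M <- solve_mask(domain, valve_on)
  M <- keep_inlet_component(M, domain)
  inlet_col <- M[1, ]                       # inlet faces on the left edge
  outlet <- matrix(FALSE, nx, ny); outlet[nx, ] <- M[nx, ]

  UF <- M[1:(nx - 1), , drop = FALSE] & M[2:nx, , drop = FALSE]
  VF <- M[, 1:(ny - 1), drop = FALSE] & M[, 2:ny, drop = FALSE]

  nu <- sum(UF); nv <- sum(VF); np <- sum(M)
  uidx <- matrix(0L, nx - 1, ny); uidx[UF] <- seq_len(nu)
  vidx <- matrix(0L, nx, ny - 1); vidx[VF] <- seq_len(nv)
  pidx <- matrix(0L, nx, ny); pidx[M] <- seq_len(np)

  a <- mu / dx^2                 # viscous stencil weight
  cdrag <- 12 * mu / H^2         # Brinkman plate drag
  gi <- 1 / dx                   # pressure gradient / divergence weight

  ti <- vector("list", 24); tj <- vector("list", 24); tv <- vector("list", 24)
  nt <- 0L
  add <- function(i, j, v) {
    nt <<- nt + 1L
    ti[[nt]] <<- i; tj[[nt]] <<- j
    tv[[nt]] <<- if (length(v) == 1L) rep(v, length(i)) else v
  }
  rhs <- numeric(nu + nv + np)

  ## --- u momentum -----------------------------------------------------
  uf <- which(UF, arr.ind = TRUE)
  fi <- uf[, 1]; fj <- uf[, 2]
  row <- uidx[UF]
  self <- rep(-4 * a - cdrag, nu)

  # east neighbour (face fi+1): interior, outlet zero-gradient, or wall
  east_in <- fi + 1L <= nx - 1L
  e_idx <- ifelse(east_in, uidx[cbind(pmin(fi + 1L, nx - 1L), fj)], 0L)
  has_e <- east_in & e_idx > 0L
  add(row[has_e], e_idx[has_e], a)
  at_outlet_e <- (fi + 1L == nx) & outlet[cbind(rep(nx, nu), fj)]
  self[at_outlet_e] <- self[at_outlet_e] + a        # ghost u_E = u
  # otherwise wall face: u_E = 0, nothing to add

  # west neighbour: interior, inlet Dirichlet, or wall
  west_in <- fi - 1L >= 1L
  w_idx <- ifelse(west_in, uidx[cbind(pmax(fi - 1L, 1L), fj)], 0L)
  has_w <- west_in & w_idx > 0L
  add(row[has_w], w_idx[has_w], a)
  at_inlet_w <- (fi == 1L) & inlet_col[fj]
  rhs[row[at_inlet_w]] <- rhs[row[at_inlet_w]] - a * u_in

  # north/south tangential neighbours: interior or no-slip ghost (-u)
  north_in <- fj + 1L <= ny
  n_idx <- ifelse(north_in, uidx[cbind(fi, pmin(fj + 1L, ny))], 0L)
  has_n <- north_in & n_idx > 0L
  add(row[has_n], n_idx[has_n], a)
  self[!has_n] <- self[!has_n] - a
  south_in <- fj - 1L >= 1L
  s_idx <- ifelse(south_in, uidx[cbind(fi, pmax(fj - 1L, 1L))], 0L)
  has_s <- south_in & s_idx > 0L
  add(row[has_s], s_idx[has_s], a)
  self[!has_s] <- self[!has_s] - a

  add(row, row, self)
  # pressure gradient -(p_E - p_W)/dx
  pw <- pidx[cbind(fi, fj)]; pe <- pidx[cbind(fi + 1L, fj)]
  off_p <- nu + nv
  add(row, off_p + pe, -gi)
  add(row, off_p + pw, +gi)

  ## --- v momentum -----------------------------------------------------
  vf <- which(VF, arr.ind = TRUE)
  fi <- vf[, 1]; fj <- vf[, 2]
  row <- nu + vidx[VF]
  self <- rep(-4 * a - cdrag, nv)

  north_in <- fj + 1L <= ny - 1L
  n_idx <- ifelse(north_in, vidx[cbind(fi, pmin(fj + 1L, ny - 1L))], 0L)
  has_n <- north_in & n_idx > 0L
  add(row[has_n], nu + n_idx[has_n], a)
  # missing north face: wall (v_N = 0), nothing to add
  south_in <- fj - 1L >= 1L
  s_idx <- ifelse(south_in, vidx[cbind(fi, pmax(fj - 1L, 1L))], 0L)
  has_s <- south_in & s_idx > 0L
  add(row[has_s], nu + s_idx[has_s], a)

  east_in <- fi + 1L <= nx
  e_idx <- ifelse(east_in, vidx[cbind(pmin(fi + 1L, nx), fj)], 0L)
  has_e <- east_in & e_idx > 0L
  add(row[has_e], nu + e_idx[has_e], a)
  # right-edge v faces next to the outlet: zero-gradient ghost
  zg_e <- (!has_e) & (fi == nx)
  self[zg_e] <- self[zg_e] + a
  self[!has_e & !zg_e] <- self[!has_e & !zg_e] - a   # no-slip ghost
  west_in <- fi - 1L >= 1L
  w_idx <- ifelse(west_in, vidx[cbind(pmax(fi - 1L, 1L), fj)], 0L)
  has_w <- west_in & w_idx > 0L
  add(row[has_w], nu + w_idx[has_w], a)
  self[!has_w] <- self[!has_w] - a     # left edge (plug inflow, v = 0) or wall

  add(row, row, self)
  ps <- pidx[cbind(fi, fj)]; pn <- pidx[cbind(fi, fj + 1L)]
  add(row, off_p + pn, -gi)
  add(row, off_p + ps, +gi)

  ## --- continuity / outlet pressure ------------------------------------
  pc <- which(M & !outlet, arr.ind = TRUE)
  ci <- pc[, 1]; cj <- pc[, 2]
  row <- off_p + pidx[pc]
  # east u face
  ein <- ci <= nx - 1L
  eidx <- ifelse(ein, uidx[cbind(pmin(ci, nx - 1L), cj)], 0L)
  he <- ein & eidx > 0L
  add(row[he], eidx[he], gi)
  # west u face (inlet boundary contributes known flux)
  win <- ci - 1L >= 1L
  widx <- ifelse(win, uidx[cbind(pmax(ci - 1L, 1L), cj)], 0L)
  hw <- win & widx > 0L
  add(row[hw], widx[hw], -gi)
  at_inlet <- ci == 1L
  rhs[row[at_inlet]] <- rhs[row[at_inlet]] + gi * u_in
  # north v face
  nin <- cj <= ny - 1L
  nidx <- ifelse(nin, vidx[cbind(ci, pmin(cj, ny - 1L))], 0L)
  hn <- nin & nidx > 0L
  add(row[hn], nu + nidx[hn], gi)
  # south v face
  sin_ <- cj - 1L >= 1L
  sidx <- ifelse(sin_, vidx[cbind(ci, pmax(cj - 1L, 1L))], 0L)
  hs <- sin_ & sidx > 0L
  add(row[hs], nu + sidx[hs], -gi)

  po <- which(outlet, arr.ind = TRUE)
  row_o <- off_p + pidx[po]
  add(row_o, row_o, 1)

  A <- Matrix::sparseMatrix(
    i = unlist(ti[seq_len(nt)]), j = unlist(tj[seq_len(nt)]),
    x = unlist(tv[seq_len(nt)]), dims = rep(nu + nv + np, 2))
  sol <- as.numeric(Matrix::solve(A, rhs))

  ## --- unpack ----------------------------------------------------------
  # face arrays padded with boundary values for advection/flux use
  Uf <- matrix(0, nx + 1, ny)            # face i+1 lies at x = x0 + i*dx
  Uf[2:nx, ][UF] <- sol[seq_len(nu)]
  Uf[1, inlet_col] <- u_in
  Uf[nx + 1, M[nx, ]] <- Uf[nx, M[nx, ]]  # zero-gradient outflow
  Vf <- matrix(0, nx, ny + 1)
  Vf[, 2:ny][VF] <- sol[nu + seq_len(nv)]
  P <- matrix(NA_real_, nx, ny)
  P[M] <- sol[off_p + seq_len(np)]

  U <- (Uf[1:nx, ] + Uf[2:(nx + 1), ]) / 2; U[!M] <- NA_real_
  V <- (Vf[, 1:ny] + Vf[, 2:(ny + 1)]) / 2; V[!M] <- NA_real_

  divm <- (Uf[2:(nx + 1), ] - Uf[1:nx, ] + Vf[, 2:(ny + 1)] - Vf[, 1:ny]) / dx
  interior <- M & !outlet
  residual <- max(abs(divm[interior])) * dx / u_in
  if (!is.finite(residual) || residual > tol) {
    rlang::abort(sprintf("flow solve failed mass balance: residual %.3e > %.0e",
                         residual, tol), class = "traploop_solver_error")
  }
  flux_in <- sum(Uf[1, inlet_col]) * dx
  flux_out <- sum(Uf[nx + 1, M[nx, ]]) * dx

  structure(list(
    domain = domain, valve_on = valve_on, fluid = fluid,
    inlet_velocity = u_in, height = H, dx = dx,
    mask = M, u = U, v = V, p = P, u_faces = Uf, v_faces = Vf,
    residual = residual, flux_in_um2_s = flux_in, flux_out_um2_s = flux_out
  ), class = "flow_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

keep_inlet_component <- function(M, domain) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(M * 1)))
  keep <- unique(lab[1, ][M[1, ]])
  keep <- keep[keep > 0]
  M & matrix(lab %in% keep, nrow(M), ncol(M))
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d, dx = %g um, inlet %g um/s%s\n",
              x$domain$nx, x$domain$ny, x$dx, x$inlet_velocity,
              if (x$valve_on) ", valve ON" else ""))
  cat(sprintf("  mass-balance residual %.2e; inlet/outlet flux %.6g / %.6g um^2/s\n",
              x$residual, x$flux_in_um2_s, x$flux_out_um2_s))
  invisible(x)
}

#' Tidy a flow field into a long tibble
#'
#' @param x a `flow_field`.
#' @param ... unused.
#' @return Tibble with `x`, `y` (um), `u`, `v`, `speed` (um/s), `p` (Pa)
#'   for fluid cells.
#' @method tidy flow_field
#' @export
tidy.flow_field <- function(x, ...) {
  d <- x$domain
  keep <- as.vector(x$mask)
  tibble::tibble(
    x = rep(d$xc, times = d$ny)[keep],
    y = rep(d$yc, each = d$nx)[keep],
    u = as.vector(x$u)[keep],
    v = as.vector(x$v)[keep],
    p = as.vector(x$p)[keep]
  ) |> dplyr::mutate(speed = sqrt(.data$u^2 + .data$v^2))
}

#' Minimal straight-channel domain (validation geometry)
#'
#' A plain rectangular channel, inlet left and outlet right, used to
#' validate the field solver against the closed-form duct model.
#'
#' @param length,width channel plan dimensions (um).
#' @param height channel depth (um).
#' @param dx grid spacing (um).
#' @return A `raster_domain` without junction gates.
#' @export
straight_channel_domain <- function(length = 200, width = 25, height = 15,
                                    dx = 0.5) {
  nx <- round(length / dx); ny <- round(width / dx)
  mask <- matrix(TRUE, nx, ny)
  labels <- matrix(1L, nx, ny)
  labels[1, ] <- 2L; labels[nx, ] <- 3L
  structure(list(
    dx = dx, x0 = 0, y0 = -width / 2, nx = nx, ny = ny,
    xc = (seq_len(nx) - 0.5) * dx, yc = -width / 2 + (seq_len(ny) - 0.5) * dx,
    mask_fluid = mask, mask = mask, labels = labels, particle_radius = 0,
    gates = list(), layout = NULL, unit = NULL, height = height
  ), class = "raster_domain")
}

#' Integrate gate fluxes from a solved field
#'
#' Integrates the normal velocity across the Path-1 and bypass gate
#' sections at junction A, giving the field-based counterpart of the
#' resistance-network [flow_split()].
#'
#' @param field a solved [flow_field()].
#' @return One-row tibble: `Q1_m3_s`, `Q2_m3_s` (volumetric, using the
#'   channel depth), `ratio` = Q2/Q1, and `Q_in_m3_s`.
#' @export
flux_split_from_field <- function(field) {
  d <- field$domain
  if (is.null(d$gates$path1)) {
    rlang::abort("domain has no junction gates", class = "traploop_geometry_error")
  }
  dx <- field$dx; H <- field$height
  # Path-1 gate: vertical cut at x = gate x
  g1 <- d$gates$path1
  i_face <- round((g1$x - d$x0) / dx) + 1L       # column in the face array
  jsel <- which(d$yc > g1$y[1] & d$yc < g1$y[2])
  Q1 <- sum(field$u_faces[i_face, jsel]) * dx * H
  # bypass gate: horizontal cut at y = gate y
  g2 <- d$gates$bypass
  j_face <- round((g2$y - d$y0) / dx) + 1L
  isel <- which(d$xc > g2$x[1] & d$xc < g2$x[2])
  Q2 <- sum(field$v_faces[isel, j_face]) * dx * H
  um3 <- 1e-18                                    # um^3/s -> m^3/s
  tibble::tibble(Q1_m3_s = Q1 * um3, Q2_m3_s = Q2 * um3,
                 ratio = Q2 / Q1,
                 Q_in_m3_s = field$flux_in_um2_s * H * um3)
}

#' Peak velocity in the trapping gaps
#'
#' Maximum depth-averaged speed on the transverse mid-plane of each
#' trapping gap (regions ii and iv).  With the valve off this is the
#' fastest flow in the device; with the valve sealing the middle chamber it
#' collapses to a residual-eddy level far below the inlet velocity (no flow
#' through the gap).
#'
#' @param field a solved [flow_field()] on a trap-unit domain.
#' @return Peak mid-gap speed (um/s).
#' @export
gap_peak_velocity <- function(field) {
  d <- field$domain
  r <- d$unit$regions
  e <- cumsum(r$length); s <- c(0, e[-5])
  mids <- c((s[2] + e[2]) / 2, (s[4] + e[4]) / 2)
  sp <- sqrt(field$u^2 + field$v^2)
  out <- vapply(mids, function(xm) {
    i <- which.min(abs(d$xc - xm))
    col <- sp[i, d$labels[i, ] == 5L & field$mask[i, ]]
    if (!length(col)) 0 else max(col, na.rm = TRUE)
  }, 0)
  max(out)
}

# mean pressure over a label strip (validation helper)
strip_pressure <- function(field, label) {
  mean(field$p[field$domain$labels == label & field$mask], na.rm = TRUE)
}

# flux (um^2/s, per unit depth) across the vertical cut at grid x-index i
cut_flux <- function(field, i_face) {
  sum(field$u_faces[i_face, field$mask[pmin(i_face, field$domain$nx), ]]) * field$dx
}
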