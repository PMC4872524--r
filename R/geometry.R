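# Trap-unit geometry: presets, validation, rasterization.
# All lengths in micrometres (um) unless noted.

.design_table <- tibble::tribble(
  ~design, ~L11, ~L12, ~W12, ~W13, ~L13, ~W2, ~L2,
  1L,       10,    5,    5,   25,   50,  25, 805,
  2L,        6,    3,    3,   15,   48,  15, 761
)
.design_heights <- c(15, 25)

#' Channel segment (rectangular cross-section, optionally tapered in plan)
#'
#' A straight duct of uniform height whose plan-view width may vary linearly
#' from `width_start` to `width_end` along its length.  Equal widths give a
#' straight segment.
#'
#' @param width_start,width_end plan-view widths at the two ends (um).
#' @param length segment length (um).
#' @param height channel depth (um); uniform across a device.
#' @return A one-row tibble with columns `width_start`, `width_end`,
#'   `length`, `height`.
#' @export
channel_segment <- function(width_start, width_end = width_start, length, height) {
  vals <- c(width_start = width_start, width_end = width_end,
            length = length, height = height)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all channel_segment dimensions must be finite and > 0",
                 class = "traploop_invalid_argument")
  }
  tibble::tibble(width_start = width_start, width_end = width_end,
                 length = length, height = height)
}

new_trap_unit <- function(regions, bypass, height, design = NA_integer_,
                          valve_width = NULL) {
  stopifnot(nrow(regions) == 5, nrow(bypass) == 1)
  gap_w <- regions$width_end[1]
  entrance_w <- regions$width_start[1]
  if (!(regions$width_start[2] < regions$width_start[3] &&
        regions$width_start[4] < regions$width_start[3])) {
    rlang::abort("trapping-gap widths (regions ii/iv) must be below the chamber width (region iii)",
                 class = "traploop_invalid_argument")
  }
  x <- list(
    design = design,
    height = height,
    regions = regions,
    bypass = bypass,
    gap_width = regions$width_start[2],
    entrance_width = regions$width_start[3],
    path1_length = sum(regions$length),
    # valve-on seals the middle chamber completely (membrane fully deflected)
    valve_width = min(valve_width %||% regions$length[3], regions$length[3])
  )
  structure(x, class = "trap_unit")
}

#' Trap-unit geometry presets and custom construction
#'
#' `trap_unit()` returns one of the two catalogued trapping-unit designs
#' (design 1: 5 um trapping gap, 25 um main channel; design 2: 3 um gap,
#' 15 um main channel), at a channel height of 15 or 25 um.
#'
#' Path 1 (the straight trapping path) is modelled as five regions: a
#' funnel-shaped trap pocket tapering linearly from the main-channel width
#' down to the gap width (region i), a trapping gap (ii), the middle valve
#' chamber (iii), and the mirror-image gap (iv) and pocket (v).  Path 2 is
#' the bypass loop of width `W2` and centreline length `L2`.
#'
#' @param design catalogue id, 1 or 2.
#' @param height channel depth in um, 15 or 25.
#' @return An object of class `trap_unit`.
#' @examples
#' u <- trap_unit(1, 15)
#' u$bypass$length   # 805
#' @export
trap_unit <- function(design = 1, height = 15) {
  row <- .design_table[.design_table$design == design, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("unknown design id %s (catalogue has designs 1 and 2)",
                         format(design)), class = "traploop_invalid_argument")
  }
  if (!height %in% .design_heights) {
    rlang::abort(sprintf("height %s um is not catalogued (use 15 or 25)",
                         format(height)), class = "traploop_invalid_argument")
  }
  trap_unit_from_dims(L11 = row$L11, L12 = row$L12, W12 = row$W12,
                      W13 = row$W13, L13 = row$L13, W2 = row$W2, L2 = row$L2,
                      height = height, design = as.integer(design))
}

#' @rdname trap_unit
#' @param L11,L12,W12,W13,L13,W2,L2 channel dimensions in um following the
#'   usual naming: regions i/v have length `L11` and taper from `W13` to
#'   `W12`; regions ii/iv are gaps of width `W12` and length `L12`; region
#'   iii is the middle chamber (`W13` x `L13`); the bypass loop is `W2` wide
#'   with total centreline length `L2`.
#' @export
trap_unit_from_dims <- function(L11, L12, W12, W13, L13, W2, L2, height,
                                design = NA_integer_) {
  regions <- dplyr::bind_rows(
    channel_segment(W13, W12, L11, height),  # i: trap pocket (funnel)
    channel_segment(W12, W12, L12, height),  # ii: trapping gap
    channel_segment(W13, W13, L13, height),  # iii: middle chamber (valve)
    channel_segment(W12, W12, L12, height),  # iv: trapping gap
    channel_segment(W12, W13, L11, height)   # v: trap pocket (funnel)
  )
  regions <- dplyr::mutate(regions,
                           region = c("i", "ii", "iii", "iv", "v"),
                           .before = 1)
  bypass <- channel_segment(W2, W2, L2, height)
  if (L2 <= sum(regions$length) + W2) {
    rlang::abort("bypass length L2 must exceed the Path-1 length plus W2",
                 class = "traploop_invalid_argument")
  }
  new_trap_unit(regions, bypass, height, design = design)
}

#' @export
print.trap_unit <- function(x, ...) {
  cat(sprintf("<trap_unit> design %s, H = %g um\n",
              ifelse(is.na(x$design), "custom", x$design), x$height))
  cat(sprintf("  Path 1: %g um in 5 regions (gap %g um, chamber %g x %g um)\n",
              x$path1_length, x$gap_width, x$entrance_width, x$regions$length[3]))
  cat(sprintf("  Path 2: bypass loop %g um wide, %g um long\n",
              x$bypass$width_start, x$bypass$length))
  invisible(x)
}

# plan-view Path-1 half-width at along-path coordinate x in [0, L1]
path1_halfwidth <- function(unit, x) {
  r <- unit$regions
  ends <- cumsum(r$length)
  starts <- c(0, ends[-5])
  w <- numeric(length(x))
  idx <- findInterval(pmin(pmax(x, 0), sum(r$length)), c(starts, Inf),
                      rightmost.closed = TRUE)
  idx[idx > 5] <- 5
  for (k in seq_len(5)) {
    sel <- idx == k
    if (!any(sel)) next
    f <- (x[sel] - starts[k]) / r$length[k]
    w[sel] <- r$width_start[k] + f * (r$width_end[k] - r$width_start[k])
  }
  w / 2
}

# Plan-view layout parameters shared by rasterize() and the analytic area.
unit_layout <- function(unit, lead = 50) {
  L1 <- unit$path1_length
  W13 <- unit$entrance_width
  W2 <- unit$bypass$width_start
  L2 <- unit$bypass$length
  yc <- (L2 - (L1 + W2)) / 2          # bypass top-leg centreline height
  list(L1 = L1, W13 = W13, W2 = W2, L2 = L2, lead = lead, yc = yc,
       x_min = -(W2 + lead), x_max = L1 + W2 + lead,
       y_min = -W13 / 2, y_max = yc + W2 / 2,
       legA = c(-W2, 0), legB = c(L1, L1 + W2),
       valve_x = unit$regions$length[1] + unit$regions$length[2] +
         unit$regions$length[3] / 2 + c(-1, 1) * unit$valve_width / 2)
}

# analytic plan-view fluid area (um^2), for raster-convergence checks
unit_fluid_area <- function(unit, lead = 50) {
  g <- unit_layout(unit, lead)
  r <- unit$regions
  path1 <- sum((r$width_start + r$width_end) / 2 * r$length)
  mains <- 2 * (g$W2 + g$lead) * g$W13
  legs <- 2 * g$W2 * ((g$yc - g$W2 / 2) - g$W13 / 2)
  top <- (g$L1 + 2 * g$W2) * g$W2
  path1 + mains + legs + top
}

# analytic perimeter of the fluid polygon (approximate; for the convergence bound)
unit_fluid_perimeter <- function(unit, lead = 50) {
  g <- unit_layout(unit, lead)
  r <- unit$regions
  taper_side <- sqrt(r$length[1]^2 + ((r$width_start[1] - r$width_end[1]) / 2)^2)
  path1_sides <- 2 * (2 * taper_side + 2 * r$length[2] + r$length[3]) +
    2 * (r$width_start[3] - r$width_end[2])
  mains <- 2 * 2 * (g$W2 + g$lead) + 2 * g$W13
  loop_in <- 2 * (g$yc - g$W2 / 2 - g$W13 / 2) + g$L1
  loop_out <- 2 * (g$yc + g$W2 / 2 - g$W13 / 2) + g$L1 + 2 * g$W2
  path1_sides + mains + loop_in + loop_out
}

#' Rasterize a trap unit onto a regular grid
#'
#' Builds the plan-view fluid mask of one trapping unit (Path 1 plus bypass
#' loop between inlet and outlet leads) on a cell-centred square grid, with
#' region labels for the inlet, outlet, trapping gaps, trap pockets and the
#' valve chamber, and gate segments at the two junctions separating Path 1
#' from Path 2.
#'
#' The coordinate origin is junction A (entrance of Path 1), x runs along
#' Path 1 towards junction B, and the bypass loop lies in +y.
#'
#' @param unit a [trap_unit()].
#' @param dx grid spacing (um); must resolve the trapping gap with at least
#'   three cells.
#' @param particle_radius if > 0, the accessible mask (`$mask`) is the fluid
#'   mask eroded by this radius, modelling finite particle size; the
#'   uneroded fluid mask is kept in `$mask_fluid`.
#' @param lead length of the inlet/outlet leads beyond the bypass legs (um).
#' @return An object of class `raster_domain`: grid metadata, logical
#'   matrices `mask_fluid` (fluid) and `mask` (accessible to a particle
#'   centre), an integer `labels` matrix, and gate segment coordinates.
#' @export
rasterize <- function(unit, dx, particle_radius = 0, lead = 50) {
  stopifnot(inherits(unit, "trap_unit"), dx > 0, particle_radius >= 0)
  if (dx > unit$gap_width / 3) {
    rlang::abort(sprintf(
      "dx = %g um too coarse: the %g um trapping gap needs >= 3 cells (dx <= %g)",
      dx, unit$gap_width, unit$gap_width / 3), class = "traploop_resolution_error")
  }
  g <- unit_layout(unit, lead)
  nx <- round((g$x_max - g$x_min) / dx)
  ny <- round((g$y_max - g$y_min) / dx)
  xc <- g$x_min + (seq_len(nx) - 0.5) * dx
  yc <- g$y_min + (seq_len(ny) - 0.5) * dx
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  W13h <- g$W13 / 2
  in_main_left  <- X < 0 & abs(Y) < W13h
  in_main_right <- X > g$L1 & abs(Y) < W13h
  hw <- matrix(0, nx, ny)
  sel <- X >= 0 & X <= g$L1
  hw[sel] <- path1_halfwidth(unit, X[sel])
  in_path1 <- sel & abs(Y) < hw
  top_lo <- g$yc - g$W2 / 2
  top_hi <- g$yc + g$W2 / 2
  in_legA <- X > g$legA[1] & X < g$legA[2] & Y > W13h & Y < top_hi
  in_legB <- X > g$legB[1] & X < g$legB[2] & Y > W13h & Y < top_hi
  in_top  <- X > g$legA[1] & X < g$legB[2] & Y > top_lo & Y < top_hi
  mask <- in_main_left | in_main_right | in_path1 | in_legA | in_legB | in_top

  labels <- matrix(0L, nx, ny)
  labels[mask] <- 1L
  labels[mask & X == min(xc)] <- 2L                                   # inlet strip
  labels[mask & X == max(xc)] <- 3L                                   # outlet strip
  labels[in_path1 & X > g$valve_x[1] & X < g$valve_x[2]] <- 4L        # valve chamber
  r <- unit$regions
  e <- cumsum(r$length); s <- c(0, e[-5])
  gapsel <- in_path1 & ((X > s[2] & X < e[2]) | (X > s[4] & X < e[4]))
  labels[gapsel] <- 5L                                                # trapping gaps
  pock <- in_path1 & ((X > s[1] & X < e[1]) | (X > s[5] & X < e[5]))
  labels[pock] <- 6L                                                  # trap pockets

  acc <- mask
  if (particle_radius > 0) acc <- erode_mask(mask, dx, particle_radius)

  structure(list(
    dx = dx, x0 = g$x_min, y0 = g$y_min, nx = nx, ny = ny,
    xc = xc, yc = yc,
    mask_fluid = mask, mask = acc, labels = labels,
    particle_radius = particle_radius,
    gates = list(
      path1  = list(x = 0, y = c(-W13h, W13h)),
      # transmission plane inside the first trapping gap: crossing it (or
      # wedging in the pocket upstream of it) is the operational "into the
      # trap" fate, robust against trajectories that merely graze the
      # Path-1 mouth at the junction
      gap    = list(x = s[2] + r$length[2] / 2, y = c(-W13h, W13h)),
      bypass = list(y = W13h, x = g$legA),
      path1_exit  = list(x = g$L1, y = c(-W13h, W13h)),
      bypass_exit = list(y = W13h, x = g$legB)
    ),
    layout = g, unit = unit
  ), class = "raster_domain")
}

#' @export
print.raster_domain <- function(x, ...) {
  cat(sprintf("<raster_domain> %d x %d cells, dx = %g um, %d fluid cells\n",
              x$nx, x$ny, x$dx, sum(x$mask_fluid)))
  if (x$particle_radius > 0)
    cat(sprintf("  accessible mask eroded by %g um (%d cells)\n",
                x$particle_radius, sum(x$mask)))
  invisible(x)
}

# Distance (um) from each cell centre to the nearest wall.  Open
# inlet/outlet ends (left/right domain edges) are extended with their own
# fluid pattern so they do not act as walls; the top/bottom domain edges
# are walls.
mask_wall_distance <- function(mask, dx, pad = 4L) {
  k <- max(4L, pad)
  nx <- nrow(mask); ny <- ncol(mask)
  padded <- matrix(FALSE, nx + 2L * k, ny + 2L * k)
  jj <- k + seq_len(ny)
  padded[k + seq_len(nx), jj] <- mask
  padded[seq_len(k), jj] <- matrix(mask[1L, ], k, ny, byrow = TRUE)
  padded[nx + k + seq_len(k), jj] <- matrix(mask[nx, ], k, ny, byrow = TRUE)
  d <- EBImage::distmap(EBImage::Image(padded * 1), metric = "euclidean")
  EBImage::imageData(d)[k + seq_len(nx), jj] * dx
}

# Erode a fluid mask by a physical radius: keep cells whose centre is at
# least `radius` from the nearest wall (finite-size exclusion).
erode_mask <- function(mask, dx, radius) {
  dist_um <- mask_wall_distance(mask, dx, pad = ceiling(radius / dx) + 1L)
  mask & (dist_um > radius)
}

# Number of independent inlet->outlet flow paths, from the topology of the
# fluid mask: paths = (number of enclosed holes) + 1.
count_flow_paths <- function(domain, valve_on = FALSE) {
  m <- solve_mask(domain, valve_on)
  bg <- !m
  padded <- matrix(TRUE, nrow(bg) + 2L, ncol(bg) + 2L)
  padded[1L + seq_len(nrow(bg)), 1L + seq_len(ncol(bg))] <- bg
  lab <- EBImage::bwlabel(EBImage::Image(padded * 1))
  n_bg <- max(EBImage::imageData(lab))
  as.integer(n_bg - 1L + 1L)  # holes + 1
}

# fluid mask actually open to flow under a valve state
solve_mask <- function(domain, valve_on = FALSE) {
  m <- domain$mask_fluid
  if (valve_on) m[domain$labels == 4L] <- FALSE
  m
}

#' Tidy a raster domain into a long tibble of cells
#'
#' @param x a `raster_domain`.
#' @param ... unused.
#' @return A tibble with one row per grid cell: `x`, `y` (um), `fluid`,
#'   `accessible`, `label`.
#' @method tidy raster_domain
#' @export
tidy.raster_domain <- function(x, ...) {
  lab_names <- c("wall", "fluid", "inlet", "outlet", "valve", "gap", "pocket")
  xs <- rep(x$xc, times = x$ny)
  ys <- rep(x$yc, each = x$nx)
  fl <- as.vector(x$mask_fluid)
  acc <- as.vector(x$mask)
  lab <- lab_names[as.vector(x$labels) + 1L]
  lab[!fl] <- "wall"
  tibble::tibble(x = xs, y = ys, fluid = fl, accessible = acc, label = lab)
}

#' Read / write trap-unit geometry as key = value text
#'
#' The structured-text format stores the named channel dimensions in um,
#' one `key = value` pair per line (`design`, `height`, `L11`, `L12`,
#' `W12`, `W13`, `L13`, `W2`, `L2`).
#'
#' @param unit a [trap_unit()].
#' @param path file path.
#' @return `read_trap_config()` returns a `trap_unit`;
#'   `write_trap_config()` returns `path` invisibly.
#' @export
write_trap_config <- function(unit, path) {
  r <- unit$regions
  vals <- c(design = unit$design, height = unit$height,
            L11 = r$length[1], L12 = r$length[2], W12 = r$width_start[2],
            W13 = r$width_start[3], L13 = r$length[3],
            W2 = unit$bypass$width_start, L2 = unit$bypass$length)
  writeLines(sprintf("%s = %s", names(vals), vapply(vals, format, "")), path)
  invisible(path)
}

#' @rdname write_trap_config
#' @export
read_trap_config <- function(path) {
  ln <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(ln, "\\s*=\\s*")
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          trimws(vapply(kv, `[`, "", 1L)))
  need <- c("height", "L11", "L12", "W12", "W13", "L13", "W2", "L2")
  if (!all(need %in% names(vals))) {
    rlang::abort(paste("geometry config is missing keys:",
                       paste(setdiff(need, names(vals)), collapse = ", ")),
                 class = "traploop_invalid_argument")
  }
  v <- function(k) unname(vals[[k]])
  trap_unit_from_dims(v("L11"), v("L12"), v("W12"), v("W13"),
                      v("L13"), v("W2"), v("L2"), v("height"),
                      design = if ("design" %in% names(vals))
                        as.integer(v("design")) else NA_integer_)
}

#' Export a rasterized domain as a portable greymap (PGM) plus JSON sidecar
#'
#' Writes a plain-text (P2) PGM image of the region labels and a JSON
#' sidecar (same path with `.json` appended) holding the grid spacing,
#' origin, gate coordinates and the label -> grey-level legend.
#'
#' @param domain a `raster_domain`.
#' @param path output PGM path.
#' @return `path`, invisibly.
#' @export
write_raster_pgm <- function(domain, path) {
  shades <- c(wall = 0L, fluid = 255L, inlet = 230L, outlet = 210L,
              valve = 120L, gap = 160L, pocket = 190L)
  grey <- unname(shades)[as.vector(domain$labels) + 1L]
  grey[!as.vector(domain$mask_fluid)] <- 0L
  img <- matrix(grey, domain$nx, domain$ny)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", domain$nx, domain$ny), "255"), con)
  # raster rows top-to-bottom = decreasing y
  for (j in rev(seq_len(domain$ny))) {
    writeLines(paste(img[, j], collapse = " "), con)
  }
  jsonlite::write_json(
    list(dx = domain$dx, origin = c(domain$x0, domain$y0),
         nx = domain$nx, ny = domain$ny,
         particle_radius = domain$particle_radius,
         gates = domain$gates, legend = as.list(shades)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
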