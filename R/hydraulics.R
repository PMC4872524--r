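# Resistance-network design model for rectangular microchannels.
#
# Laminar fully developed duct flow: dp = fRe * L * ubar * eta / (2 * Dh^2),
# with fRe the Shah-London geometry constant for rectangular sections.
# SI internally; interfaces take um and ul/h.

UM <- 1e-6            # um -> m
ULH <- 1e-9 / 3600    # ul/h -> m^3/s

#' Fluid properties
#'
#' @param viscosity dynamic viscosity (Pa s).
#' @param density density (kg m^-3).
#' @return A list of class `fluid_spec`.
#' @export
fluid_spec <- function(viscosity = 1.0e-3, density = 1.0e3) {
  stopifnot(viscosity > 0, density > 0)
  structure(list(viscosity = viscosity, density = density), class = "fluid_spec")
}

#' @rdname fluid_spec
#' @export
fluid_water <- function() fluid_spec(1.0e-3, 1.0e3)

#' Inlet flow conditions
#'
#' Exactly one of mean velocity or volumetric rate is given; the other is
#' derived from the inlet cross-section via Q = ubar * A.
#'
#' @param velocity_um_s mean inlet velocity (um/s).
#' @param rate_ul_h volumetric flow rate (ul/h).
#' @return A list of class `flow_conditions`.
#' @export
flow_conditions <- function(velocity_um_s = NULL, rate_ul_h = NULL) {
  if (is.null(velocity_um_s) == is.null(rate_ul_h)) {
    rlang::abort("give exactly one of velocity_um_s or rate_ul_h",
                 class = "traploop_invalid_argument")
  }
  if (!is.null(velocity_um_s)) {
    stopifnot(velocity_um_s > 0)
    structure(list(type = "velocity", value = velocity_um_s * UM),
              class = "flow_conditions")
  } else {
    stopifnot(rate_ul_h > 0)
    structure(list(type = "rate", value = rate_ul_h * ULH),
              class = "flow_conditions")
  }
}

inlet_rate_m3s <- function(flow, area_m2) {
  if (flow$type == "rate") flow$value else flow$value * area_m2
}

#' Hydraulic diameter of a rectangular section
#'
#' Dh = 4A/P for a W x H rectangle: 2WH/(W+H).
#'
#' @param width,height section sides (um).
#' @return Hydraulic diameter in um.
#' @examples
#' hydraulic_diameter(15, 15)  # 15: square duct
#' hydraulic_diameter(25, 15)  # 18.75
#' @export
hydraulic_diameter <- function(width, height) {
  stopifnot(all(width > 0), all(height > 0))
  2 * width * height / (width + height)
}

#' Shah-London fRe constant for a rectangular duct
#'
#' Product of Darcy friction factor and Reynolds number for fully developed
#' laminar flow in a rectangular duct of aspect ratio `aspect` =
#' min(W,H)/max(W,H), from the standard fifth-order polynomial fit:
#' 96 (1 - 1.3553 a + 1.9467 a^2 - 1.7012 a^3 + 0.9564 a^4 - 0.2537 a^5).
#' Ranges from 96 (parallel plates, a -> 0) to ~56.91 (square, a = 1).
#'
#' @param aspect aspect ratio in (0, 1].
#' @return Dimensionless fRe.
#' @export
f_re <- function(aspect) {
  if (any(aspect <= 0 | aspect > 1)) {
    rlang::abort("aspect ratio must lie in (0, 1]",
                 class = "traploop_invalid_argument")
  }
  96 * (1 - 1.3553 * aspect + 1.9467 * aspect^2 - 1.7012 * aspect^3 +
          0.9564 * aspect^4 - 0.2537 * aspect^5)
}

#' Channel Reynolds number
#'
#' Re = rho * ubar * Dh / eta.
#'
#' @param fluid a [fluid_spec()].
#' @param velocity_um_s mean velocity (um/s).
#' @param dh_um hydraulic diameter (um).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, velocity_um_s, dh_um) {
  stopifnot(velocity_um_s >= 0, dh_um > 0)
  fluid$density * (velocity_um_s * UM) * (dh_um * UM) / fluid$viscosity
}

# local per-length resistance density (Pa s / m^3 per m) of a W x H section
resistance_density <- function(width_um, height_um, viscosity) {
  W <- width_um * UM; H <- height_um * UM
  A <- W * H
  Dh <- 2 * W * H / (W + H)
  a <- pmin(W, H) / pmax(W, H)
  f_re(a) * viscosity / (2 * Dh^2 * A)
}

#' Per-segment hydraulic quantities and resistance
#'
#' For a straight segment, R = fRe * L * eta / (2 Dh^2 A) (so that
#' dp = R Q reproduces dp = fRe L ubar eta / (2 Dh^2)).  For a linearly
#' tapered segment the resistance is the integral of the local straight-duct
#' resistance density along the length (Simpson quadrature, 64 intervals).
#'
#' @param segment a [channel_segment()] (one-row tibble).
#' @param fluid a [fluid_spec()].
#' @return A one-row tibble: `A_m2`, `P_m`, `Dh_um`, `aspect`, `fRe`,
#'   `R_Pa_s_m3` (geometric quantities evaluated at the segment mean width).
#' @export
segment_hydraulics <- function(segment, fluid = fluid_water()) {
  w0 <- segment$width_start; w1 <- segment$width_end
  H <- segment$height; L <- segment$length
  wbar <- (w0 + w1) / 2
  A <- (wbar * UM) * (H * UM)
  P <- 2 * (wbar + H) * UM
  Dh <- hydraulic_diameter(wbar, H)
  aspect <- min(wbar, H) / max(wbar, H)
  if (w0 == w1) {
    R <- resistance_density(w0, H, fluid$viscosity) * (L * UM)
  } else {
    n <- 64L
    s <- seq(0, 1, length.out = n + 1L)
    w <- w0 + s * (w1 - w0)
    dens <- resistance_density(w, H, fluid$viscosity)
    wts <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
    R <- sum(wts * dens) * (L * UM) / (3 * n)
  }
  tibble::tibble(A_m2 = A, P_m = P, Dh_um = Dh, aspect = aspect,
                 fRe = f_re(aspect), R_Pa_s_m3 = R)
}

# total Path-1 and Path-2 resistances of a unit (Pa s / m^3)
unit_resistances <- function(unit, fluid = fluid_water(),
                             lump_pocket_gap = FALSE) {
  regs <- unit$regions
  if (lump_pocket_gap) {
    # treat (i + ii) and (iv + v) as single gap-width segments of the
    # combined length: sensitivity option for the pocket model
    regs <- dplyr::bind_rows(
      channel_segment(regs$width_start[2], regs$width_start[2],
                      regs$length[1] + regs$length[2], unit$height) |>
        dplyr::mutate(region = "i+ii", .before = 1),
      regs[3, ],
      channel_segment(regs$width_start[4], regs$width_start[4],
                      regs$length[4] + regs$length[5], unit$height) |>
        dplyr::mutate(region = "iv+v", .before = 1)
    )
  }
  per_region <- dplyr::bind_cols(
    regs[, "region"],
    tibble::tibble(W_um = (regs$width_start + regs$width_end) / 2,
                   L_um = regs$length),
    purrr::list_rbind(purrr::map(seq_len(nrow(regs)),
                                 ~segment_hydraulics(regs[.x, ], fluid)))
  )
  R1 <- sum(per_region$R_Pa_s_m3)
  R2 <- segment_hydraulics(unit$bypass, fluid)$R_Pa_s_m3
  list(per_region = per_region, R1 = R1, R2 = R2)
}

#' Flow split between the trapping path and the bypass loop
#'
#' Solves the two-resistor parallel network between junctions A and B:
#' dp1 = dp2, Q1/Q2 = R2/R1, Q1 + Q2 = Q.  An occupied trap or an activated
#' valve blocks Path 1 entirely (Q1 = 0).
#'
#' @param unit a [trap_unit()].
#' @param fluid a [fluid_spec()].
#' @param flow a [flow_conditions()]; the inlet cross-section is the main
#'   channel (`W13` x `H`).
#' @param valve_on,trap_occupied logical; either blocks Path 1.
#' @param lump_pocket_gap treat pocket+gap as one lumped gap segment
#'   (sensitivity option).
#' @return An object of class `flow_split`; see [tidy.flow_split()] and
#'   [glance.flow_split()].
#' @examples
#' fs <- flow_split(trap_unit(1, 15))
#' glance(fs)$ratio   # Q2/Q1 < 1
#' @export
flow_split <- function(unit, fluid = fluid_water(),
                       flow = flow_conditions(velocity_um_s = 100),
                       valve_on = FALSE, trap_occupied = FALSE,
                       lump_pocket_gap = FALSE) {
  res <- unit_resistances(unit, fluid, lump_pocket_gap)
  A_in <- (unit$entrance_width * UM) * (unit$height * UM)
  Q <- inlet_rate_m3s(flow, A_in)
  blocked <- isTRUE(valve_on) || isTRUE(trap_occupied)
  if (blocked) {
    Q1 <- 0; Q2 <- Q
  } else {
    Q1 <- Q * res$R2 / (res$R1 + res$R2)
    Q2 <- Q - Q1
  }
  dp1 <- Q1 * res$R1
  per_region <- dplyr::mutate(res$per_region, dp_Pa = Q1 * .data$R_Pa_s_m3)
  structure(list(
    Q_m3_s = Q, Q1 = Q1, Q2 = Q2,
    ratio = if (blocked) Inf else Q2 / Q1,
    dp1_Pa = dp1, dp2_Pa = Q2 * res$R2,
    R1 = res$R1, R2 = res$R2,
    per_region = per_region,
    valve_on = valve_on, trap_occupied = trap_occupied,
    unit = unit, fluid = fluid
  ), class = "flow_split")
}

#' @export
print.flow_split <- function(x, ...) {
  cat(sprintf("<flow_split> Q = %.3g ul/h; Q1 = %.3g, Q2 = %.3g ul/h (Q2/Q1 = %.3g)\n",
              x$Q_m3_s / ULH, x$Q1 / ULH, x$Q2 / ULH, x$ratio))
  if (x$valve_on) cat("  valve on: Path 1 blocked\n")
  if (x$trap_occupied) cat("  trap occupied: Path 1 blocked\n")
  invisible(x)
}

#' @param x a `flow_split`.
#' @param ... unused.
#' @describeIn flow_split `tidy()` returns the per-region table (region, W,
#'   L, Dh, fRe, R, dp).
#' @method tidy flow_split
#' @export
tidy.flow_split <- function(x, ...) {
  dplyr::relocate(x$per_region, "region")
}

#' @describeIn flow_split `glance()` returns a one-row summary: flows,
#'   resistances, the Q2/Q1 ratio and the criterion verdict.
#' @method glance flow_split
#' @export
glance.flow_split <- function(x, ...) {
  tibble::tibble(
    Q_ul_h = x$Q_m3_s / ULH, Q1_ul_h = x$Q1 / ULH, Q2_ul_h = x$Q2 / ULH,
    ratio = x$ratio, dp1_Pa = x$dp1_Pa,
    R1_Pa_s_m3 = x$R1, R2_Pa_s_m3 = x$R2,
    criterion_pass = is.finite(x$ratio) && x$ratio < 1
  )
}

#' Check the Q2/Q1 < 1 trapping design criterion
#'
#' A unit traps efficiently only if, with the valve off and the trap empty,
#' the bypass carries less flow than the trapping path (Q2/Q1 < 1).
#'
#' @inheritParams flow_split
#' @return A list of class `criterion_report` with the ratio, the verdict
#'   and the per-region pressure-drop table.
#' @export
criterion_check <- function(unit, fluid = fluid_water(),
                            flow = flow_conditions(velocity_um_s = 100)) {
  fs <- flow_split(unit, fluid, flow, valve_on = FALSE, trap_occupied = FALSE)
  structure(list(ratio = fs$ratio, pass = fs$ratio < 1,
                 per_region = tidy(fs), split = fs),
            class = "criterion_report")
}

#' @export
print.criterion_report <- function(x, ...) {
  cat(sprintf("Q2/Q1 = %.4f -> criterion %s\n", x$ratio,
              ifelse(x$pass, "PASS (bypass slower than trapping path)",
                     "FAIL (bypass would outrun the trapping path)")))
  print(x$per_region)
  invisible(x)
}

#' @method tidy criterion_report
#' @export
tidy.criterion_report <- function(x, ...) x$per_region

#' @method glance criterion_report
#' @export
glance.criterion_report <- function(x, ...) {
  tibble::tibble(ratio = x$ratio, pass = x$pass)
}
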