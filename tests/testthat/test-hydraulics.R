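test_that("hydraulic diameter matches hand-evaluated cases and limits", {
  expect_equal(hydraulic_diameter(15, 15), 15)            # square duct
  expect_equal(hydraulic_diameter(25, 15), 4 * 375 / 80)  # 18.75
  # parallel-plate limit: Dh -> 2H as W -> Inf
  expect_equal(hydraulic_diameter(1e9, 15), 30, tolerance = 1e-6)
})

test_that("Shah-London fRe spans the rectangular-duct range", {
  expect_equal(f_re(1e-9), 96, tolerance = 1e-6)
  # polynomial at alpha = 1, evaluated independently
  a <- 1
  expect_equal(f_re(1),
               96 * (1 - 1.3553 * a + 1.9467 * a^2 - 1.7012 * a^3 +
                       0.9564 * a^4 - 0.2537 * a^5))
  expect_equal(f_re(1), 56.91, tolerance = 1e-3)
  # tabulated rectangular-duct value near alpha = 0.6
  expect_equal(f_re(0.6), 59.9, tolerance = 1e-2)
  expect_error(f_re(0), class = "traploop_invalid_argument")
  expect_error(f_re(1.2), class = "traploop_invalid_argument")
  # monotone decreasing over (0, 1]
  a <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(f_re(a)) < 0))
})

test_that("Reynolds number confirms creeping flow and scales linearly", {
  w <- fluid_water()
  re <- reynolds_number(w, 100, 18.75)
  expect_equal(re, 1e3 * 100e-6 * 18.75e-6 / 1e-3)   # ~1.9e-3
  expect_lt(re, 0.01)
  expect_equal(reynolds_number(w, 0, 18.75), 0)
  expect_equal(reynolds_number(w, 200, 18.75), 2 * re)
})

test_that("segment resistance matches the printed pressure-drop formula", {
  # independent evaluation of R = fRe L eta / (2 Dh^2 A) for the design-1
  # gap and bypass segments
  eta <- 1e-3
  gap <- segment_hydraulics(channel_segment(5, 5, 5, 15))
  Dh <- 2 * 5e-6 * 15e-6 / (20e-6)
  fre <- 96 * (1 - 1.3553 / 3 + 1.9467 / 9 - 1.7012 / 27 + 0.9564 / 81 -
                 0.2537 / 243)
  R_gap <- fre * 5e-6 * eta / (2 * Dh^2 * 75e-12)
  expect_equal(gap$R_Pa_s_m3, R_gap, tolerance = 1e-12)
  byp <- segment_hydraulics(channel_segment(25, 25, 805, 15))
  expect_true(byp$R_Pa_s_m3 > 0 && gap$R_Pa_s_m3 > 0)
  # Path-1 total (2 tapers + 2 gaps + chamber) stays below the bypass:
  # the ordering that gives Q2/Q1 < 1
  u <- trap_unit(1, 15)
  res <- traploop:::unit_resistances(u)
  expect_lt(res$R1, res$R2)
})

test_that("series additivity and taper behaviour", {
  s <- channel_segment(10, 10, 20, 15)
  one <- segment_hydraulics(s)$R_Pa_s_m3
  expect_equal(segment_hydraulics(channel_segment(10, 10, 40, 15))$R_Pa_s_m3,
               2 * one, tolerance = 1e-12)
  # degenerate taper equals the straight closed form
  tap0 <- segment_hydraulics(channel_segment(10, 10 + 1e-12, 20, 15))$R_Pa_s_m3
  expect_equal(tap0, one, tolerance = 1e-10)
  # tapered resistance lies between the straight end-width resistances
  tap <- segment_hydraulics(channel_segment(25, 5, 10, 15))$R_Pa_s_m3
  lo <- segment_hydraulics(channel_segment(25, 25, 10, 15))$R_Pa_s_m3
  hi <- segment_hydraulics(channel_segment(5, 5, 10, 15))$R_Pa_s_m3
  expect_gt(tap, lo)
  expect_lt(tap, hi)
  # independent slice-sum oracle for the taper quadrature
  n <- 400
  xs <- (seq_len(n) - 0.5) / n
  ws <- 25 + xs * (5 - 25)
  slices <- sum(vapply(ws, function(w)
    segment_hydraulics(channel_segment(w, w, 10 / n, 15))$R_Pa_s_m3, 0))
  expect_equal(tap, slices, tolerance = 1e-4)
})

test_that("flow split solves the parallel network and conserves flow", {
  u <- trap_unit(1, 15)
  fs <- flow_split(u)
  expect_equal(fs$Q1 + fs$Q2, fs$Q_m3_s, tolerance = 1e-12)
  expect_equal(fs$ratio, fs$R1 / fs$R2, tolerance = 1e-12)
  # parallel paths share the pressure drop
  expect_equal(fs$dp1_Pa, fs$dp2_Pa, tolerance = 1e-12)
  # per-region drops sum to the Path-1 drop
  expect_equal(sum(fs$per_region$dp_Pa), fs$dp1_Pa, tolerance = 1e-12)
  # valve or occupancy block Path 1 completely
  for (blocked in list(flow_split(u, valve_on = TRUE),
                       flow_split(u, trap_occupied = TRUE))) {
    expect_equal(blocked$Q1, 0)
    expect_equal(blocked$Q2, blocked$Q_m3_s)
  }
})

test_that("pressure drop scales linearly with viscosity and velocity", {
  u <- trap_unit(1, 15)
  base <- flow_split(u, fluid_spec(1e-3, 1e3), flow_conditions(100))
  eta2 <- flow_split(u, fluid_spec(2e-3, 1e3), flow_conditions(100))
  vel2 <- flow_split(u, fluid_spec(1e-3, 1e3), flow_conditions(200))
  expect_equal(eta2$dp1_Pa, 2 * base$dp1_Pa, tolerance = 1e-12)
  expect_equal(vel2$dp1_Pa, 2 * base$dp1_Pa, tolerance = 1e-12)
  # the split itself is invariant
  expect_equal(eta2$ratio, base$ratio, tolerance = 1e-12)
})

test_that("design criterion: monotone response to bypass length and gap width", {
  u <- trap_unit(1, 15)
  base <- criterion_check(u)$ratio
  # longer bypass loop lowers Q2/Q1
  longer <- trap_unit_from_dims(10, 5, 5, 25, 50, 25, 1200, 15)
  expect_lt(criterion_check(longer)$ratio, base)
  # narrower trapping gap chokes Path 1, raising Q2/Q1
  narrower <- trap_unit_from_dims(10, 5, 3, 25, 50, 25, 805, 15)
  expect_gt(criterion_check(narrower)$ratio, base)
})

test_that("both catalogued designs satisfy the trapping criterion at H = 15", {
  c1 <- criterion_check(trap_unit(1, 15))
  c2 <- criterion_check(trap_unit(2, 15))
  expect_true(c1$pass)
  expect_true(c2$pass)
  expect_lt(c1$ratio, 1)
  expect_lt(c2$ratio, 1)
})

test_that("identical parallel paths split the flow evenly", {
  u <- balanced_unit()
  fs <- flow_split(u)
  expect_equal(fs$Q1, fs$Q2, tolerance = 0.02)
  expect_equal(fs$ratio, 1, tolerance = 0.02)
  expect_false(criterion_check(u)$pass)   # borderline ratio ~ 1 fails
})

test_that("flow conditions accept either velocity or rate, not both", {
  expect_error(flow_conditions(), class = "traploop_invalid_argument")
  expect_error(flow_conditions(100, 20), class = "traploop_invalid_argument")
  u <- trap_unit(1, 15)
  # 20 ul/h through the 25 x 15 um inlet equals ~14.8 mm/s mean velocity
  q <- 20 * 1e-9 / 3600
  v_um_s <- q / (25e-6 * 15e-6) * 1e6
  a <- flow_split(u, flow = flow_conditions(rate_ul_h = 20))
  b <- flow_split(u, flow = flow_conditions(velocity_um_s = v_um_s))
  expect_equal(a$Q_m3_s, b$Q_m3_s, tolerance = 1e-10)
})

test_that("tidy and glance expose the per-region table and verdict", {
  cc <- criterion_check(trap_unit(1, 15))
  td <- tidy(cc)
  expect_equal(td$region, c("i", "ii", "iii", "iv", "v"))
  expect_true(all(c("W_um", "L_um", "Dh_um", "fRe", "R_Pa_s_m3", "dp_Pa") %in%
                    names(td)))
  gl <- glance(cc)
  expect_true(gl$pass)
  # lumped pocket+gap sensitivity option: treating the whole pocket at gap
  # width is strictly more resistive on Path 1, raising Q2/Q1
  fs <- flow_split(trap_unit(1, 15), lump_pocket_gap = TRUE)
  expect_equal(nrow(tidy(fs)), 3)
  expect_gt(glance(fs)$ratio, glance(cc$split)$ratio)
})
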