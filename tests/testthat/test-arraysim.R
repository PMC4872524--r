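test_that("routing follows occupancy, valve state and the flow split", {
  st <- trap_array(3, trap_unit(1, 15))
  # criterion-passing design: empty unit deterministically traps
  expect_gt(st$p_trap, 0.5)
  expect_equal(route_particle(st, 1), "trap")
  st$units$occupied[1] <- 7L
  expect_equal(route_particle(st, 1), "bypass")
  st$units$valve_on[2] <- TRUE
  expect_equal(route_particle(st, 2), "bypass")
})

test_that("sequential filling occupies traps in upstream-to-downstream order", {
  st <- fill_simulation(trap_array(10, trap_unit(1, 15)), 10)
  expect_equal(st$units$occupied, 1:10)
  expect_equal(glance(st)$single_occupancy_fraction, 1)
  # particle conservation: trapped + exited = injected
  trapped <- sum(st$log$event == "trap")
  exited <- sum(st$log$event == "exit")
  expect_equal(trapped + exited, 10)
})

test_that("no particle is trapped when every valve is activated", {
  st <- trap_array(10, trap_unit(1, 15))
  st$units$valve_on <- rep(TRUE, 10)
  st <- fill_simulation(st, 10)
  expect_true(all(is.na(st$units$occupied)))
  expect_equal(sum(st$log$event == "exit"), 10)
})

test_that("stochastic routing matches the binomial flow-split probability", {
  n <- 1e4
  st <- trap_array(1, p_trap = 0.62)
  trapped <- 0L
  set.seed(99)
  for (k in seq_len(n)) {
    d <- route_particle(st, 1, mode = "stochastic")
    trapped <- trapped + (d == "trap")
  }
  se <- sqrt(0.62 * 0.38 / n)
  expect_lt(abs(trapped / n - 0.62), 4 * se)
})

test_that("release ejects, re-traps downstream, and guards prevent re-trapping", {
  # release unit 3 of 5 with 4,5 occupied: particle exits, {1,2,4,5} remain
  st <- fill_simulation(trap_array(5, trap_unit(1, 15)), 5)
  st <- release(st, release_schedule(3))
  expect_equal(which(!is.na(st$units$occupied)), c(1, 2, 4, 5))
  # release an upstream unit with an empty valve-off trap downstream:
  # the particle is re-trapped there
  st2 <- fill_simulation(trap_array(5, trap_unit(1, 15)), 4)  # unit 5 empty
  st2 <- release(st2, release_schedule(2), guard_downstream = FALSE)
  expect_equal(st2$units$occupied[5], 2L)   # particle 2 re-trapped at unit 5
  expect_true(is.na(st2$units$occupied[2]))
  # with the downstream guard the released particle always exits
  st3 <- fill_simulation(trap_array(5, trap_unit(1, 15)), 4)
  st3 <- release(st3, release_schedule(2), guard_downstream = TRUE)
  expect_true(is.na(st3$units$occupied[5]))
  expect_equal(sum(st3$log$event == "release"), 1)
  # the guard is transient: valves reopen afterwards
  expect_false(any(st3$units$valve_on))
  # releasing an empty unit warns and changes nothing
  expect_warning(release(st3, release_schedule(2)), "empty")
})

test_that("release order does not matter (exhaustive over all 120 orders)", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  all_orders <- perms(1:5)
  expect_length(all_orders, 120)
  final <- lapply(all_orders, function(ord) {
    st <- fill_simulation(trap_array(5, trap_unit(1, 15)), 5)
    st <- release(st, release_schedule(ord), guard_downstream = TRUE)
    st$units$occupied
  })
  expect_true(all(vapply(final, identical, TRUE, final[[1]])))
  expect_true(all(is.na(final[[1]])))
  # partial schedules too: releasing {1, 3, 5} in any order leaves {2, 4}
  sub_orders <- perms(c(1L, 3L, 5L))
  final_sub <- lapply(sub_orders, function(ord) {
    st <- fill_simulation(trap_array(5, trap_unit(1, 15)), 5)
    st <- release(st, release_schedule(ord), guard_downstream = TRUE)
    st$units$occupied
  })
  expect_true(all(vapply(final_sub, identical, TRUE, final_sub[[1]])))
  expect_equal(which(!is.na(final_sub[[1]])), c(2, 4))
})

test_that("the event log replays to the same final state", {
  st <- fill_simulation(trap_array(6, trap_unit(1, 15)), 4)
  st <- release(st, release_schedule(c(2, 4)), guard_downstream = TRUE)
  re <- replay_log(st)
  expect_equal(re$units$occupied, st$units$occupied)
  # log is append-only and time-ordered
  expect_true(all(diff(st$log$time) >= 0))
})

test_that("occupancy classifier reproduces the empirical size cases", {
  # 10 um particle, 3 um gap, 15 um wide, 25 um tall: vertical stacking
  expect_equal(classify_fit(10, 3, 15, 25)$label, "multiple_vertical")
  # 8 um particle in the snug 3 um-gap, 15 um device: single occupancy
  expect_equal(classify_fit(8, 3, 15, 15)$label, "single")
  # particle smaller than the gap flows straight through
  expect_equal(classify_fit(2, 3, 15, 15)$label, "passes_gap")
  # oversized particle clogs the narrow device
  expect_equal(classify_fit(14, 3, 15, 15)$label, "blockage_risk")
  # wide 25 um entrance admits particles side by side
  expect_equal(classify_fit(8, 5, 25, 15)$label, "multiple_lateral")
  # both dimensions ~ twice the particle: up to three per trap
  both <- classify_fit(10, 5, 25, 25)
  expect_setequal(strsplit(both$labels, ",")[[1]],
                  c("multiple_vertical", "multiple_lateral"))
  expect_equal(both$capacity, 3L)
  expect_equal(classify_fit(8, 3, 15, 15)$capacity, 1L)
  expect_equal(classify_fit(2, 3, 15, 15)$capacity, 0L)
})
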