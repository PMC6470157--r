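test_that("force-to-tension conversion matches the mass/length/density geometry", {
  # 40 mN on the default strip (20 mg, 15 mm, rho 1) is 30 mN/mm^2
  expect_equal(force_to_tension(40, 20, 15, 1), 30)
  expect_equal(force_to_tension(0, 20, 15, 1), 0)
  # scaling laws: doubling mass halves tension; doubling length doubles it
  expect_equal(force_to_tension(10, 40, 15, 1),
               force_to_tension(10, 20, 15, 1) / 2)
  expect_equal(force_to_tension(10, 20, 30, 1),
               force_to_tension(10, 20, 15, 1) * 2)
  expect_error(force_to_tension(10, 0, 15, 1), "admissible")
})

test_that("segmentation yields one segment per hold with the analytic transient mean", {
  pr <- strain_protocol(n_cycles = 1)
  p <- default_tissue_params()
  tr <- simulate_trace(pr, p, noise_sd = 0, seed = 1)
  seg <- segment_steps(tr)
  # one segment per constant-length run
  expect_equal(nrow(seg), length(rle(tr$commanded_length_mm)$values))
  steps <- dplyr::filter(seg, direction != "baseline")
  expect_true(all(steps$end_s - steps$start_s ==
                    pr$hold_s - pr$log_interval_s))
  # hold mean equals the discrete time-average of the exponential transient
  m <- trace_meta(tr)
  area <- m$mass_mg / (m$rho * m$L0_mm)
  lseg <- dplyr::filter(seg, direction == "lengthen")
  act <- p$muscle$basal_tone_fraction
  for (i in seq_len(nrow(lseg))) {
    f_ss <- composite_tension(lseg$strain[i], act, p) * area
    expect_equal(
      lseg$mean_force_mN[i],
      hold_mean_lengthen(f_ss, p$relax$overshoot, p$relax$tau_s,
                         pr$log_interval_s,
                         round(pr$hold_s / pr$log_interval_s)),
      tolerance = 1e-10)
  }
})

test_that("directions partition the segments and cycles are assigned at reversals", {
  tr <- simulate_trace(three_cycle_protocol(), default_tissue_params(),
                       noise_sd = 0.2, seed = 4)
  seg <- segment_steps(tr)
  expect_true(all(seg$direction %in% c("baseline", "lengthen", "shorten")))
  expect_setequal(unique(seg$cycle[seg$direction != "baseline"]), 1:3)
  # a single lengthen-only ramp is all cycle 1, direction lengthen
  ramp <- suppressWarnings(simulate_trace(
    strain_protocol(n_cycles = 1, shorten_stop_mN = 1e6),
    default_tissue_params(), noise_sd = 0.2, seed = 1))
  rseg <- dplyr::filter(segment_steps(ramp), direction == "lengthen")
  expect_true(all(rseg$cycle == 1))
})

test_that("a trace with no commanded-length changes segments to an empty table with a warning", {
  tr <- simulate_trace(seed = 1)
  flat <- tr[tr$commanded_length_mm == tr$commanded_length_mm[1], ]
  attr(flat, "meta") <- trace_meta(tr)
  class(flat) <- class(tr)
  expect_warning(seg <- segment_steps(flat), "no commanded length changes")
  expect_equal(nrow(seg), 0)
})

test_that("cycle curves are normalization-consistent and survive a CSV round trip", {
  tr <- simulate_trace(three_cycle_protocol(), default_tissue_params(),
                       noise_sd = 0.2, seed = 2)
  m <- trace_meta(tr)
  seg <- segment_steps(tr)
  cur <- build_cycle_curves(seg)
  expect_equal(nrow(dplyr::distinct(cur, cycle, direction)), 6)
  # tension x area reproduces the segment's mean force
  area <- m$mass_mg / (m$rho * m$L0_mm)
  reg <- dplyr::filter(seg, direction %in% c("lengthen", "shorten"),
                       !irregular)
  expect_equal(cur$tension * area, reg$mean_force_mN, tolerance = 1e-12)
  # strains strictly monotone within each (cycle, direction)
  cur |>
    dplyr::group_by(cycle, direction) |>
    dplyr::group_walk(function(df, key) {
      expect_true(all(diff(df$strain) > 0) || all(diff(df$strain) < 0))
    })
  f <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(cur, f)
  expect_equal(as.data.frame(read_curves_csv(f)), as.data.frame(cur),
               tolerance = 1e-9)
})

test_that("round trip through simulation and analysis recovers the model tension", {
  p <- default_tissue_params()
  tr <- simulate_trace(three_cycle_protocol(), p, noise_sd = 0.2, seed = 6)
  cur <- build_cycle_curves(segment_steps(tr))
  # cycle 2 carries the matrix-only element: compare to ecm_tension
  c2 <- cycle_curve(cur, 2)
  pred <- ecm_tension(c2$strain, p$ecm)
  # transient-average bias (< ~11% of steady state) plus noise
  expect_true(all(abs(c2$tension - pred) <= 0.115 * pmax(pred, 1) + 0.1))
  expect_lt(median(abs(c2$tension - pred) / pmax(pred, 0.5)), 0.115)
})

test_that("agonist responses recover the activation gain at the length-tension optimum", {
  # strip with no passive matrix, held near the optimal strain, saturating dose
  p <- tissue_params(
    ecm = ecm_params(amplitude = 0),
    muscle = muscle_params(max_tension = 10, basal_tone_fraction = 0)
  )
  pr <- strain_protocol(n_cycles = 1, max_strain = 2.5,
                        dose_events = list(dose_event(1, "carbachol", 100)))
  tr <- suppressWarnings(simulate_trace(pr, p, noise_sd = 0.05, seed = 3))
  resp <- agonist_response(tr)
  gain <- activation_level(c(carbachol = 100), p$pharm, basal = 0)
  held_strain <- tail(tr$commanded_length_mm, 1) / trace_meta(tr)$L0_mm
  expected <- gain * active_tension(held_strain, 1, p$muscle)
  expect_equal(resp$induced_tension_mN_mm2, expected, tolerance = 0.1)
  expect_gt(resp$induced_tension_mN_mm2, 0.9 * gain * p$muscle$max_tension *
              exp(-((held_strain - 2.5) / 0.6)^2))
  expect_false(resp$truncated)
})

test_that("zero-muscle strips show no agonist response and dose-response is monotone", {
  dead <- tissue_params(
    ecm = ecm_params(amplitude = 0),
    muscle = muscle_params(max_tension = 0, basal_tone_fraction = 0)
  )
  pr <- strain_protocol(n_cycles = 1, max_strain = 2.5,
                        dose_events = list(dose_event(1, "carbachol", 1)))
  tr <- suppressWarnings(simulate_trace(pr, dead, noise_sd = 0.05, seed = 2))
  resp <- agonist_response(tr)
  expect_lt(abs(resp$induced_tension_mN_mm2), 0.1)
  # concentration-dependent force responses: monotone over log-spaced doses
  p <- tissue_params(ecm = ecm_params(amplitude = 0),
                     muscle = muscle_params(basal_tone_fraction = 0))
  induced <- vapply(c(0.01, 0.1, 1, 10), function(conc) {
    pri <- strain_protocol(n_cycles = 1, max_strain = 2.5,
                           dose_events = list(dose_event(1, "carbachol",
                                                         conc)))
    tri <- suppressWarnings(simulate_trace(pri, p, noise_sd = 0.02,
                                           seed = 10))
    agonist_response(tri)$induced_tension_mN_mm2
  }, numeric(1))
  expect_true(all(diff(induced) > 0))
})
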