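#' Convert transducer force to tissue tension
#'
#' Average tension is force per cross-sectional area, with the cross-section
#' estimated from the strip's wet mass, reference length and density:
#' `area = mass / (rho * length)`, so
#' `tension = force * length * rho / mass` (mN/mm^2). With the default strip
#' geometry (mass 20 mg, length 15 mm, rho 1 mg/mm^3) a 40 mN force
#' corresponds to 30 mN/mm^2.
#'
#' @param force_mN Force in mN; vectorized.
#' @param mass_mg Wet mass in mg, > 0.
#' @param length_mm Reference length in mm, > 0.
#' @param rho Density in mg/mm^3, > 0.
#' @return Tension in mN/mm^2.
#' @examples
#' force_to_tension(40, mass_mg = 20, length_mm = 15)  # 30
#' @export
force_to_tension <- function(force_mN, mass_mg, length_mm, rho = 1) {
  check_num(mass_mg, "mass_mg", lower = 0, strict = TRUE)
  check_num(length_mm, "length_mm", lower = 0, strict = TRUE)
  check_num(rho, "rho", lower = 0, strict = TRUE)
  force_mN * length_mm * rho / mass_mg
}

#' Segment a trace into constant-length hold steps
#'
#' Splits the logged record at every change of the commanded length. Each
#' constant-length run becomes one step segment with its direction inferred
#' from the sign of the length jump entering the hold (`lengthen`, `shorten`;
#' the initial run with no preceding jump is `baseline`). The force is averaged
#' over all logged samples in the hold, absorbing the step transient exactly as
#' the instrument-side averaging does. Cycle indices increment at every
#' transition into a lengthening run; holds much longer than the protocol hold
#' (dose/stabilization periods) are flagged `irregular` and excluded from
#' cycle curves.
#'
#' @param trace A `transducer_trace` (simulated or read from CSV).
#' @param hold_s,log_interval_s Protocol hold duration and sampling interval;
#'   defaults come from the trace metadata.
#' @return A tibble with one row per hold: `cycle`, `direction`,
#'   `commanded_length_mm`, `strain`, `start_s`, `end_s`, `n_samples`,
#'   `mean_force_mN`, `mean_tension_mN_mm2`, `irregular`.
#' @export
segment_steps <- function(trace, hold_s = NULL, log_interval_s = NULL) {
  m <- trace_meta(trace)
  hold_s <- hold_s %||% m$hold_s
  log_interval_s <- log_interval_s %||% m$log_interval_s
  if (nrow(trace) == 0 || length(unique(trace$commanded_length_mm)) == 1) {
    warn("trace has no commanded length changes; returning empty segmentation")
    return(tibble::tibble(
      cycle = integer(), direction = character(),
      commanded_length_mm = numeric(), strain = numeric(),
      start_s = numeric(), end_s = numeric(), n_samples = integer(),
      mean_force_mN = numeric(), mean_tension_mN_mm2 = numeric(),
      irregular = logical()
    ))
  }
  r <- rle(trace$commanded_length_mm)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  lengths_mm <- r$values
  jump <- c(NA, diff(lengths_mm))
  direction <- dplyr::case_when(
    is.na(jump) ~ "baseline",
    jump > 0 ~ "lengthen",
    jump < 0 ~ "shorten"
  )
  cycle <- cumsum(direction == "lengthen" &
                    dplyr::lag(direction, default = "baseline") != "lengthen")
  cycle[direction == "baseline"] <- 0L
  seg <- tibble::tibble(
    cycle = as.integer(cycle),
    direction = direction,
    commanded_length_mm = lengths_mm,
    strain = lengths_mm / m$L0_mm,
    start_s = trace$time_s[starts],
    end_s = trace$time_s[ends],
    n_samples = as.integer(r$lengths),
    mean_force_mN = vapply(seq_along(starts), function(i) {
      mean(trace$force_mN[starts[i]:ends[i]])
    }, numeric(1))
  )
  expected_n <- round(hold_s / log_interval_s)
  seg$irregular <- seg$n_samples > expected_n + 1L
  short <- seg$n_samples < expected_n - 1L & seg$direction != "baseline"
  if (any(short)) {
    warn(sprintf("%d hold(s) have fewer samples than expected; averaged over available samples", sum(short)))
  }
  seg$mean_tension_mN_mm2 <- force_to_tension(
    seg$mean_force_mN, m$mass_mg, m$L0_mm, m$rho)
  seg
}

#' Build per-cycle tension-versus-strain curves
#'
#' Reduces step segments to one `(strain, tension)` curve per cycle and
#' direction, the representation on which the power-law stiffness fit
#' operates. Only regular protocol holds contribute (baseline and
#' dose/stabilization holds are dropped). Points are ordered in time, which
#' within one direction means strictly monotone strain.
#'
#' @param segments Output of [segment_steps()].
#' @return A tibble with columns `cycle`, `direction`, `strain`, `tension`
#'   (mN/mm^2).
#' @export
build_cycle_curves <- function(segments) {
  curves <- segments |>
    dplyr::filter(.data$direction %in% c("lengthen", "shorten"),
                  !.data$irregular) |>
    dplyr::transmute(.data$cycle, .data$direction, .data$strain,
                     tension = .data$mean_tension_mN_mm2)
  mono_ok <- curves |>
    dplyr::group_by(.data$cycle, .data$direction) |>
    dplyr::summarise(ok = all(diff(.data$strain) > 0) ||
                       all(diff(.data$strain) < 0) ||
                       dplyr::n() < 2, .groups = "drop")
  if (!all(mono_ok$ok)) {
    warn("strain is not strictly monotone within some cycle/direction group")
  }
  curves
}

#' Extract one cycle curve
#'
#' @param curves Output of [build_cycle_curves()].
#' @param cycle Cycle index.
#' @param direction `"lengthen"` or `"shorten"`.
#' @return A tibble with columns `strain`, `tension`, sorted by strain.
#' @export
cycle_curve <- function(curves, cycle, direction = "lengthen") {
  out <- curves |>
    dplyr::filter(.data$cycle == !!cycle, .data$direction == !!direction) |>
    dplyr::arrange(.data$strain) |>
    dplyr::select("strain", "tension")
  if (nrow(out) == 0) {
    abort(sprintf("no curve for cycle %s, direction %s", cycle, direction))
  }
  out
}

#' Write or read cycle curves as CSV
#'
#' @param curves Tibble from [build_cycle_curves()].
#' @param path File path.
#' @return `write_curves_csv()` returns `path` invisibly; `read_curves_csv()`
#'   the curves tibble.
#' @export
write_curves_csv <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    cycle = readr::col_integer(),
                    direction = readr::col_character(),
                    strain = readr::col_double(),
                    tension = readr::col_double()
                  ))
}

#' Quantify agonist-induced tension responses
#'
#' For every dose event recorded in the trace metadata, computes the induced
#' tension as the difference between the post-dose plateau (by default the
#' last 60 s of a 5-minute post-dose window) and the pre-dose baseline (the
#' 60 s preceding the dose), converted to tension via the strip geometry.
#' Windows truncated by the available record are flagged.
#'
#' @param trace A `transducer_trace` whose metadata records dose events.
#' @param baseline_s Length of the pre-dose baseline window (s).
#' @param response_window_s Post-dose window length (s).
#' @param plateau_s Length of the plateau window at the end of the post-dose
#'   window (s).
#' @return A tibble with one row per dose: `time_s`, `agonist`,
#'   `concentration`, `baseline_mN`, `plateau_mN`, `induced_tension_mN_mm2`,
#'   `truncated`.
#' @export
agonist_response <- function(trace, baseline_s = 60, response_window_s = 300,
                             plateau_s = 60) {
  m <- trace_meta(trace)
  doses <- m$doses
  if (nrow(doses) == 0) {
    abort("trace metadata records no dose events")
  }
  purrr::pmap_dfr(doses, function(time_s, agonist, concentration, ...) {
    pre <- trace$force_mN[trace$time_s > time_s - baseline_s &
                            trace$time_s <= time_s]
    lo <- time_s + response_window_s - plateau_s
    hi <- time_s + response_window_s
    post <- trace$force_mN[trace$time_s > lo & trace$time_s <= hi]
    truncated <- FALSE
    if (!length(post)) {
      # window extends beyond the record: fall back to the last plateau_s
      # of what is available after the dose
      avail <- trace$time_s[trace$time_s > time_s]
      post <- trace$force_mN[trace$time_s > max(avail) - plateau_s &
                               trace$time_s <= max(avail)]
      truncated <- TRUE
    } else if (hi > max(trace$time_s)) {
      truncated <- TRUE
    }
    if (!length(pre)) {
      pre <- trace$force_mN[trace$time_s <= time_s]
      truncated <- TRUE
    }
    b <- mean(pre)
    p <- mean(post)
    tibble::tibble(
      time_s = time_s, agonist = agonist, concentration = concentration,
      baseline_mN = b, plateau_mN = p,
      induced_tension_mN_mm2 = force_to_tension(p - b, m$mass_mg, m$L0_mm,
                                                m$rho),
      truncated = truncated
    )
  })
}
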