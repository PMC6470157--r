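#' Stepwise strain-cycle protocol
#'
#' Describes the automated organ-bath protocol: the strip is lengthened in
#' fixed increments, held at each length while the transducer output is logged,
#' and the lengthening is reversed once the hold-averaged force exceeds a
#' threshold chosen to avoid tissue damage; stepwise shortening is then
#' reversed as the force approaches zero. Optional dose events apply a
#' contractile agonist between cycles.
#'
#' @param step_mm Length increment per step (mm).
#' @param hold_s Hold duration per step (s).
#' @param log_interval_s Transducer sampling interval (s); must divide
#'   `hold_s`.
#' @param force_reversal_mN Lengthening reversal threshold on the hold-averaged
#'   force (mN).
#' @param shorten_stop_mN Hold-averaged force at or below which shortening
#'   reverses (mN); defaults to the ~1 mN preload, i.e. "force approaching
#'   zero".
#' @param n_cycles Number of lengthen/shorten cycles.
#' @param preload_mN Initial stable force after slack removal (mN); recorded as
#'   metadata.
#' @param full_scale_mN Transducer full-scale deflection (mN); simulated forces
#'   are clipped here.
#' @param max_strain Safety cap on commanded strain for protocols that would
#'   otherwise never reach the reversal threshold.
#' @param dose_events List of [dose_event()] objects.
#' @return An object of class `strain_protocol`.
#' @export
strain_protocol <- function(step_mm = 0.8, hold_s = 120, log_interval_s = 5,
                            force_reversal_mN = 40, shorten_stop_mN = 1,
                            n_cycles = 1, preload_mN = 1, full_scale_mN = 196,
                            max_strain = 3, dose_events = list()) {
  check_num(step_mm, "step_mm", lower = 0, strict = TRUE)
  check_num(hold_s, "hold_s", lower = 0, strict = TRUE)
  check_num(log_interval_s, "log_interval_s", lower = 0, strict = TRUE)
  if (abs(hold_s / log_interval_s - round(hold_s / log_interval_s)) > 1e-9) {
    abort("log_interval_s must divide hold_s")
  }
  check_num(force_reversal_mN, "force_reversal_mN", lower = 0, strict = TRUE)
  if (force_reversal_mN >= full_scale_mN) {
    abort("force_reversal_mN must be below full_scale_mN")
  }
  check_num(shorten_stop_mN, "shorten_stop_mN", lower = 0)
  check_num(n_cycles, "n_cycles", lower = 1)
  check_num(max_strain, "max_strain", lower = 1, strict = TRUE)
  stopifnot(is.list(dose_events),
            all(vapply(dose_events, inherits, TRUE, "dose_event")))
  structure(
    list(step_mm = step_mm, hold_s = hold_s, log_interval_s = log_interval_s,
         force_reversal_mN = force_reversal_mN,
         shorten_stop_mN = shorten_stop_mN, n_cycles = n_cycles,
         preload_mN = preload_mN, full_scale_mN = full_scale_mN,
         max_strain = max_strain, dose_events = dose_events),
    class = "strain_protocol"
  )
}

#' Agonist dose event within a protocol
#'
#' A dose applied after a given cycle's shortening has finished: the strip is
#' first held at its current length for `stabilize_s` so the force output
#' settles, the dose is then applied and the response recorded for `settle_s`.
#' If further cycles follow, the strip is shortened stepwise back to the
#' near-zero force level before the next lengthening begins (mirroring the
#' contracted tissue being returned to preload tension).
#'
#' @param after_cycle Cycle index after which the dose is applied.
#' @param agonist Agonist name (`"carbachol"`, `"histamine"`,
#'   `"isoproterenol"`).
#' @param concentration Concentration in uM.
#' @param stabilize_s Pre-dose stabilization hold (s).
#' @param settle_s Post-dose recording window (s).
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(after_cycle, agonist, concentration,
                       stabilize_s = 240, settle_s = 300) {
  check_num(after_cycle, "after_cycle", lower = 0)
  stopifnot(is.character(agonist), length(agonist) == 1)
  check_num(concentration, "concentration", lower = 0)
  check_num(stabilize_s, "stabilize_s", lower = 0)
  check_num(settle_s, "settle_s", lower = 0, strict = TRUE)
  structure(
    list(after_cycle = as.integer(after_cycle), agonist = agonist,
         concentration = concentration, stabilize_s = stabilize_s,
         settle_s = settle_s),
    class = "dose_event"
  )
}

#' Default three-cycle stiffness protocol
#'
#' Three strain cycles with 1 uM carbachol applied after cycle 2, so that
#' cycle 1 probes basal (ECM + basal tone), cycle 2 matrix-only (tone lost by
#' stretch), and cycle 3 agonist-induced stiffness.
#'
#' @param ... Overrides passed to [strain_protocol()].
#' @return A `strain_protocol`.
#' @export
three_cycle_protocol <- function(...) {
  defaults <- list(
    n_cycles = 3,
    dose_events = list(dose_event(2, "carbachol", 1))
  )
  args <- modifyList(defaults, list(...))
  do.call(strain_protocol, args)
}

#' Write or read a strain protocol as a flat key = value config file
#'
#' @param protocol A [strain_protocol()] object.
#' @param path File path.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns a `strain_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "strain_protocol"))
  scalar <- protocol[setdiff(names(protocol), "dose_events")]
  lines <- paste(names(scalar), "=", unlist(scalar))
  for (i in seq_along(protocol$dose_events)) {
    d <- protocol$dose_events[[i]]
    lines <- c(lines, sprintf(
      "dose.%d = after_cycle=%d agonist=%s concentration=%g stabilize_s=%g settle_s=%g",
      i, d$after_cycle, d$agonist, d$concentration, d$stabilize_s, d$settle_s))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  kv <- read_kv(path)
  dose_keys <- grep("^dose\\.", names(kv), value = TRUE)
  doses <- lapply(kv[dose_keys], function(v) {
    parts <- strsplit(strsplit(v, "\\s+")[[1]], "=")
    vals <- setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
    dose_event(
      after_cycle = as.numeric(vals[["after_cycle"]]),
      agonist = vals[["agonist"]],
      concentration = as.numeric(vals[["concentration"]]),
      stabilize_s = as.numeric(vals[["stabilize_s"]]),
      settle_s = as.numeric(vals[["settle_s"]])
    )
  })
  scalars <- kv[setdiff(names(kv), dose_keys)]
  args <- lapply(scalars, function(v) as.numeric(v))
  args$dose_events <- unname(doses)
  do.call(strain_protocol, args)
}
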