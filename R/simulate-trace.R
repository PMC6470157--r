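#' Simulate a force-transducer trace through a strain-cycle protocol
#'
#' Drives the forward tissue model through the stepwise lengthen/hold/shorten
#' protocol and returns the logged transducer record. At each hold the force
#' follows the step transient toward the composite steady-state tension
#' (converted to force via the strip cross-section `mass / (rho * L0)`);
#' lengthening reverses at the first step whose hold-averaged (noisy) force
#' exceeds the reversal threshold, shortening reverses once the hold-averaged
#' force falls to the near-zero stop level (or the commanded length returns to
#' the reference length). Basal muscle tone is lost at the lengthen-to-shorten
#' reversal of any cycle that stretched the strip beyond the tone-loss
#' threshold, and is only restored by an agonist dose. Dose events apply their
#' agonist after the given cycle, record the response, and (if cycles remain)
#' shorten the now-contracted strip back to the stop force before the next
#' lengthening.
#'
#' Gaussian noise of standard deviation `noise_sd` is added to every logged
#' sample, and forces are clipped to `[0, full_scale_mN]`. The same seed always
#' reproduces the identical trace. A protocol that can never reach the reversal
#' threshold ends at the protocol's maximum strain cap with a warning and a
#' `cap_hit` metadata flag.
#'
#' @param protocol A [strain_protocol()].
#' @param params A [tissue_params()].
#' @param noise_sd Force noise standard deviation (mN).
#' @param seed Integer seed; all randomness derives from it.
#' @param tissue_layer,treatment,donor Metadata labels carried in the trace.
#' @return A tibble of class `transducer_trace` with columns `time_s`,
#'   `force_mN`, `commanded_length_mm`, and a `meta` attribute (geometry,
#'   labels, seed, protocol, dose log, flags). Access metadata with
#'   [trace_meta()].
#' @examples
#' tr <- simulate_trace(three_cycle_protocol(), default_tissue_params(),
#'                      noise_sd = 0.2, seed = 1)
#' head(tr)
#' @export
simulate_trace <- function(protocol = three_cycle_protocol(),
                           params = default_tissue_params(),
                           noise_sd = 0.2, seed = 1,
                           tissue_layer = "mucosa", treatment = "vehicle",
                           donor = "donor_01") {
  stopifnot(inherits(protocol, "strain_protocol"),
            inherits(params, "tissue_params"))
  check_num(noise_sd, "noise_sd", lower = 0)
  withr::with_seed(seed, simulate_trace_impl(
    protocol, params, noise_sd, seed, tissue_layer, treatment, donor))
}

simulate_trace_impl <- function(protocol, params, noise_sd, seed,
                                tissue_layer, treatment, donor) {
  geom <- params$geometry
  area <- geom$mass_mg / (geom$rho * geom$L0_mm)   # mm^2
  d_lambda <- protocol$step_mm / geom$L0_mm
  n_per_hold <- round(protocol$hold_s / protocol$log_interval_s)
  t_rel <- seq_len(n_per_hold) * protocol$log_interval_s

  state <- new.env(parent = emptyenv())
  state$time <- 0
  state$lambda <- 1
  state$basal <- params$muscle$basal_tone_fraction
  state$doses <- numeric()
  state$rows <- vector("list", 0)
  state$cap_hit <- FALSE
  state$tone_lost_after_cycle <- NA_integer_
  state$dose_log <- vector("list", 0)

  activation <- function() {
    activation_level(state$doses, params$pharm, basal = state$basal)
  }
  steady_force <- function(lambda) {
    composite_tension(lambda, activation(), params) * area
  }
  log_hold <- function(lambda, kind, duration_s = protocol$hold_s,
                       f_from = NULL) {
    tt <- if (duration_s == protocol$hold_s) t_rel else {
      seq_len(round(duration_s / protocol$log_interval_s)) *
        protocol$log_interval_s
    }
    f_ss <- steady_force(lambda)
    f <- switch(kind,
      lengthen = step_transient(f_ss, params$relax, tt, "lengthen"),
      shorten = step_transient(f_ss, params$relax, tt, "shorten"),
      settle = rep(f_ss, length(tt)),
      dose = f_from + (f_ss - f_from) * (1 - exp(-tt / params$relax$tau_s))
    )
    f <- f + rnorm(length(f), sd = noise_sd)
    f <- pmin(pmax(f, 0), protocol$full_scale_mN)
    state$rows[[length(state$rows) + 1]] <- list(
      time_s = state$time + tt, force_mN = f,
      commanded_length_mm = rep(lambda * geom$L0_mm, length(tt))
    )
    state$time <- state$time + max(tt)
    mean(f)
  }
  shorten_to_stop <- function() {
    repeat {
      if (state$lambda <= 1 + 1e-9) break
      state$lambda <- max(1, state$lambda - d_lambda)
      m <- log_hold(state$lambda, "shorten")
      if (m <= protocol$shorten_stop_mN) break
    }
  }

  # initial stabilized baseline hold at the reference length
  log_hold(1, "settle")

  for (cycle in seq_len(protocol$n_cycles)) {
    max_lambda <- state$lambda
    # lengthening phase
    repeat {
      nxt <- state$lambda + d_lambda
      if (nxt > protocol$max_strain + 1e-9) {
        state$cap_hit <- TRUE
        break
      }
      state$lambda <- nxt
      max_lambda <- max(max_lambda, nxt)
      m <- log_hold(state$lambda, "lengthen")
      if (m > protocol$force_reversal_mN) break
    }
    # stretch-induced loss of basal tone takes effect at the reversal
    if (max_lambda > params$muscle$tone_loss_strain_threshold &&
        state$basal > 0) {
      state$basal <- 0
      state$tone_lost_after_cycle <- cycle
    }
    shorten_to_stop()
    # dose events scheduled after this cycle
    for (d in protocol$dose_events) {
      if (d$after_cycle != cycle) next
      if (d$stabilize_s > 0) log_hold(state$lambda, "settle", d$stabilize_s)
      f_before <- steady_force(state$lambda)
      dose_time <- state$time
      prev <- if (d$agonist %in% names(state$doses)) {
        state$doses[[d$agonist]]
      } else 0
      state$doses[d$agonist] <- prev + d$concentration
      log_hold(state$lambda, "dose", d$settle_s, f_from = f_before)
      state$dose_log[[length(state$dose_log) + 1]] <- tibble::tibble(
        time_s = dose_time, agonist = d$agonist,
        concentration = d$concentration,
        activation_after = activation()
      )
      if (cycle < protocol$n_cycles) shorten_to_stop()
    }
  }
  if (state$cap_hit) {
    warn("lengthening never reached the reversal threshold; trace capped at the protocol's maximum strain")
  }

  out <- dplyr::bind_rows(lapply(state$rows, tibble::as_tibble))
  meta <- list(
    L0_mm = geom$L0_mm, mass_mg = geom$mass_mg, rho = geom$rho,
    tissue_layer = tissue_layer, treatment = treatment, donor = donor,
    seed = seed, noise_sd = noise_sd,
    hold_s = protocol$hold_s, log_interval_s = protocol$log_interval_s,
    preload_mN = protocol$preload_mN, full_scale_mN = protocol$full_scale_mN,
    cap_hit = state$cap_hit,
    tone_lost_after_cycle = state$tone_lost_after_cycle,
    doses = if (length(state$dose_log)) {
      dplyr::bind_rows(state$dose_log)
    } else {
      tibble::tibble(time_s = numeric(), agonist = character(),
                     concentration = numeric(), activation_after = numeric())
    }
  )
  new_trace(out, meta)
}

new_trace <- function(df, meta) {
  out <- tibble::as_tibble(df)
  attr(out, "meta") <- meta
  class(out) <- c("transducer_trace", class(out))
  out
}

#' Trace metadata
#'
#' @param trace A `transducer_trace`.
#' @return The metadata list (geometry, labels, seed, flags, dose log).
#' @export
trace_meta <- function(trace) {
  m <- attr(trace, "meta")
  if (is.null(m)) abort("not a transducer trace: missing metadata")
  m
}

#' Write or read a transducer trace as CSV
#'
#' Plain CSV with columns `time_s`, `force_mN`, `commanded_length_mm` and a
#' commented header block (`# key: value`) carrying the strip metadata and the
#' dose log, so a written file round-trips to an equivalent trace.
#'
#' @param trace A `transducer_trace`.
#' @param path Output path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `transducer_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  m <- trace_meta(trace)
  hdr <- c(
    sprintf("# L0_mm: %.10g", m$L0_mm),
    sprintf("# mass_mg: %.10g", m$mass_mg),
    sprintf("# rho: %.10g", m$rho),
    sprintf("# tissue_layer: %s", m$tissue_layer),
    sprintf("# treatment: %s", m$treatment),
    sprintf("# donor: %s", m$donor),
    sprintf("# seed: %d", as.integer(m$seed)),
    sprintf("# noise_sd: %.10g", m$noise_sd),
    sprintf("# hold_s: %.10g", m$hold_s),
    sprintf("# log_interval_s: %.10g", m$log_interval_s),
    sprintf("# preload_mN: %.10g", m$preload_mN),
    sprintf("# full_scale_mN: %.10g", m$full_scale_mN),
    sprintf("# cap_hit: %s", m$cap_hit),
    sprintf("# tone_lost_after_cycle: %s", m$tone_lost_after_cycle)
  )
  if (nrow(m$doses)) {
    hdr <- c(hdr, sprintf(
      "# dose: time_s=%.10g agonist=%s concentration=%.10g activation_after=%.10g",
      m$doses$time_s, m$doses$agonist, m$doses$concentration,
      m$doses$activation_after))
  }
  writeLines(hdr, path)
  readr::write_csv(as.data.frame(trace), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- readr::read_csv(I(lines[!startsWith(lines, "#")]),
                          show_col_types = FALSE)
  need <- c("time_s", "force_mN", "commanded_length_mm")
  if (!all(need %in% names(body))) {
    abort(sprintf("trace CSV must contain columns %s",
                  paste(need, collapse = ", ")))
  }
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]+:\\s*", "", kv))
  get1 <- function(key, coerce = as.numeric, default = NA) {
    i <- which(keys == key)
    if (!length(i)) return(default)
    coerce(vals[i[1]])
  }
  doses <- vals[keys == "dose"]
  dose_df <- if (length(doses)) {
    dplyr::bind_rows(lapply(doses, function(v) {
      parts <- strsplit(strsplit(v, "\\s+")[[1]], "=")
      vv <- setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
      tibble::tibble(time_s = as.numeric(vv[["time_s"]]),
                     agonist = vv[["agonist"]],
                     concentration = as.numeric(vv[["concentration"]]),
                     activation_after = as.numeric(vv[["activation_after"]]))
    }))
  } else {
    tibble::tibble(time_s = numeric(), agonist = character(),
                   concentration = numeric(), activation_after = numeric())
  }
  meta <- list(
    L0_mm = get1("L0_mm"), mass_mg = get1("mass_mg"), rho = get1("rho"),
    tissue_layer = get1("tissue_layer", as.character, "unknown"),
    treatment = get1("treatment", as.character, "unknown"),
    donor = get1("donor", as.character, "unknown"),
    seed = get1("seed", as.integer, NA_integer_),
    noise_sd = get1("noise_sd"),
    hold_s = get1("hold_s", default = 120),
    log_interval_s = get1("log_interval_s", default = 5),
    preload_mN = get1("preload_mN", default = 1),
    full_scale_mN = get1("full_scale_mN", default = 196),
    cap_hit = isTRUE(get1("cap_hit", as.logical, FALSE)),
    tone_lost_after_cycle = get1("tone_lost_after_cycle", as.integer,
                                 NA_integer_),
    doses = dose_df
  )
  if (!is.finite(meta$L0_mm) || !is.finite(meta$mass_mg)) {
    abort("trace CSV is missing required geometry metadata (L0_mm, mass_mg)")
  }
  new_trace(body, meta)
}

#' @export
print.transducer_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf(
    "<transducer_trace> %d samples, %.0f s; %s/%s (%s), L0 = %g mm, mass = %g mg\n",
    nrow(x), max(x$time_s), m$tissue_layer, m$treatment, m$donor,
    m$L0_mm, m$mass_mg))
  NextMethod()
}
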