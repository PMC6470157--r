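#' Extracellular-matrix element parameters
#'
#' The passive element of the tissue model: a slack-length power-law spring.
#' Below the slack strain `slack_strain` the element carries no tension; above
#' it, tension rises as a power of the normalized strain. Two functional forms
#' are supported:
#'
#' * `"engage"` (default): `A_e * ((lambda / lambda_s)^k_e - 1)` for
#'   `lambda > lambda_s`, zero below. Continuous at the slack strain; this is
#'   the form that reproduces the matrix-only strain cycle, which bears no
#'   tension from the reference length up to twice the reference length and
#'   then stiffens rapidly.
#' * `"power"`: `A_e * (lambda / lambda_s)^k_e` for `lambda >= lambda_s`, zero
#'   below. With `slack_strain = 1` this is the textbook hyperelastic power law
#'   `T = A * lambda^k` with resting tension `A` at the reference length --
#'   exactly the model class the stiffness regression fits, which makes it the
#'   right generating form for parameter-recovery studies.
#'
#' @param amplitude Tension scale \eqn{A_e} (mN/mm^2), >= 0.
#' @param exponent Dimensionless stiffening exponent \eqn{k_e}, >= 1.
#' @param slack_strain Strain \eqn{\lambda_s} (dimensionless, >= 1) below which
#'   the element is slack.
#' @param form `"engage"` or `"power"`; see Details.
#' @return An object of class `ecm_params`.
#' @seealso [ecm_tension()], [tissue_params()]
#' @export
ecm_params <- function(amplitude = 10, exponent = 6, slack_strain = 2,
                       form = c("engage", "power")) {
  form <- match.arg(form)
  check_num(amplitude, "amplitude", lower = 0)
  check_num(exponent, "exponent", lower = 1)
  check_num(slack_strain, "slack_strain", lower = 1)
  structure(
    list(amplitude = amplitude, exponent = exponent,
         slack_strain = slack_strain, form = form),
    class = "ecm_params"
  )
}

#' Active-muscle element parameters
#'
#' A lumped length-tension element: active tension is a Gaussian in strain,
#' peaking at the optimal strain where filament overlap is maximal, scaled by
#' the activation level. `basal_tone_fraction` is the activation present before
#' any agonist; once the tissue has been stretched beyond
#' `tone_loss_strain_threshold`, basal tone is lost (from the following
#' shortening onward) until a contractile agonist re-activates the muscle.
#'
#' @param max_tension Maximal active tension \eqn{T_{max}} (mN/mm^2) at full
#'   activation and optimal strain.
#' @param optimal_strain Strain of peak active tension (dimensionless, > 1).
#' @param width Gaussian width of the length-tension curve (dimensionless).
#' @param basal_tone_fraction Activation in `[0, 1]` before any agonist.
#' @param tone_loss_strain_threshold Strain beyond which basal tone is lost
#'   after stretch.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(max_tension = 10, optimal_strain = 2.5, width = 0.6,
                          basal_tone_fraction = 0.3,
                          tone_loss_strain_threshold = 2) {
  check_num(max_tension, "max_tension", lower = 0)
  check_num(optimal_strain, "optimal_strain", lower = 1, strict = TRUE)
  check_num(width, "width", lower = 0, strict = TRUE)
  check_num(basal_tone_fraction, "basal_tone_fraction", lower = 0, upper = 1)
  check_num(tone_loss_strain_threshold, "tone_loss_strain_threshold", lower = 1)
  structure(
    list(max_tension = max_tension, optimal_strain = optimal_strain,
         width = width, basal_tone_fraction = basal_tone_fraction,
         tone_loss_strain_threshold = tone_loss_strain_threshold),
    class = "muscle_params"
  )
}

#' Pharmacology parameters
#'
#' Hill dose-response parameters for the contractile agonists (carbachol,
#' histamine) and an inhibitory factor for the beta-agonist isoproterenol.
#' Concentrations are in micromolar throughout. Isoproterenol scales activation
#' multiplicatively into `[0, 1]` (it attenuates but cannot invert force).
#'
#' @param carbachol_ec50,histamine_ec50 Half-maximal concentrations (uM), > 0.
#' @param carbachol_hill,histamine_hill Hill coefficients, > 0.
#' @param iso_ic50 Isoproterenol half-inhibition concentration (uM).
#' @param iso_hill Isoproterenol Hill coefficient.
#' @param iso_max_relaxation Maximal fractional attenuation in `[0, 1)`.
#' @return An object of class `pharm_params`.
#' @export
pharm_params <- function(carbachol_ec50 = 0.1, carbachol_hill = 1.5,
                         histamine_ec50 = 2, histamine_hill = 1.2,
                         iso_ic50 = 0.1, iso_hill = 1,
                         iso_max_relaxation = 0.8) {
  for (v in c("carbachol_ec50", "carbachol_hill", "histamine_ec50",
              "histamine_hill", "iso_ic50", "iso_hill")) {
    check_num(get(v), v, lower = 0, strict = TRUE)
  }
  check_num(iso_max_relaxation, "iso_max_relaxation", lower = 0, upper = 1)
  structure(
    list(
      agonists = list(
        carbachol = list(ec50 = carbachol_ec50, hill = carbachol_hill),
        histamine = list(ec50 = histamine_ec50, hill = histamine_hill)
      ),
      iso = list(ic50 = iso_ic50, hill = iso_hill,
                 max_relaxation = iso_max_relaxation)
    ),
    class = "pharm_params"
  )
}

#' Step-relaxation parameters
#'
#' After each length step the transducer force shows an instantaneous
#' overshoot (undershoot on shortening) that relaxes exponentially to the
#' steady-state value. With the default time constant the residual at 120 s is
#' below 5% of steady state, matching force that stabilizes within two minutes.
#'
#' @param tau_s Relaxation time constant (s), > 0.
#' @param overshoot Fractional instantaneous overshoot above steady state, >= 0.
#' @return An object of class `relax_params`.
#' @export
relax_params <- function(tau_s = 25, overshoot = 0.5) {
  check_num(tau_s, "tau_s", lower = 0, strict = TRUE)
  check_num(overshoot, "overshoot", lower = 0)
  structure(list(tau_s = tau_s, overshoot = overshoot), class = "relax_params")
}

#' Strip geometry
#'
#' Reference length, wet mass and density of a tissue strip. The
#' cross-sectional area used to convert force to tension is
#' `mass / (rho * length)`.
#'
#' @param L0_mm Reference length \eqn{L_0} (mm), > 0.
#' @param mass_mg Wet mass (mg), > 0.
#' @param rho Density (mg/mm^3), > 0.
#' @return An object of class `strip_geometry`.
#' @export
strip_geometry <- function(L0_mm = 15, mass_mg = 20, rho = 1) {
  check_num(L0_mm, "L0_mm", lower = 0, strict = TRUE)
  check_num(mass_mg, "mass_mg", lower = 0, strict = TRUE)
  check_num(rho, "rho", lower = 0, strict = TRUE)
  structure(list(L0_mm = L0_mm, mass_mg = mass_mg, rho = rho),
            class = "strip_geometry")
}

#' Full tissue-strip parameter set
#'
#' Bundles the ECM element, muscle element, pharmacology, relaxation kinetics
#' and strip geometry into one object consumed by the forward model and the
#' trace simulator.
#'
#' @param ecm An [ecm_params()] object.
#' @param muscle A [muscle_params()] object.
#' @param pharm A [pharm_params()] object.
#' @param relax A [relax_params()] object.
#' @param geometry A [strip_geometry()] object.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(ecm = ecm_params(), muscle = muscle_params(),
                          pharm = pharm_params(), relax = relax_params(),
                          geometry = strip_geometry()) {
  stopifnot(inherits(ecm, "ecm_params"), inherits(muscle, "muscle_params"),
            inherits(pharm, "pharm_params"), inherits(relax, "relax_params"),
            inherits(geometry, "strip_geometry"))
  structure(list(ecm = ecm, muscle = muscle, pharm = pharm, relax = relax,
                 geometry = geometry),
            class = "tissue_params")
}

#' Default mucosal strip parameters
#'
#' The documented default parameterization of a cultured mucosal strip:
#' engagement-form ECM with slack at twice the reference length, a Gaussian
#' length-tension muscle element with basal tone, and relaxation kinetics that
#' settle within two minutes.
#'
#' @return A [tissue_params()] object.
#' @export
default_tissue_params <- function() tissue_params()

#' Pure power-law (matrix-only) strip parameters
#'
#' A strip whose tension is exactly `T = A * lambda^k` for all strains at or
#' above the reference length, with no active muscle. This is the model class
#' of the stiffness regression itself, so traces simulated from it have a known
#' ground-truth `A` and `k`; it is the generating model for parameter-recovery
#' and group-comparison studies. The default amplitude is small (a compliant
#' mucosa whose resting tension is a fraction of a mN/mm^2), placing the 40 mN
#' lengthening reversal near 2.45 times the reference length and giving curves
#' with ~25-30 fit points.
#'
#' @param amplitude Resting tension `A` (mN/mm^2).
#' @param exponent Stiffening exponent `k`.
#' @param geometry A [strip_geometry()].
#' @return A [tissue_params()] object with `T_max = 0` (no muscle).
#' @export
power_law_tissue <- function(amplitude = 0.12, exponent = 6,
                             geometry = strip_geometry()) {
  tissue_params(
    ecm = ecm_params(amplitude = amplitude, exponent = exponent,
                     slack_strain = 1, form = "power"),
    muscle = muscle_params(max_tension = 0, basal_tone_fraction = 0),
    geometry = geometry
  )
}

# ---- flat key = value serialization ---------------------------------------

flatten_params <- function(p) {
  c(
    ecm.amplitude = p$ecm$amplitude, ecm.exponent = p$ecm$exponent,
    ecm.slack_strain = p$ecm$slack_strain, ecm.form = p$ecm$form,
    muscle.max_tension = p$muscle$max_tension,
    muscle.optimal_strain = p$muscle$optimal_strain,
    muscle.width = p$muscle$width,
    muscle.basal_tone_fraction = p$muscle$basal_tone_fraction,
    muscle.tone_loss_strain_threshold = p$muscle$tone_loss_strain_threshold,
    pharm.carbachol_ec50 = p$pharm$agonists$carbachol$ec50,
    pharm.carbachol_hill = p$pharm$agonists$carbachol$hill,
    pharm.histamine_ec50 = p$pharm$agonists$histamine$ec50,
    pharm.histamine_hill = p$pharm$agonists$histamine$hill,
    pharm.iso_ic50 = p$pharm$iso$ic50, pharm.iso_hill = p$pharm$iso$hill,
    pharm.iso_max_relaxation = p$pharm$iso$max_relaxation,
    relax.tau_s = p$relax$tau_s, relax.overshoot = p$relax$overshoot,
    geometry.L0_mm = p$geometry$L0_mm, geometry.mass_mg = p$geometry$mass_mg,
    geometry.rho = p$geometry$rho
  )
}

#' Write or read tissue parameters as a flat key = value config file
#'
#' Plain-text serialization: one `key = value` line per parameter, `#` comments
#' ignored on read. All defaults are emitted, so a written file is a complete
#' record of the parameterization.
#'
#' @param params A [tissue_params()] object.
#' @param path File path.
#' @return `write_tissue_params()` returns `path` invisibly;
#'   `read_tissue_params()` returns a [tissue_params()] object.
#' @export
write_tissue_params <- function(params, path) {
  stopifnot(inherits(params, "tissue_params"))
  kv <- flatten_params(params)
  writeLines(paste(names(kv), "=", unname(kv)), path)
  invisible(path)
}

#' @rdname write_tissue_params
#' @export
read_tissue_params <- function(path) {
  kv <- read_kv(path)
  num <- function(key, default) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else default
  }
  tissue_params(
    ecm = ecm_params(
      amplitude = num("ecm.amplitude", 10),
      exponent = num("ecm.exponent", 6),
      slack_strain = num("ecm.slack_strain", 2),
      form = kv[["ecm.form"]] %||% "engage"
    ),
    muscle = muscle_params(
      max_tension = num("muscle.max_tension", 10),
      optimal_strain = num("muscle.optimal_strain", 2.5),
      width = num("muscle.width", 0.6),
      basal_tone_fraction = num("muscle.basal_tone_fraction", 0.3),
      tone_loss_strain_threshold = num("muscle.tone_loss_strain_threshold", 2)
    ),
    pharm = pharm_params(
      carbachol_ec50 = num("pharm.carbachol_ec50", 0.1),
      carbachol_hill = num("pharm.carbachol_hill", 1.5),
      histamine_ec50 = num("pharm.histamine_ec50", 2),
      histamine_hill = num("pharm.histamine_hill", 1.2),
      iso_ic50 = num("pharm.iso_ic50", 0.1),
      iso_hill = num("pharm.iso_hill", 1),
      iso_max_relaxation = num("pharm.iso_max_relaxation", 0.8)
    ),
    relax = relax_params(
      tau_s = num("relax.tau_s", 25),
      overshoot = num("relax.overshoot", 0.5)
    ),
    geometry = strip_geometry(
      L0_mm = num("geometry.L0_mm", 15),
      mass_mg = num("geometry.mass_mg", 20),
      rho = num("geometry.rho", 1)
    )
  )
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(m) != 3
  if (any(bad)) {
    abort(sprintf("malformed config line: %s", lines[bad][1]))
  }
  vals <- trimws(vapply(m, `[`, "", 3))
  names(vals) <- trimws(vapply(m, `[`, "", 2))
  as.list(vals)
}

check_num <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) && !is.character(x)) {
    abort(sprintf("`%s` must be numeric", name))
  }
  if (is.character(x)) return(invisible(x))
  if (length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (strict) x > lower && x <= upper else x >= lower && x <= upper
  if (!ok) {
    abort(sprintf("`%s` = %g is outside its admissible range", name, x))
  }
  invisible(x)
}

#' @export
print.tissue_params <- function(x, ...) {
  kv <- flatten_params(x)
  cat("<tissue_params>\n")
  cat(paste0("  ", names(kv), " = ", unname(kv)), sep = "\n")
  invisible(x)
}
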