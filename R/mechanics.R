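#' Passive extracellular-matrix tension
#'
#' Tension carried by the ECM element at a given strain. The element is slack
#' (zero tension) up to `slack_strain`; above it tension increases strictly
#' monotonically. See [ecm_params()] for the two supported functional forms.
#'
#' @param strain Strain \eqn{\lambda = L / L_0} (dimensionless, >= 0);
#'   vectorized.
#' @param ecm An [ecm_params()] object.
#' @return Tension in mN/mm^2, same length as `strain`.
#' @examples
#' ecm_tension(c(1.5, 2, 2.2), ecm_params())
#' @export
ecm_tension <- function(strain, ecm = ecm_params()) {
  stopifnot(inherits(ecm, "ecm_params"))
  if (any(strain < 0)) abort("strain must be nonnegative")
  x <- strain / ecm$slack_strain
  if (ecm$form == "engage") {
    ifelse(strain <= ecm$slack_strain, 0,
           ecm$amplitude * (x^ecm$exponent - 1))
  } else {
    ifelse(strain < ecm$slack_strain, 0, ecm$amplitude * x^ecm$exponent)
  }
}

#' Smooth-muscle activation level from agonist doses
#'
#' Combines basal tone with per-agonist Hill occupancies. Each contractile
#' agonist (carbachol, histamine) contributes a Hill occupancy
#' `c^n / (EC50^n + c^n)`; occupancies combine complement-wise
#' (`1 - prod(1 - occ_i)`), so a second agonist augments the first but the
#' combination saturates at full activation. The result is scaled onto the
#' head-room above basal tone and finally attenuated by the isoproterenol
#' relaxation factor:
#' `activation = (basal + (1 - basal) * combined) * relax(c_iso)`.
#'
#' @param doses Named numeric vector or list of concentrations in uM, e.g.
#'   `c(carbachol = 1)`. Names must be known agonists (`carbachol`,
#'   `histamine`) or `isoproterenol`. An empty vector means no stimulus.
#' @param pharm A [pharm_params()] object.
#' @param basal Basal tone fraction in `[0, 1]`.
#' @return Activation level in `[0, 1]`.
#' @examples
#' activation_level(c(carbachol = 1), pharm_params(), basal = 0)
#' @export
activation_level <- function(doses = numeric(), pharm = pharm_params(),
                             basal = 0) {
  stopifnot(inherits(pharm, "pharm_params"))
  check_num(basal, "basal", lower = 0, upper = 1)
  doses <- unlist(doses)
  if (length(doses)) {
    if (is.null(names(doses)) || any(!nzchar(names(doses)))) {
      abort("doses must be a named vector of agonist concentrations")
    }
    known <- c(names(pharm$agonists), "isoproterenol")
    unknown <- setdiff(names(doses), known)
    if (length(unknown)) {
      abort(sprintf("unknown agonist(s): %s", paste(unknown, collapse = ", ")))
    }
    if (any(doses < 0)) abort("concentrations must be nonnegative")
  }
  occ <- vapply(names(pharm$agonists), function(a) {
    conc <- if (a %in% names(doses)) unname(doses[[a]]) else 0
    hill_occupancy(conc, pharm$agonists[[a]]$ec50, pharm$agonists[[a]]$hill)
  }, numeric(1))
  combined <- 1 - prod(1 - occ)
  act <- basal + (1 - basal) * combined
  iso <- if ("isoproterenol" %in% names(doses)) {
    unname(doses[["isoproterenol"]])
  } else 0
  act <- act * relaxation_factor(iso, pharm)
  min(max(act, 0), 1)
}

hill_occupancy <- function(conc, ec50, hill) {
  if (conc <= 0) return(0)
  conc^hill / (ec50^hill + conc^hill)
}

#' Isoproterenol relaxation factor
#'
#' Multiplier in `[0, 1]`, monotonically nonincreasing in concentration, equal
#' to 1 at zero dose: `1 - max_relaxation * c^n / (IC50^n + c^n)`.
#'
#' @param conc Isoproterenol concentration (uM), >= 0; vectorized.
#' @param pharm A [pharm_params()] object.
#' @return Relaxation multiplier(s) in `[0, 1]`.
#' @export
relaxation_factor <- function(conc, pharm = pharm_params()) {
  if (any(conc < 0)) abort("concentrations must be nonnegative")
  occ <- vapply(conc, hill_occupancy, numeric(1),
                ec50 = pharm$iso$ic50, hill = pharm$iso$hill)
  1 - pharm$iso$max_relaxation * occ
}

#' Active smooth-muscle tension
#'
#' Gaussian length-tension curve scaled by activation:
#' `activation * T_max * exp(-((lambda - lambda_opt) / w)^2)`. The maximum over
#' strain sits exactly at the optimal strain; zero activation gives zero
#' tension at every strain.
#'
#' @param strain Strain (dimensionless); vectorized.
#' @param activation Activation level in `[0, 1]`.
#' @param muscle A [muscle_params()] object.
#' @return Tension in mN/mm^2.
#' @examples
#' active_tension(2.5, 1, muscle_params())  # = T_max
#' @export
active_tension <- function(strain, activation, muscle = muscle_params()) {
  stopifnot(inherits(muscle, "muscle_params"))
  check_num(activation, "activation", lower = 0, upper = 1)
  activation * muscle$max_tension *
    exp(-((strain - muscle$optimal_strain) / muscle$width)^2)
}

#' Composite tissue tension
#'
#' The two elements of the model are exactly additive: composite tension is
#' ECM tension plus active muscle tension.
#'
#' @param strain Strain (dimensionless); vectorized.
#' @param activation Activation level in `[0, 1]`.
#' @param params A [tissue_params()] object.
#' @return Tension in mN/mm^2.
#' @export
composite_tension <- function(strain, activation, params = default_tissue_params()) {
  stopifnot(inherits(params, "tissue_params"))
  ecm_tension(strain, params$ecm) +
    active_tension(strain, activation, params$muscle)
}

#' Force transient after a length step
#'
#' Immediately after a lengthening step the force overshoots its new steady
#' state and relaxes exponentially down to it; after a shortening step it
#' undershoots (floored at zero force) and relaxes up:
#' lengthening `F(t) = F_ss * (1 + overshoot * exp(-t / tau))`,
#' shortening `F(t) = max(0, F_ss * (1 - overshoot * exp(-t / tau)))`.
#'
#' @param f_steady Steady-state force (mN).
#' @param relax A [relax_params()] object.
#' @param t_since_step Time since the step (s), >= 0; vectorized.
#' @param direction `"lengthen"` or `"shorten"`.
#' @return Force in mN, same length as `t_since_step`.
#' @examples
#' step_transient(10, relax_params(), c(0, 120), "lengthen")
#' @export
step_transient <- function(f_steady, relax = relax_params(), t_since_step,
                           direction = c("lengthen", "shorten")) {
  direction <- match.arg(direction)
  stopifnot(inherits(relax, "relax_params"))
  if (any(t_since_step < 0)) abort("time since step must be nonnegative")
  decay <- relax$overshoot * exp(-t_since_step / relax$tau_s)
  if (direction == "lengthen") {
    f_steady * (1 + decay)
  } else {
    pmax(0, f_steady * (1 - decay))
  }
}
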