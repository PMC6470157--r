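#' Fit the power-law stiffness model to a tension-strain curve
#'
#' Fits `tension = A * strain^k` by ordinary least squares on the double
#' natural-log transformed data: `ln T = b + k ln(lambda)`, with `A = e^b`.
#' Points with tension at or below `min_tension` are excluded before the log
#' transform (the log is undefined at zero and the matrix-only cycle is
#' genuinely tension-free over its slack region), as are points with strain
#' <= 1. A valid fit requires more than 5 retained data pairs; with fewer the
#' function returns an invalid-fit object carrying the reason rather than
#' throwing.
#'
#' @param curve A tibble/data frame with columns `strain` and `tension`
#'   (one cycle, one direction; see [cycle_curve()]).
#' @param min_tension Tension floor (mN/mm^2) below which points are excluded
#'   from the log-log regression.
#' @return An object of class `power_law_fit` with elements `A`, `b`, `k`,
#'   `r_squared`, `n_points`, `n_excluded`, `strain_range`, `valid`, `reason`.
#' @examples
#' curve <- tibble::tibble(strain = seq(1.1, 2.5, by = 0.1))
#' curve$tension <- 5 * curve$strain^3
#' fit_power_law(curve)
#' @export
fit_power_law <- function(curve, min_tension = 0.05) {
  stopifnot(is.data.frame(curve), all(c("strain", "tension") %in% names(curve)))
  check_num(min_tension, "min_tension", lower = 0)
  keep <- curve$strain > 1 & curve$tension > min_tension &
    is.finite(curve$strain) & is.finite(curve$tension)
  used <- curve[keep, , drop = FALSE]
  n_excluded <- nrow(curve) - nrow(used)
  if (nrow(used) < 6) {
    return(structure(
      list(A = NA_real_, b = NA_real_, k = NA_real_, r_squared = NA_real_,
           n_points = nrow(used), n_excluded = n_excluded,
           strain_range = range(used$strain, na.rm = TRUE) |>
             (\(r) if (nrow(used)) r else c(NA_real_, NA_real_))(),
           valid = FALSE,
           reason = sprintf("only %d usable points (> 5 required)",
                            nrow(used))),
      class = "power_law_fit"
    ))
  }
  fit <- lm(log(tension) ~ log(strain), data = used)
  b <- unname(coef(fit)[1])
  k <- unname(coef(fit)[2])
  y <- log(used$tension)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(
    list(A = exp(b), b = b, k = k,
         r_squared = r2,
         n_points = nrow(used), n_excluded = n_excluded,
         strain_range = range(used$strain),
         valid = TRUE, reason = NA_character_),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<power_law_fit> invalid: %s\n", x$reason))
  } else {
    cat(sprintf(
      "<power_law_fit> T = A * strain^k;  A = %.4g mN/mm^2, k = %.4g, r^2 = %.4f (n = %d, excluded %d)\n",
      x$A, x$k, x$r_squared, x$n_points, x$n_excluded))
  }
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "b", "k"),
    estimate = c(x$A, x$b, x$k)
  )
}

#' @rdname fit_power_law
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, n_points = x$n_points,
    n_excluded = x$n_excluded,
    strain_min = x$strain_range[1], strain_max = x$strain_range[2],
    valid = x$valid, reason = x$reason
  )
}

#' Fit every cycle/direction curve of a trace
#'
#' Maps [fit_power_law()] over the `(cycle, direction)` groups of a curves
#' table. Lengthening curves are the primary fitting target (the tension
#' versus strain analysis is performed on lengthening data); shortening fits
#' are included when `direction = "both"`.
#'
#' @param curves Tibble from [build_cycle_curves()].
#' @param direction `"lengthen"`, `"shorten"`, or `"both"`.
#' @param min_tension Tension floor passed to [fit_power_law()].
#' @return A tibble with one row per fitted curve: `cycle`, `direction`, `A`,
#'   `b`, `k`, `r_squared`, `n_points`, `n_excluded`, `valid`, `reason`.
#' @export
fit_cycle_curves <- function(curves, direction = "lengthen",
                             min_tension = 0.05) {
  dirs <- if (direction == "both") c("lengthen", "shorten") else direction
  curves |>
    dplyr::filter(.data$direction %in% dirs) |>
    dplyr::group_by(.data$cycle, .data$direction) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_power_law(df, min_tension = min_tension)
      tibble::tibble(A = f$A, b = f$b, k = f$k, r_squared = f$r_squared,
                     n_points = f$n_points, n_excluded = f$n_excluded,
                     valid = f$valid, reason = f$reason)
    }) |>
    dplyr::ungroup()
}

#' Stiffness of a fitted power law at a given strain
#'
#' Stiffness is the derivative of the power law with respect to strain,
#' `A * k * lambda^(k - 1)`; at the reference length (`lambda = 1`) it equals
#' `A * k`.
#'
#' @param fit A `power_law_fit`, or any list/one-row data frame with elements
#'   `A` and `k`.
#' @param strain Strain(s) >= 1.
#' @return Stiffness in mN/mm^2 per unit strain.
#' @examples
#' stiffness_at(list(A = 5, k = 3), 1)  # 15
#' @export
stiffness_at <- function(fit, strain) {
  ak <- fit_ak(fit)
  if (any(strain < 1)) abort("stiffness is evaluated at strains >= 1")
  ak$A * ak$k * strain^(ak$k - 1)
}

fit_ak <- function(fit) {
  if (inherits(fit, "power_law_fit") && !isTRUE(fit$valid)) {
    abort(sprintf("cannot evaluate an invalid fit (%s)", fit$reason))
  }
  A <- fit[["A"]]
  k <- fit[["k"]]
  if (is.null(A) || is.null(k) || !is.finite(A) || !is.finite(k)) {
    abort("fit must provide finite `A` and `k`")
  }
  list(A = A, k = k)
}

#' Compliance curve
#'
#' Compliance is the pointwise reciprocal of stiffness. Given a power-law fit
#' it is evaluated analytically on the strain grid; given a raw
#' `(strain, tension)` curve, stiffness is first estimated by central finite
#' differences. Wherever stiffness is zero (e.g. the slack region of a
#' matrix-only cycle) the compliance is undefined: it is reported as `NA` with
#' `defined = FALSE`, an explicit marker rather than an infinite number. For a
#' power law with `k > 1`, compliance decreases monotonically with strain.
#'
#' @param x A `power_law_fit` (or list with `A`, `k`), or a data frame with
#'   `strain` and `tension` columns.
#' @param strain_grid Strains at which to evaluate (required for fits; ignored
#'   for raw curves, which use their own support).
#' @return A tibble with columns `strain`, `stiffness`, `compliance`,
#'   `defined`.
#' @export
compliance_curve <- function(x, strain_grid = NULL) {
  if (is.data.frame(x) && all(c("strain", "tension") %in% names(x))) {
    x <- x[order(x$strain), ]
    n <- nrow(x)
    if (n < 3) abort("need at least 3 curve points for finite differences")
    s <- x$strain
    tn <- x$tension
    stiff <- numeric(n)
    stiff[1] <- (tn[2] - tn[1]) / (s[2] - s[1])
    stiff[n] <- (tn[n] - tn[n - 1]) / (s[n] - s[n - 1])
    if (n > 2) {
      stiff[2:(n - 1)] <- (tn[3:n] - tn[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
    }
    grid <- s
  } else {
    if (is.null(strain_grid)) abort("strain_grid is required for a fitted model")
    grid <- strain_grid
    stiff <- stiffness_at(x, grid)
  }
  defined <- is.finite(stiff) & stiff > 0
  tibble::tibble(
    strain = grid, stiffness = stiff,
    compliance = ifelse(defined, 1 / stiff, NA_real_),
    defined = defined
  )
}

#' Subtract one cycle curve from another
#'
#' Computes the pointwise difference `curve_a - curve_b` on the strain overlap
#' of the two curves: `curve_b` is linearly interpolated onto `curve_a`'s
#' strain points within the overlap. This is the operation that isolates the
#' smooth-muscle contribution by removing the matrix-only (post-stretch) cycle
#' from the basal or agonist-induced cycle. Negative differences are permitted
#' and flagged.
#'
#' @param curve_a,curve_b Tibbles with `strain` and `tension` columns.
#' @return A tibble with columns `strain`, `tension` (the difference), and a
#'   scalar attribute `any_negative`.
#' @export
subtract_cycles <- function(curve_a, curve_b) {
  stopifnot(all(c("strain", "tension") %in% names(curve_a)),
            all(c("strain", "tension") %in% names(curve_b)))
  a <- curve_a[order(curve_a$strain), ]
  b <- curve_b[order(curve_b$strain), ]
  lo <- max(min(a$strain), min(b$strain))
  hi <- min(max(a$strain), max(b$strain))
  if (!(lo <= hi)) abort("curves have no overlapping strain support")
  a <- a[a$strain >= lo - 1e-12 & a$strain <= hi + 1e-12, ]
  if (nrow(a) == 0) abort("curves have no overlapping strain support")
  b_interp <- approx(b$strain, b$tension, xout = a$strain, rule = 1)$y
  out <- tibble::tibble(strain = a$strain, tension = a$tension - b_interp)
  attr(out, "any_negative") <- any(out$tension < 0)
  out
}

#' Locate the peak of a difference curve
#'
#' Finds the tension maximum of a (typically muscle-contribution) curve with
#' sub-grid resolution: a parabola is fit through the maximal point and its
#' two neighbours and its vertex returned. When the maximum sits on the curve
#' boundary the two adjacent interior points are used and the result is
#' flagged `boundary`. The vertex is only trusted within one grid step of the
#' maximal point (and only when the parabola is concave); otherwise the raw
#' grid maximum is returned with `refined = FALSE`. Ties break toward the
#' lower strain.
#'
#' @param curve A tibble with `strain` and `tension` columns (>= 3 points).
#' @return A one-row tibble: `peak_strain`, `peak_tension`, `boundary`,
#'   `refined`.
#' @export
find_peak <- function(curve) {
  stopifnot(all(c("strain", "tension") %in% names(curve)))
  curve <- curve[order(curve$strain), ]
  n <- nrow(curve)
  if (n < 3) abort("need at least 3 points to locate a peak")
  s <- curve$strain
  tn <- curve$tension
  i <- which.max(tn)  # which.max breaks ties toward the first (lower strain)
  boundary <- i == 1L || i == n
  idx <- if (i == 1L) 1:3 else if (i == n) (n - 2):n else (i - 1):(i + 1)
  x <- s[idx]
  y <- tn[idx]
  denom <- (y[1] - 2 * y[2] + y[3])
  h <- mean(diff(x))
  refined <- FALSE
  peak_strain <- s[i]
  peak_tension <- tn[i]
  if (is.finite(denom) && denom < 0) {
    vertex <- x[2] + 0.5 * h * (y[1] - y[3]) / denom
    # the three-point parabola is only trusted to sub-grid accuracy: its
    # vertex is clamped to within one grid step of the observed maximum
    peak_strain <- min(max(vertex, s[i] - h), s[i] + h)
    # evaluate the interpolating parabola at the (possibly clamped) vertex
    lag <- function(p) {
      y[1] * (p - x[2]) * (p - x[3]) / ((x[1] - x[2]) * (x[1] - x[3])) +
        y[2] * (p - x[1]) * (p - x[3]) / ((x[2] - x[1]) * (x[2] - x[3])) +
        y[3] * (p - x[1]) * (p - x[2]) / ((x[3] - x[1]) * (x[3] - x[2]))
    }
    peak_tension <- max(lag(peak_strain), tn[i])
    refined <- TRUE
  }
  tibble::tibble(peak_strain = peak_strain, peak_tension = peak_tension,
                 boundary = boundary, refined = refined)
}

#' Decompose strain cycles into muscle and matrix contributions
#'
#' Subtracts the matrix-only cycle from the basal cycle (basal muscle
#' contribution) and from the agonist-induced cycle (induced muscle
#' contribution), and locates each difference-curve peak. With the default
#' three-cycle protocol these are cycle 1 - cycle 2 and cycle 3 - cycle 2 on
#' the lengthening curves.
#'
#' @param curves Tibble from [build_cycle_curves()].
#' @param basal_cycle,ecm_cycle,induced_cycle Cycle indices. Set
#'   `induced_cycle = NULL` if no agonist cycle was recorded.
#' @param direction Curve direction used for the subtraction.
#' @return An object of class `cycle_decomposition`: a list with tibbles
#'   `muscle_basal`, `muscle_induced` and a `peaks` tibble (one row per
#'   component).
#' @export
decompose_cycles <- function(curves, basal_cycle = 1, ecm_cycle = 2,
                             induced_cycle = 3, direction = "lengthen") {
  ecm <- cycle_curve(curves, ecm_cycle, direction)
  basal <- subtract_cycles(cycle_curve(curves, basal_cycle, direction), ecm)
  comps <- list(basal = basal)
  if (!is.null(induced_cycle)) {
    comps$induced <- subtract_cycles(
      cycle_curve(curves, induced_cycle, direction), ecm)
  }
  peaks <- purrr::imap_dfr(comps, function(crv, nm) {
    dplyr::bind_cols(tibble::tibble(component = nm), find_peak(crv))
  })
  structure(
    list(muscle_basal = comps$basal,
         muscle_induced = comps$induced %||% NULL,
         peaks = peaks),
    class = "cycle_decomposition"
  )
}

#' @export
print.cycle_decomposition <- function(x, ...) {
  cat("<cycle_decomposition>\n")
  print(x$peaks)
  invisible(x)
}

#' @rdname decompose_cycles
#' @param x A `cycle_decomposition`.
#' @param ... Unused.
#' @export
tidy.cycle_decomposition <- function(x, ...) x$peaks

#' Compare stiffness exponents between two groups
#'
#' Unpaired, two-tailed pooled-variance t-test on the fitted exponent `k`
#' between two treatment groups. `k` is the comparison parameter of choice
#' because, unlike `A`, its value does not depend on an accurate measurement
#' of the reference length. Degenerate (zero-variance) inputs short-circuit to
#' an exact-equality comparison.
#'
#' @param data A data frame of per-strip fits.
#' @param k Column of exponent values (tidy-eval).
#' @param group Column of group labels (tidy-eval); exactly two levels.
#' @return A one-row tibble: `group1`, `group2`, `mean1`, `mean2`,
#'   `difference` (`mean1 - mean2`), `statistic`, `df`, `p_value`, `method`.
#' @examples
#' df <- tibble::tibble(k = c(6.1, 5.9, 6.2, 9.0, 9.1, 8.8),
#'                      arm = rep(c("vehicle", "cocktail"), each = 3))
#' compare_k(df, k, arm)
#' @export
compare_k <- function(data, k, group) {
  kq <- enquo(k)
  gq <- enquo(group)
  kv <- dplyr::pull(data, !!kq)
  gv <- as.character(dplyr::pull(data, !!gq))
  levels <- unique(gv)
  if (length(levels) != 2) abort("exactly two groups are required")
  x <- kv[gv == levels[1]]
  y <- kv[gv == levels[2]]
  if (length(x) < 2 || length(y) < 2) {
    abort("at least two values per group are required")
  }
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    # all within-group variation is zero: exact-equality fast path
    diff <- mean(x) - mean(y)
    return(tibble::tibble(
      group1 = levels[1], group2 = levels[2],
      mean1 = mean(x), mean2 = mean(y), difference = diff,
      statistic = if (diff == 0) 0 else Inf * sign(diff),
      df = length(x) + length(y) - 2,
      p_value = if (diff == 0) 1 else 0,
      method = "exact equality (degenerate variance)"
    ))
  }
  tt <- t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  tibble::tibble(
    group1 = levels[1], group2 = levels[2],
    mean1 = mean(x), mean2 = mean(y), difference = mean(x) - mean(y),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, method = "unpaired two-tailed t-test"
  )
}
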