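#' Worm-like-chain spring parameters
#'
#' Bundles the physical constants of one entropic spring: the persistence
#' length of a chain unit, the thermal energy, the number of chain units and
#' the contour length derived from them. Defaults describe a 16-residue
#' unfolded polypeptide linker at room temperature, the configuration of the
#' MthK bundle-crossing-to-RCK-ring linker (Ile99 to Ser115).
#'
#' @param n_units number of chain units (residues) in the spring; >= 1.
#' @param persistence_length persistence length of one unit, nm. The value
#'   0.38 nm is the consensus from polypeptide force-spectroscopy stretching
#'   experiments.
#' @param thermal_energy thermal energy kT, pN nm. Ignored when
#'   `temperature` is given.
#' @param temperature optional absolute temperature in Kelvin; when supplied,
#'   `thermal_energy` is computed as 0.0138065 * temperature pN nm.
#'
#' @return An object of class `"wlc_params"`: a list with fields
#'   `n_units`, `persistence_length` (nm), `thermal_energy` (pN nm) and
#'   `contour_length` (nm, = n_units * persistence_length).
#' @examples
#' wlc_params()                  # the canonical 16-residue linker
#' wlc_params(n_units = 13)      # a 3-residue-shortened linker
#' wlc_params(temperature = 298)
#' @export
wlc_params <- function(n_units = 16, persistence_length = 0.38,
                       thermal_energy = 4.114, temperature = NULL) {
  if (!is.null(temperature)) {
    if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
      stop("`temperature` must be a single positive number (Kelvin)")
    thermal_energy <- 0.0138065 * temperature
  }
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 1 ||
      n_units != round(n_units))
    stop("`n_units` must be a single integer >= 1")
  if (!is.numeric(persistence_length) || length(persistence_length) != 1L ||
      persistence_length <= 0)
    stop("`persistence_length` must be a single positive number (nm)")
  if (!is.numeric(thermal_energy) || length(thermal_energy) != 1L ||
      thermal_energy <= 0)
    stop("`thermal_energy` must be a single positive number (pN nm)")
  structure(list(
    n_units            = as.integer(n_units),
    persistence_length = persistence_length,
    thermal_energy     = thermal_energy,
    contour_length     = contour_length(n_units, persistence_length)
  ), class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat("Worm-like-chain spring parameters\n")
  cat(sprintf("  chain units        : %d\n", x$n_units))
  cat(sprintf("  persistence length : %.3f nm\n", x$persistence_length))
  cat(sprintf("  thermal energy kT  : %.3f pN nm\n", x$thermal_energy))
  cat(sprintf("  contour length     : %.3f nm (%.1f Angstrom)\n",
              x$contour_length, 10 * x$contour_length))
  invisible(x)
}

#' Contour length of a chain
#'
#' Maximum backbone extension of the spring: the number of chain units times
#' the persistence length of one unit.
#'
#' @param n_units number of chain units; >= 1.
#' @param persistence_length persistence length per unit, nm.
#' @return Contour length in nm.
#' @examples
#' contour_length(16, 0.38)  # 6.08 nm
#' @export
contour_length <- function(n_units, persistence_length = 0.38) {
  if (any(n_units < 1) || any(persistence_length <= 0))
    stop("contour_length: n_units must be >= 1 and persistence_length > 0")
  n_units * persistence_length
}

# convert an extension to nm; `unit` is "A" (Angstrom, the structural
# convention) or "nm"
.ext_to_nm <- function(x, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  if (unit == "A") x / 10 else x
}

# validate extension(s) against the contour length; returns x in nm with a
# logical "near_contour" attribute flagging values beyond 98% of Lc
.check_extension <- function(x, params, unit) {
  stopifnot(inherits(params, "wlc_params"))
  x_nm <- .ext_to_nm(x, unit)
  if (any(x_nm < 0)) stop("extension must be >= 0")
  if (any(x_nm >= params$contour_length))
    stop(sprintf(
      "extension (%.3f nm) reaches the contour length (%.3f nm): force diverges",
      max(x_nm), params$contour_length))
  near <- x_nm > 0.98 * params$contour_length
  if (any(near))
    warning("extension within 2% of the contour length; force is near-divergent")
  attr(x_nm, "near_contour") <- near
  x_nm
}

#' Worm-like-chain force at a given extension
#'
#' Marko-Siggia interpolation for the entropic restoring force of a
#' semiflexible chain stretched to end-to-end extension x:
#' \deqn{F = (k_BT/l_p)\,[\tfrac14 (1 - x/L_C)^{-2} + x/L_C - \tfrac14].}
#' The force is zero at zero extension, strictly increasing, and diverges as
#' the extension approaches the contour length.
#'
#' @param x extension(s); Angstrom by default (see `unit`).
#' @param params a [wlc_params()] object.
#' @param unit unit of `x`: `"A"` (Angstrom, default) or `"nm"`.
#' @return Force(s) in pN, with attribute `near_contour` (logical) flagging
#'   extensions beyond 98% of the contour length.
#' @examples
#' wlc_force(36.2)   # ~20.3 pN, the highly stretched outlier linker
#' wlc_force(0)      # 0 pN
#' @export
wlc_force <- function(x, params = wlc_params(), unit = c("A", "nm")) {
  x_nm <- .check_extension(x, params, unit)
  r <- x_nm / params$contour_length
  f <- (params$thermal_energy / params$persistence_length) *
    (0.25 * (1 - r)^-2 + r - 0.25)
  attr(f, "near_contour") <- attr(x_nm, "near_contour")
  f
}

#' Elastic energy stored stretching a worm-like chain
#'
#' Closed-form integral of the Marko-Siggia force between two extensions,
#' reported as a positive stretching energy in units of kT. The energy stored
#' loading the spring from `x_from` to `x_to` (with `x_to >= x_from`) is
#' \deqn{U/k_BT = (L_C/l_p)\,[\tfrac14(\tfrac{1}{1-x_2/L_C} -
#'   \tfrac{1}{1-x_1/L_C}) + \tfrac{x_2^2 - x_1^2}{2 L_C^2} -
#'   \tfrac14 \tfrac{x_2 - x_1}{L_C}].}
#' It is additive over subintervals and zero on a degenerate interval.
#'
#' @param x_from lower extension bound(s).
#' @param x_to upper extension bound(s); must satisfy `x_to >= x_from`.
#' @inheritParams wlc_force
#' @return Energy in multiples of kT (dimensionless).
#' @examples
#' wlc_energy(0, 29.4)     # ~3.7 kT stored in a mean open-state linker
#' wlc_energy(29.1, 36.2)  # ~2.7 kT excess in the stretched outlier
#' @export
wlc_energy <- function(x_from, x_to, params = wlc_params(), unit = c("A", "nm")) {
  a <- .check_extension(x_from, params, unit)
  b <- .check_extension(x_to, params, unit)
  if (any(b - a < 0)) stop("wlc_energy: x_to must be >= x_from")
  lc <- params$contour_length
  antider <- function(x) {   # indefinite integral of the bracket, in kT units
    r <- x / lc
    (lc / params$persistence_length) *
      (0.25 / (1 - r) + 0.5 * r^2 - 0.25 * r)
  }
  as.numeric(antider(b) - antider(a))
}

#' Worm-like-chain spring constant at a given extension
#'
#' Local stiffness, the derivative of the Marko-Siggia force with respect to
#' extension:
#' \deqn{k = (k_BT/l_p)\,[\tfrac{1}{2 L_C}(1 - x/L_C)^{-3} + 1/L_C].}
#' Strictly positive and increasing in the extension; at zero extension it
#' reduces to the entropic-coil value 3 kT / (2 l_p L_C).
#'
#' @inheritParams wlc_force
#' @return Stiffness in pN/nm.
#' @examples
#' wlc_stiffness(29.1)  # ~8.1 pN/nm at the canonical open-state length
#' @export
wlc_stiffness <- function(x, params = wlc_params(), unit = c("A", "nm")) {
  x_nm <- .check_extension(x, params, unit)
  r <- x_nm / params$contour_length
  k <- (params$thermal_energy / params$persistence_length) *
    (0.5 / params$contour_length * (1 - r)^-3 + 1 / params$contour_length)
  attr(k, "near_contour") <- attr(x_nm, "near_contour")
  k
}

#' Extension producing a given worm-like-chain force
#'
#' Inverts the Marko-Siggia force-extension relation by bracketed root
#' finding; monotonicity of the force guarantees a unique solution in
#' [0, contour length).
#'
#' @param target_force force(s) in pN; must be >= 0.
#' @param params a [wlc_params()] object.
#' @param unit unit of the returned extension: `"A"` (default) or `"nm"`.
#' @return Extension(s) with `wlc_force(x) == target_force` to 1e-9 pN.
#' @examples
#' wlc_inverse_force(20.3)  # ~36.2 Angstrom
#' @export
wlc_inverse_force <- function(target_force, params = wlc_params(),
                              unit = c("A", "nm")) {
  unit <- match.arg(unit)
  if (any(target_force < 0)) stop("target_force must be >= 0")
  lc <- params$contour_length
  solve1 <- function(f) {
    if (f == 0) return(0)
    # shrink the upper bracket away from the divergence until it encloses f
    hi <- lc * (1 - 1e-12)
    g <- function(x) {
      r <- x / lc
      (params$thermal_energy / params$persistence_length) *
        (0.25 * (1 - r)^-2 + r - 0.25) - f
    }
    stats::uniroot(g, lower = 0, upper = hi, tol = 1e-13)$root
  }
  x_nm <- vapply(target_force, solve1, numeric(1))
  if (unit == "A") 10 * x_nm else x_nm
}
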