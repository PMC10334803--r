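#' Gating free energy from an open probability
#'
#' Two-state Boltzmann relation between a single-channel open probability
#' and the closed-open free-energy difference:
#' `dG = -ln(P_O / (1 - P_O))` in units of kT. Negative values favour the
#' open state; `P_O = 0.5` maps to zero.
#'
#' @param p_open open probability, strictly inside (0, 1); vectorized.
#' @return An object of class `"thermo_result"`: list with `delta_g` (kT)
#'   and the echoed `inputs`.
#' @examples
#' delta_g_from_open_probability(0.994)    # about -5.1 kT
#' delta_g_from_open_probability(0.0001)   # about +9.2 kT
#' @export
delta_g_from_open_probability <- function(p_open) {
  if (any(p_open <= 0 | p_open >= 1))
    stop("p_open must lie strictly inside (0, 1)")
  structure(list(delta_g = -log(p_open / (1 - p_open)),
                 inputs = list(p_open = p_open)),
            class = "thermo_result")
}

#' Open probability from a gating free energy
#'
#' Inverse of [delta_g_from_open_probability()]:
#' `P_O = 1 / (1 + exp(dG))` with `dG` in kT.
#'
#' @param delta_g free-energy difference in kT; vectorized.
#' @return Open probability in (0, 1).
#' @export
open_probability_from_delta_g <- function(delta_g) {
  1 / (1 + exp(delta_g))
}

#' Ligand-binding free energy from a dissociation constant
#'
#' Standard-state (1 M) binding free energy per site,
#' `|dG0| = ln(1 / K_D)` in kT for `K_D` in molar, and the total over
#' `n_sites` independent sites. This bounds the energy that ligand binding
#' can deliver to gating; for MthK, six calcium ions at `K_D` ~ 1 mM give
#' about 41 kT.
#'
#' @param kd dissociation constant in molar; > 0.
#' @param n_sites number of binding sites; >= 1.
#' @return An object of class `"thermo_result"`: list with `per_site` (kT),
#'   `total` (kT), `delta_g` (the signed standard free energy of binding,
#'   `-per_site * n_sites`) and the echoed `inputs`.
#' @examples
#' binding_energy_from_kd(1e-3, n_sites = 6)  # ~41.4 kT total
#' @export
binding_energy_from_kd <- function(kd, n_sites = 1) {
  if (any(kd <= 0)) stop("kd must be positive (molar)")
  if (any(n_sites < 1)) stop("n_sites must be >= 1")
  per_site <- log(1 / kd)
  structure(list(per_site = per_site, total = n_sites * per_site,
                 delta_g = -n_sites * per_site,
                 inputs = list(kd = kd, n_sites = n_sites)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  if (!is.null(x$delta_g) && is.null(x$per_site)) {
    cat(sprintf("delta G = %s kT (P_O = %s)\n",
                paste(sprintf("%.2f", x$delta_g), collapse = ", "),
                paste(format(x$inputs$p_open), collapse = ", ")))
  } else {
    cat(sprintf(
      "binding energy: %.2f kT per site, %.2f kT total (%d site(s), K_D = %g M)\n",
      x$per_site[1], x$total[1], x$inputs$n_sites[1], x$inputs$kd[1]))
  }
  invisible(x)
}
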