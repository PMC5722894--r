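#' @title Internal unit system and physical constants
#'
#' @description
#' All mechanics inside the package is computed in a molecular unit system:
#' length in Angstrom, energy in kcal/mol, force in kcal/(mol*Angstrom) and
#' stress/modulus in kcal/(mol*Angstrom^3).  Inputs are accepted in the units
#' the literature uses (Pa for moduli, mN/m for membrane tension) and
#' converted at the boundary by the helpers below, so no scattered magic
#' factors appear in element routines.
#'
#' Conversion anchor: 1 kcal/(mol*A^3) = 6.9477e9 Pa (from
#' 1 kcal/mol = 6.9477e-21 J and 1 A = 1e-10 m).
#' @name bundlegate-units
NULL

## CODATA 2018 exact constants
.const <- list(
  N_A     = 6.02214076e23,    # 1/mol
  e_C     = 1.602176634e-19,  # C
  eps0    = 8.8541878128e-12, # F/m
  k_B     = 1.380649e-23,     # J/K
  kcal_J  = 4184,             # J per kcal
  coulomb_kcalA = 332.06      # kcal*A/(mol*e^2), Coulomb constant
)

## 1 kcal/mol expressed in J, per molecule
.kcalmol_J <- .const$kcal_J / .const$N_A   # 6.9477e-21 J

#' Convert a modulus or stress from Pa to kcal/(mol*Angstrom^3)
#' @param pa numeric, Pa
#' @return numeric, kcal/(mol*A^3)
#' @export
pa_to_internal <- function(pa) pa * 1e-30 / .kcalmol_J

#' Convert kcal/(mol*Angstrom^3) to Pa
#' @param x numeric, internal stress units
#' @return numeric, Pa
#' @export
internal_to_pa <- function(x) x * .kcalmol_J / 1e-30

#' Convert a membrane tension from mN/m to kcal/(mol*Angstrom^2)
#'
#' Membrane tension is a force per unit length; internally it becomes
#' kcal/(mol*A) per Angstrom of edge.
#' @param mn_per_m numeric, mN/m
#' @return numeric, kcal/(mol*A^2)
#' @export
tension_to_internal <- function(mn_per_m) {
  # mN/m -> N/m -> N/A -> internal force/A
  mn_per_m * 1e-3 * 1e-10 / (.kcalmol_J / 1e-10)
}

#' Membrane tension to equivalent edge stress
#'
#' Divides a membrane tension (force per unit length) by the bilayer
#' thickness to give the equivalent in-plane edge stress, the conversion the
#' gating literature quotes as, e.g., 9.5 mN/m == 2.63 MPa for an effective
#' thickness near 36 A.
#'
#' @param tension membrane tension, mN/m; must be finite and >= 0
#' @param thickness bilayer thickness, Angstrom; must be > 0
#' @return equivalent stress in Pa
#' @examples
#' tension_to_stress(9.5, 36.1)  # ~2.63e6 Pa
#' @export
tension_to_stress <- function(tension, thickness) {
  stop_if_not(is.numeric(tension), length(tension) == 1L, is.finite(tension),
              msg = "'tension' must be a single finite number")
  stop_if_not(tension >= 0, msg = "'tension' must be >= 0")
  stop_if_not(is.numeric(thickness), length(thickness) == 1L,
              is.finite(thickness), thickness > 0,
              msg = "'thickness' must be a single positive number")
  (tension * 1e-3) / (thickness * 1e-10)
}

## small internal assertion helper: all ... must be TRUE
stop_if_not <- function(..., msg) {
  ok <- vapply(list(...), function(x) isTRUE(all(x)), logical(1))
  if (!all(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
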