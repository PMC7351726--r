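# Physical constants and frozen lookup tables.

#' Thermodynamic constants for dock-score / K_i / IC50 conversions
#'
#' Bundles the gas constant and the two temperature conventions used by the
#' analysis: `T_dock` for back-converting predicted inhibition constants from
#' docking scores (the docking-engine convention, 298.15 K) and `T_exp` for
#' the IC50-derived experimental binding free energy (300 K).
#'
#' @param R_kcal Gas constant in kcal K^-1 mol^-1.
#' @param T_dock Temperature (K) used for the K_i,pred <-> dock-score relation.
#' @param T_exp Temperature (K) used for Delta G_exp = R T ln(IC50 in mol/L).
#' @return An object of class `"thermo_constants"`.
#' @examples
#' tc <- thermo_constants()
#' tc$R_kcal * tc$T_exp  # RT at the experimental convention, kcal/mol
#' @export
thermo_constants <- function(R_kcal = 1.987e-3, T_dock = 298.15, T_exp = 300) {
  stopifnot(is.numeric(R_kcal), R_kcal > 0,
            is.numeric(T_dock), T_dock > 0,
            is.numeric(T_exp), T_exp > 0)
  structure(list(R_kcal = R_kcal, T_dock = T_dock, T_exp = T_exp),
            class = "thermo_constants")
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("Thermodynamic constants:\n")
  cat(sprintf("  R      = %g kcal K^-1 mol^-1\n", x$R_kcal))
  cat(sprintf("  T_dock = %g K (K_i,pred convention)\n", x$T_dock))
  cat(sprintf("  T_exp  = %g K (IC50 -> Delta G_exp)\n", x$T_exp))
  invisible(x)
}

# Standard atomic weights (IUPAC conventional values), g/mol.
.ATOMIC_WEIGHTS <- c(
  H = 1.008,   He = 4.0026,  B = 10.81,    C = 12.011,  N = 14.007,
  O = 15.999,  F = 18.99840, Na = 22.98977, Mg = 24.305, Si = 28.085,
  P = 30.97376, S = 32.06,   Cl = 35.45,   K = 39.0983, Ca = 40.078,
  Br = 79.904, I = 126.90447
)

# Unit conversions and simulation constants (GROMACS-style units:
# kJ/mol, nm, ps, amu, elementary charge).
.KJ_PER_KCAL <- 4.184
.KB_KJ <- 0.008314462618        # Boltzmann constant, kJ mol^-1 K^-1
.COULOMB_KJ <- 138.935458       # 1/(4 pi eps0), kJ mol^-1 nm e^-2
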