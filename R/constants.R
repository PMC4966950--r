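#' Physical constants and unit bridges
#'
#' All internal computation uses nm, ps, amu and kelvin. In these units the
#' energy unit amu nm^2 ps^-2 equals 1 kJ/mol, so the Boltzmann constant is
#' numerically R/1000. The table below is the single audited source of
#' constants used across the package (entropy, diffusion correction,
#' concentration arithmetic).
#'
#' @format A named list:
#' \describe{
#'   \item{kB_J}{Boltzmann constant, J/K}
#'   \item{kB}{Boltzmann constant, amu nm^2 ps^-2 K^-1 (= kJ/mol/K)}
#'   \item{hbar}{reduced Planck constant, amu nm^2 ps^-1}
#'   \item{R_gas}{molar gas constant, J/(mol K)}
#'   \item{avogadro}{Avogadro constant, 1/mol}
#'   \item{amu_g}{one atomic mass unit in grams}
#'   \item{nm3_L}{one nm^3 in litres}
#' }
#' @export
md_constants <- local({
  kB_J <- 1.380649e-23
  avogadro <- 6.02214076e23
  amu_kg <- 1.66053906660e-27
  # 1 amu nm^2 ps^-2 in joules
  e_int_J <- amu_kg * 1e-18 / 1e-24
  list(
    kB_J = kB_J,
    kB = kB_J / e_int_J,                      # 0.00831446... amu nm^2 ps^-2 / K
    hbar = 1.054571817e-34 / (e_int_J * 1e-12),  # amu nm^2 / ps
    R_gas = kB_J * avogadro,
    avogadro = avogadro,
    amu_g = amu_kg * 1e3,
    nm3_L = 1e-24
  )
})

# default atomic masses (amu) by element symbol
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, X = 12.011
)

# Bondi van der Waals radii (nm) by element; fallback handled in sasa()
.bondi_radii <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
  P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198,
  SE = 0.190, ZN = 0.139, FE = 0.156
)
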