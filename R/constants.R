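# Physical constants (CODATA 2018), SI unless noted.
.const <- list(
  e_charge_C     = 1.602176634e-19,   # elementary charge
  m_e_kg         = 9.1093837015e-31,  # electron mass
  m_e_c2_MeV     = 0.51099895,        # electron rest energy
  c_m_s          = 2.99792458e8,      # speed of light
  eps0_F_m       = 8.8541878128e-12,  # vacuum permittivity
  N_A            = 6.02214076e23,     # Avogadro constant
  MeV_per_g_to_Gy = 1.602176634e-10   # 1 MeV/g = 1.602e-13 J / 1e-3 kg
)

#' Molecular yield conversion constant
#'
#' One species per 100 eV of absorbed energy corresponds to
#' `1/(100 e N_A)` mol/J; in water (1 Gy = 1 J/kg = 1 J/L) this is
#' 0.10364 uM/Gy. Exposed because the radiolysis yield surrogate is
#' linear in this constant.
#'
#' @return Scalar, uM/Gy per (species / 100 eV).
#' @export
#' @examples
#' uM_per_Gy_per_G() # 0.10364
uM_per_Gy_per_G <- function() {
  1e6 / (100 * .const$e_charge_C * .const$N_A)
}
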