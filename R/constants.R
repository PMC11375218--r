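# Physical constants (SI 2019 exact values where defined)
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  Nav  = 6.02214076e23      # Avogadro constant, 1/mol
)

# mol/L -> number density in nm^-3
.molar_to_nm3 <- function(c) c * .const$Nav * 1e-24
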