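# Physical constants (CODATA 2018) and unit conversions.
# Internal length unit: nm; density: nm^-3; pressure I/O: kPa.

.AVOGADRO <- 6.02214076e23   # mol^-1
.R_GAS    <- 8.314462618     # J mol^-1 K^-1

# 1 nm^-3 = 1e27 m^-3 = 1e27/N_A mol m^-3 = 1660.539067 mol m^-3
.MOL_M3_PER_NM3 <- 1e27 / .AVOGADRO

# kPa per (nm^-3) of ideal solute at temperature T [K]
.kpa_per_density <- function(temperature) {
  .MOL_M3_PER_NM3 * .R_GAS * temperature / 1000
}
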