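# Physical constants (SI 2019 exact values where defined)
.avogadro <- 6.02214076e23          # 1/mol
.e_charge <- 1.602176634e-19        # C
.eps0     <- 8.8541878128e-12       # F/m
.kboltz   <- 1.380649e-23           # J/K
.r_gas_kj <- 8.31446261815324e-3    # kJ/mol/K

# e^2 * NA / (4 pi eps0), in kJ A / mol -- divide by eps_r and r (A) for a
# Coulomb pair energy in kJ/mol
.coulomb_kj_A <- .e_charge^2 * .avogadro / (4 * pi * .eps0) * 1e10 * 1e-3

# Average residue masses (Da); residue = amino acid minus one water
.residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153
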