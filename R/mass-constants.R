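# Residue mass tables (Da). "Residue" masses are for the dehydrated residue
# within a chain; a free peptide adds one water. Monoisotopic values follow
# the most-abundant-isotope atomic masses; average values the standard
# atomic weights. Each constant is unit-tested against an elemental-
# composition oracle.

MONO_WATER <- 18.010565
AVG_WATER <- 18.01528
PROTON_MASS <- 1.007276

MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

# Modification mass deltas (Da, monoisotopic)
MOD_DELTAS <- c(
  oxidation = 15.994915,   # +O on Met
  pyroglu = -17.026549,    # N-terminal Gln -> pyroglutamate (-NH3)
  acetyl = 42.010565       # protein N-terminal acetylation (+C2H2O)
)
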