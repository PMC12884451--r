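# Physical constants (CODATA 2018), centralized so every module shares one
# set of unit conventions: lengths in Angstrom, energies in meV, potentials
# in V, rates in 1/s, times in fs unless stated otherwise.

#' Physical constants used throughout the package
#'
#' @format A named list:
#' \describe{
#'   \item{k_coulomb}{Coulomb constant, 14.3996 V A / e.}
#'   \item{kB_meV}{Boltzmann constant, meV / K.}
#'   \item{hbar_meV_s}{Reduced Planck constant, meV s.}
#'   \item{hbar_meV_fs}{Reduced Planck constant, meV fs.}
#'   \item{rho0_water}{Bulk water number density at 298 K, molecules / A^3.}
#'   \item{T_default}{Default temperature, K.}
#' }
#' @export
#' @examples
#' quad_constants$kB_meV * 298  # ~25.68 meV
quad_constants <- list(
  k_coulomb   = 14.3996,          # V * Angstrom / e
  kB_meV      = 8.617333262e-2,   # meV / K
  hbar_meV_s  = 6.582119569e-13,  # meV * s
  hbar_meV_fs = 6.582119569e2,    # meV * fs
  rho0_water  = 0.0334,           # molecules / A^3, bulk water 298 K
  T_default   = 298
)

#' Thermal energy k_B T in meV
#'
#' @param T_K temperature in kelvin.
#' @return k_B T in meV (25.68 meV at 298 K).
#' @export
kT_meV <- function(T_K = quad_constants$T_default) {
  stopifnot(T_K > 0)
  quad_constants$kB_meV * T_K
}

# Canonical labels and pair conventions of the quadruplex. Sites are two
# tryptophans per chain (residues 122/124, chains A and D); the six pairs
# split into intramolecular "sides", interfacial "edges" and two diagonals.
QUAD_SITES <- c("124A", "122A", "122D", "124D")

QUAD_PAIR_KIND <- data.frame(
  a    = c("124A", "122D", "124A", "122A", "122D", "124A"),
  b    = c("122A", "124D", "122D", "124D", "122A", "124D"),
  kind = c("side", "side", "edge", "edge", "diagonal", "diagonal"),
  stringsAsFactors = FALSE
)

STATE_LABELS <- c("GS", "MLCT", "124A+", "122A+", "122D+", "124D+")

# Map an oxidized-state label to its site label ("124A+" -> "124A").
state_site <- function(state) sub("\\+$", "", state)

#' Pair class (side/edge/diagonal) of two quadruplex sites
#'
#' The intramolecular pairs 124A-122A and 122D-124D are "sides", the
#' interfacial pairs 124A-122D and 122A-124D are "edges", and 122D-122A /
#' 124A-124D are the short and long "diagonals".
#'
#' @param a,b site labels among `"124A"`, `"122A"`, `"122D"`, `"124D"`.
#' @return `"side"`, `"edge"` or `"diagonal"`.
#' @export
#' @examples
#' pair_kind("124A", "122D")  # "edge"
pair_kind <- function(a, b) {
  stopifnot(a %in% QUAD_SITES, b %in% QUAD_SITES, a != b)
  hit <- (QUAD_PAIR_KIND$a == a & QUAD_PAIR_KIND$b == b) |
    (QUAD_PAIR_KIND$a == b & QUAD_PAIR_KIND$b == a)
  QUAD_PAIR_KIND$kind[hit]
}

# Heavy C/N atoms of the indole ring; CB and all backbone atoms are
# deliberately excluded from every distance in this package.
INDOLE_ATOMS <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")

# Cofactor residue names recognized by the cluster miner.
COFACTOR_RESNAMES <- c("FAD", "FMN", "HEM", "HEC", "FE", "FES", "SF4",
                       "NAD", "NAI", "NAP")
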