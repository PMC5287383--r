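# Monoisotopic mass table. Residue masses are free monosaccharide minus water
# (IUPAC 2021 atomic masses); sulfate is SO3 attached without water loss.
# Charged-species arithmetic uses the proton mass for hydrogen transfers; the
# electron mass is ignored (< 0.6 ppm at m/z 1000, below the 10 ppm working
# tolerance). Cation masses are Na+ and K+ less one electron, same convention.

.RESIDUE_MASSES <- c(
  Hex    = 162.052824,  # C6H10O5
  HexNAc = 203.079373,  # C8H13NO5
  Fuc    = 146.057909,  # C6H10O4, generic deoxyhexose
  Neu5Ac = 291.095417,  # C11H17NO8
  Neu5Gc = 307.090331,  # C11H17NO9
  S      =  79.956815   # SO3
)

.MASS_WATER  <- 18.010565
.MASS_PROTON <-  1.00728
.MASS_NA     <- 22.98922
.MASS_K      <- 38.96316

.RESIDUES     <- names(.RESIDUE_MASSES)
.SUGAR_RESIDUES <- setdiff(.RESIDUES, "S")

# Canonical three-arm cohort design: senescence-resistant control strain,
# senescence-accelerated model strain, and the treated model strain.
.GROUP_LEVELS <- c("control", "model", "treated")

# package-level cache (composition lattices keyed by count bounds)
.glyco_cache <- new.env(parent = emptyenv())

#' Monoisotopic mass constants used throughout the package
#'
#' Returns the residue-mass alphabet (Hex, HexNAc, Fuc as generic deoxyhexose,
#' Neu5Ac, Neu5Gc, and `S` for sulfate as SO3) together with the water,
#' proton, sodium and potassium masses used in ion m/z arithmetic. The table
#' is a copy; the internal constants are immutable.
#'
#' @return A list with elements `residues` (named numeric vector, Da),
#'   `water`, `proton`, `sodium`, `potassium` (Da).
#' @examples
#' glyco_masses()$residues[["Hex"]]
#' @export
glyco_masses <- function() {
  list(
    residues  = .RESIDUE_MASSES,
    water     = .MASS_WATER,
    proton    = .MASS_PROTON,
    sodium    = .MASS_NA,
    potassium = .MASS_K
  )
}

#' Canonical cohort group labels
#'
#' The three-group design used by the quantification and comparison stages:
#' `"control"` (control strain), `"model"` (disease-model strain) and
#' `"treated"` (treated model strain).
#'
#' @return Character vector of length 3.
#' @export
group_levels <- function() .GROUP_LEVELS
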