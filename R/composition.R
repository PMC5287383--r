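#' Glycan composition
#'
#' A glycan composition is a count vector over the monosaccharide classes
#' Hex, HexNAc, Fuc (deoxyhexose), Neu5Ac, Neu5Gc plus a sulfate count.
#' Compositions carry no linkage or branching information. At least one
#' non-sulfate residue count must be positive.
#'
#' @param Hex,HexNAc,Fuc,Neu5Ac,Neu5Gc,S Non-negative integer counts.
#' @return An object of class `glycan_composition` (named integer vector).
#' @examples
#' glycan_composition(Hex = 5, HexNAc = 2)
#' @seealso [parse_composition()], [format_composition()],
#'   [neutral_monoisotopic_mass()]
#' @export
glycan_composition <- function(Hex = 0, HexNAc = 0, Fuc = 0,
                               Neu5Ac = 0, Neu5Gc = 0, S = 0) {
  counts <- c(Hex = Hex, HexNAc = HexNAc, Fuc = Fuc,
              Neu5Ac = Neu5Ac, Neu5Gc = Neu5Gc, S = S)
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("invalid composition: counts must be non-missing numbers")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("invalid composition: counts must be non-negative integers")
  }
  if (sum(counts[.SUGAR_RESIDUES]) == 0) {
    stop("invalid composition: at least one non-sulfate residue is required")
  }
  structure(as.integer(round(counts)), names = .RESIDUES,
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition>", format_composition(x), "\n")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) format_composition(x)

#' Render a composition in canonical table notation
#'
#' Residues are listed in the fixed order Hex, HexNAc, Fuc, Neu5Ac, Neu5Gc,
#' then `S<n>` for sulfate, omitting zero-count classes, e.g.
#' `"(Hex)3(HexNAc)5(Fuc)1(Neu5Ac)1"` or `"(Hex)3(HexNAc)6S1"`.
#' `parse_composition()` inverts this rendering exactly.
#'
#' @param comp A [glycan_composition()].
#' @return A single string.
#' @export
format_composition <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  parts <- character(0)
  for (res in .SUGAR_RESIDUES) {
    if (comp[[res]] > 0) parts <- c(parts, sprintf("(%s)%d", res, comp[[res]]))
  }
  if (comp[["S"]] > 0) parts <- c(parts, sprintf("S%d", comp[["S"]]))
  paste(parts, collapse = "")
}

# residue-name aliases accepted on input (the published tables abbreviate
# Neu5Ac/Neu5Gc as NeuAc/NeuGc in places)
.RESIDUE_ALIASES <- c(
  Hex = "Hex", HexNAc = "HexNAc", Fuc = "Fuc", dHex = "Fuc",
  Neu5Ac = "Neu5Ac", NeuAc = "Neu5Ac", Neu5Gc = "Neu5Gc", NeuGc = "Neu5Gc",
  S = "S", Sulfate = "S"
)

#' Parse a composition string
#'
#' Accepts the `"(Residue)count"` grammar of the published tables with an
#' optional `S<count>` sulfate suffix. Residue tokens may appear in any
#' order; `NeuAc`/`NeuGc` are accepted as aliases for Neu5Ac/Neu5Gc.
#' Zero counts and unknown residues are rejected with an error naming the
#' offending token. `parse_composition(format_composition(x))` is the
#' identity.
#'
#' @param text A single composition string.
#' @return A [glycan_composition()].
#' @examples
#' parse_composition("(Hex)3(HexNAc)5(Fuc)1(Neu5Ac)1")
#' parse_composition("(Hex)3(HexNAc)6S1")
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("composition parse error: input must be a single string")
  }
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) stop("composition parse error: empty string")
  token_re <- "\\(([A-Za-z0-9]+)\\)([0-9]+)|([A-Za-z]+)([0-9]+)"
  m <- gregexpr(token_re, s, perl = TRUE)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (m[1] == -1 || paste(tokens, collapse = "") != s) {
    stop(sprintf("composition parse error: cannot parse '%s'", text))
  }
  counts <- stats::setNames(integer(length(.RESIDUES)), .RESIDUES)
  for (tok in tokens) {
    if (startsWith(tok, "(")) {
      res <- sub("^\\(([A-Za-z0-9]+)\\)[0-9]+$", "\\1", tok)
      n <- as.integer(sub("^\\([A-Za-z0-9]+\\)([0-9]+)$", "\\1", tok))
    } else {
      res <- sub("^([A-Za-z]+)[0-9]+$", "\\1", tok)
      n <- as.integer(sub("^[A-Za-z]+([0-9]+)$", "\\1", tok))
    }
    if (!res %in% names(.RESIDUE_ALIASES)) {
      stop(sprintf("composition parse error: unknown residue token '%s'", res))
    }
    if (n == 0L) {
      stop(sprintf("composition parse error: zero count in token '%s'", tok))
    }
    canon <- .RESIDUE_ALIASES[[res]]
    counts[[canon]] <- counts[[canon]] + n
  }
  do.call(glycan_composition, as.list(counts))
}

#' Neutral monoisotopic mass of a glycan composition
#'
#' The neutral mass is the sum of residue masses plus one water, so that
#' mass is additive in residues: `mass(A + B) = mass(A) + mass(B) - water`.
#'
#' @param comp A [glycan_composition()].
#' @return Mass in Da.
#' @examples
#' neutral_monoisotopic_mass(glycan_composition(Hex = 5, HexNAc = 2))
#' @export
neutral_monoisotopic_mass <- function(comp) {
  if (!inherits(comp, "glycan_composition")) {
    stop("invalid composition: expected a glycan_composition")
  }
  sum(as.numeric(comp) * .RESIDUE_MASSES) + .MASS_WATER
}
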