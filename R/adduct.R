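#' MALDI adduct / ion-species specification
#'
#' Charge-carrier bookkeeping for ion species such as `[M+Na]+` or
#' `[M-2H+Na]-`: `hydrogens_removed` protons lost from the neutral molecule,
#' plus added protons, sodium and potassium cations. The net charge
#' `z = protons + sodium + potassium - hydrogens_removed` must be nonzero
#' with `|z|` 1 or 2 (the charge states observed in MALDI glycan spectra).
#'
#' @param hydrogens_removed,protons_added,sodium_added,potassium_added
#'   Non-negative integers.
#' @return An object of class `adduct_spec`.
#' @examples
#' adduct_spec(sodium_added = 1)                       # [M+Na]+
#' adduct_spec(hydrogens_removed = 2, sodium_added = 1) # [M-2H+Na]-
#' @export
adduct_spec <- function(hydrogens_removed = 0, protons_added = 0,
                        sodium_added = 0, potassium_added = 0) {
  v <- c(H_removed = hydrogens_removed, H = protons_added,
         Na = sodium_added, K = potassium_added)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("invalid adduct: counts must be non-negative integers")
  }
  if (v[["H_removed"]] > 0 && v[["H"]] > 0) {
    stop("invalid adduct: cannot both add and remove hydrogens")
  }
  z <- v[["H"]] + v[["Na"]] + v[["K"]] - v[["H_removed"]]
  if (z == 0) stop("invalid adduct: net charge is zero")
  if (abs(z) > 2) stop("invalid adduct: |charge| must be 1 or 2")
  structure(as.integer(v), names = names(v), class = "adduct_spec")
}

#' Net charge of an adduct
#' @param adduct An [adduct_spec()].
#' @return Signed integer charge.
#' @export
adduct_charge <- function(adduct) {
  stopifnot(inherits(adduct, "adduct_spec"))
  adduct[["H"]] + adduct[["Na"]] + adduct[["K"]] - adduct[["H_removed"]]
}

#' Canonical adduct label
#'
#' Renders the label grammar of the published tables: the hydrogen term
#' first (`-2H` or `+H`), then sodium, then potassium, then `]` and the
#' charge (`+`, `-`, `2+`, `2-`), e.g. `[M-3H+2Na]-`.
#' `parse_adduct_label()` inverts this rendering.
#'
#' @param adduct An [adduct_spec()].
#' @return A single string.
#' @export
format_adduct <- function(adduct) {
  stopifnot(inherits(adduct, "adduct_spec"))
  term <- function(sign, n, sym) {
    if (n == 0) return("")
    paste0(sign, if (n > 1) n else "", sym)
  }
  z <- adduct_charge(adduct)
  paste0("[M",
         term("-", adduct[["H_removed"]], "H"),
         term("+", adduct[["H"]], "H"),
         term("+", adduct[["Na"]], "Na"),
         term("+", adduct[["K"]], "K"),
         "]",
         if (abs(z) > 1) abs(z) else "",
         if (z > 0) "+" else "-")
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct>", format_adduct(x), "\n")
  invisible(x)
}

#' @export
format.adduct_spec <- function(x, ...) format_adduct(x)

#' Parse an adduct label
#'
#' Parses ion-species labels of the form `[M(+/-terms)]z+/-`, covering all
#' forms in the published tables: `[M+H]+`, `[M+Na]+`, `[M+K]+`,
#' `[M+2Na]2+`, `[M-H]-`, `[M-2H]2-`, `[M-2H+Na]-`, `[M-3H+2Na]-`,
#' `[M-4H+2Na]2-`. The trailing charge must agree with the net charge
#' implied by the terms. Unicode minus signs and superscript carets are
#' normalized before parsing.
#'
#' @param text A single adduct label.
#' @return An [adduct_spec()].
#' @examples
#' parse_adduct_label("[M-2H+Na]-")
#' @export
parse_adduct_label <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("adduct parse error: input must be a single string")
  }
  s <- gsub("[[:space:]^]", "", text)
  s <- gsub("−|–", "-", s)  # unicode minus / en-dash
  m <- regmatches(s, regexec("^\\[M((?:[+-][0-9]*(?:H|Na|K))*)\\]([0-9]*)([+-])$",
                             s, perl = TRUE))[[1]]
  if (length(m) == 0) {
    stop(sprintf("adduct parse error: unrecognized label '%s'", text))
  }
  terms <- m[2]; zmag <- m[3]; zsign <- m[4]
  counts <- c(H_removed = 0L, H = 0L, Na = 0L, K = 0L)
  if (nzchar(terms)) {
    tm <- gregexpr("[+-][0-9]*(?:H|Na|K)", terms, perl = TRUE)[[1]]
    for (tok in regmatches(terms, list(tm))[[1]]) {
      sign <- substr(tok, 1, 1)
      body <- substring(tok, 2)
      n <- sub("(H|Na|K)$", "", body)
      n <- if (nzchar(n)) as.integer(n) else 1L
      sym <- sub("^[0-9]*", "", body)
      if (sign == "-") {
        if (sym != "H") {
          stop(sprintf("adduct parse error: cannot remove '%s' in '%s'", sym, text))
        }
        counts[["H_removed"]] <- counts[["H_removed"]] + n
      } else {
        counts[[sym]] <- counts[[sym]] + n
      }
    }
  } else {
    stop(sprintf("adduct parse error: no charge carriers in '%s'", text))
  }
  ad <- adduct_spec(counts[["H_removed"]], counts[["H"]],
                    counts[["Na"]], counts[["K"]])
  z <- adduct_charge(ad)
  zmag <- if (nzchar(zmag)) as.integer(zmag) else 1L
  if (abs(z) != zmag || sign(z) != (if (zsign == "+") 1 else -1)) {
    stop(sprintf("adduct parse error: printed charge '%s%s' disagrees with terms in '%s'",
                 zmag, zsign, text))
  }
  ad
}

# mass added to the neutral molecule by the charge carriers (Da, signed)
.adduct_mass_shift <- function(adduct) {
  adduct[["Na"]] * .MASS_NA + adduct[["K"]] * .MASS_K +
    (adduct[["H"]] - adduct[["H_removed"]]) * .MASS_PROTON
}

#' Theoretical m/z of a glycan ion
#'
#' `m/z = (M + p m(Na+) + q m(K+) + (r - s) m(H+)) / |z|` where `M` is the
#' neutral monoisotopic mass, `p`/`q`/`r`/`s` the sodium/potassium/proton
#' added and hydrogen removed counts, and `z` the net charge.
#'
#' @param comp A [glycan_composition()].
#' @param adduct An [adduct_spec()] or adduct label string.
#' @return m/z in Da per unit charge.
#' @examples
#' ion_mz(glycan_composition(Hex = 5, HexNAc = 2), "[M+Na]+")  # 1257.4227
#' @export
ion_mz <- function(comp, adduct) {
  if (is.character(adduct)) adduct <- parse_adduct_label(adduct)
  stopifnot(inherits(adduct, "adduct_spec"))
  z <- adduct_charge(adduct)
  if (z == 0) stop("invalid adduct: net charge is zero")
  (neutral_monoisotopic_mass(comp) + .adduct_mass_shift(adduct)) / abs(z)
}

#' Signed relative mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`. Vectorized over both
#' arguments.
#'
#' @param observed,theoretical m/z values (theoretical must be > 0).
#' @return Signed ppm error.
#' @examples
#' ppm_error(1000.010, 1000)  # +10
#' @export
ppm_error <- function(observed, theoretical) {
  if (anyNA(theoretical) || any(theoretical <= 0)) {
    stop("invalid input: theoretical m/z must be positive")
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Ionization mode implied by an adduct
#' @param adduct An [adduct_spec()] or label.
#' @return `"positive"` or `"negative"`.
#' @export
adduct_mode <- function(adduct) {
  if (is.character(adduct)) adduct <- parse_adduct_label(adduct)
  if (adduct_charge(adduct) > 0) "positive" else "negative"
}
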