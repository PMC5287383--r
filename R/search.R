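#' Search parameters for composition assignment
#'
#' Controls the exact-mass composition search: the relative mass tolerance
#' (ppm of the theoretical m/z, default 10), an optional absolute tolerance
#' in Da that overrides the ppm window (useful when matching against masses
#' printed at two decimals, which are rounded beyond 10 ppm fidelity),
#' per-residue count bounds, the candidate adduct set per ionization mode,
#' and the plausibility rule-set.
#'
#' @param tol_ppm Relative tolerance in ppm (> 0).
#' @param tol_da Optional absolute tolerance in Da; when non-`NULL` it
#'   replaces the ppm window.
#' @param max_counts Named integer vector of per-residue upper bounds.
#' @param adducts_positive,adducts_negative Character vectors of adduct
#'   labels considered in each mode; polarity must match the mode. The
#'   defaults are the singly-charged species: without isotope-based charge
#'   assignment (out of scope here, done instrument-side on FT-ICR data)
#'   doubly-charged candidates would compete for every singly-charged
#'   peak, because the composition lattice at twice the mass is dense on
#'   the ppm scale. Add `"[M+2Na]2+"`, `"[M-2H]2-"`, `"[M-4H+2Na]2-"`
#'   explicitly when working with charge-deconvolved peak lists.
#' @param rules Plausibility rule-set identifier (see
#'   [biological_filter()]).
#' @return An object of class `search_params`.
#' @export
search_params <- function(tol_ppm = 10,
                          tol_da = NULL,
                          max_counts = c(Hex = 15, HexNAc = 10, Fuc = 4,
                                         Neu5Ac = 4, Neu5Gc = 4, S = 2),
                          adducts_positive = c("[M+Na]+", "[M+K]+", "[M+H]+"),
                          adducts_negative = c("[M-H]-", "[M-2H+Na]-",
                                               "[M-3H+2Na]-"),
                          rules = "default") {
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) stop("tolerance must be > 0")
  if (!is.null(tol_da) && (!is.numeric(tol_da) || tol_da <= 0)) {
    stop("tolerance must be > 0")
  }
  mc <- stats::setNames(integer(length(.RESIDUES)), .RESIDUES)
  mc[names(max_counts)] <- as.integer(max_counts)
  if (any(is.na(mc)) || any(mc < 0)) stop("count bounds must be >= 0")
  for (lab in adducts_positive) {
    if (adduct_mode(lab) != "positive") {
      stop(sprintf("configuration error: '%s' is not a positive-mode adduct", lab))
    }
  }
  for (lab in adducts_negative) {
    if (adduct_mode(lab) != "negative") {
      stop(sprintf("configuration error: '%s' is not a negative-mode adduct", lab))
    }
  }
  .check_rules(rules)
  structure(list(tol_ppm = tol_ppm, tol_da = tol_da, max_counts = mc,
                 adducts = list(positive = adducts_positive,
                                negative = adducts_negative),
                 rules = rules),
            class = "search_params")
}

# Exhaustive bounded residue lattice with precomputed neutral masses,
# cached per bounds vector. < 10^6 points at the default bounds, so an
# explicit enumeration is exact and cheap; no heuristic changes the
# result set.
.composition_lattice <- function(max_counts) {
  key <- paste(max_counts, collapse = ",")
  hit <- .glyco_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- expand.grid(Hex = 0:max_counts[["Hex"]],
                      HexNAc = 0:max_counts[["HexNAc"]],
                      Fuc = 0:max_counts[["Fuc"]],
                      Neu5Ac = 0:max_counts[["Neu5Ac"]],
                      Neu5Gc = 0:max_counts[["Neu5Gc"]],
                      S = 0:max_counts[["S"]],
                      KEEP.OUT.ATTRS = FALSE)
  counts <- as.matrix(grid)
  keep <- rowSums(counts[, .SUGAR_RESIDUES, drop = FALSE]) > 0
  counts <- counts[keep, , drop = FALSE]
  lattice <- list(
    counts = counts,
    mass = as.numeric(counts %*% .RESIDUE_MASSES) + .MASS_WATER,
    total = rowSums(counts)
  )
  .glyco_cache[[key]] <- lattice
  lattice
}

# --- plausibility rules ----------------------------------------------------

# Vectorized rule evaluation over a count matrix; returns character reasons
# ("" = pass). The default rule-set is a Cooper-style biological filter
# chosen so that every composition reported in the packaged tables passes:
# terminal residues (Fuc, sialic acids) and sulfate require a HexNAc core,
# sialic acid count cannot exceed the antenna bound HexNAc + 1, fucoses
# cannot outnumber the HexNAc they attach to, a released N-glycan retains
# at least one hexose, and Neu5Ac/Neu5Gc do not co-occur (mixed sialylation
# is not observed in these tissues and its exclusion resolves the exact
# Hex + Neu5Ac = Fuc + Neu5Gc isobar).
.RULE_SETS <- list(
  default = function(counts) {
    reason <- character(nrow(counts))
    sia <- counts[, "Neu5Ac"] + counts[, "Neu5Gc"]
    dec <- counts[, "Fuc"] + sia
    bad <- dec > 0 & counts[, "HexNAc"] < 1
    reason[bad & sia > 0] <- "sialic acid without HexNAc"
    reason[bad & sia == 0] <- "fucose without HexNAc"
    ok <- function() reason == ""
    reason[ok() & sia > counts[, "HexNAc"] + 1] <-
      "more sialic acids than antennae (HexNAc + 1)"
    reason[ok() & counts[, "S"] > 0 & counts[, "HexNAc"] < 1] <-
      "sulfate without HexNAc"
    reason[ok() & counts[, "Fuc"] > counts[, "HexNAc"]] <-
      "more fucoses than HexNAc attachment sites"
    reason[ok() & counts[, "Hex"] < 1] <- "no hexose"
    reason[ok() & counts[, "Neu5Ac"] > 0 & counts[, "Neu5Gc"] > 0] <-
      "mixed Neu5Ac/Neu5Gc sialylation"
    reason
  },
  none = function(counts) character(nrow(counts))
)

.check_rules <- function(rules) {
  if (!is.character(rules) || length(rules) != 1L ||
      !rules %in% names(.RULE_SETS)) {
    stop(sprintf("configuration error: unknown rule-set '%s'",
                 paste(rules, collapse = ",")))
  }
  invisible(rules)
}

#' Biological plausibility filter for glycan compositions
#'
#' Deterministic rule evaluation pruning chemically possible but
#' biologically implausible compositions from mass-match candidates.
#' The `"default"` rule-set requires a HexNAc core for fucose, sialic
#' acids and sulfate, and caps sialic acids at HexNAc + 1; `"none"`
#' disables filtering.
#'
#' @param comp A [glycan_composition()].
#' @param rules Rule-set identifier.
#' @return A list with `pass` (logical) and `reason` (string, `""` on pass).
#' @examples
#' biological_filter(glycan_composition(Hex = 6))$pass          # TRUE
#' biological_filter(glycan_composition(Hex = 1, Neu5Ac = 4))$pass # FALSE
#' @export
biological_filter <- function(comp, rules = "default") {
  stopifnot(inherits(comp, "glycan_composition"))
  .check_rules(rules)
  reason <- .RULE_SETS[[rules]](matrix(as.integer(comp), nrow = 1,
                                       dimnames = list(NULL, .RESIDUES)))
  list(pass = reason == "", reason = reason)
}

#' Enumerate candidate compositions for an observed m/z
#'
#' The first-pass exact-mass search: all (composition, adduct) pairs within
#' the bounded residue lattice whose theoretical m/z matches the observed
#' value within tolerance, for every candidate adduct of the ionization
#' mode. Identical to exhaustive enumeration over the lattice. Candidates
#' are ordered by absolute ppm error, ties broken by fewer total residues,
#' then canonical composition string. The plausibility filter result is
#' reported per candidate but no candidate is dropped here.
#'
#' @param mz Observed m/z (> 0).
#' @param mode `"positive"` or `"negative"`.
#' @param params A [search_params()].
#' @return A data frame with columns `composition`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, `total_residues`, `plausible`,
#'   `reason`, ordered as described.
#' @examples
#' head(enumerate_candidates(1257.423, "positive", search_params()))
#' @export
enumerate_candidates <- function(mz, mode = c("positive", "negative"),
                                 params = search_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "search_params"))
  if (!is.numeric(mz) || length(mz) != 1L || is.na(mz) || mz <= 0) {
    stop("invalid input: mz must be a positive number")
  }
  adducts <- params$adducts[[mode]]
  if (length(adducts) == 0) {
    stop("configuration error: empty adduct set for mode ", mode)
  }
  lat <- .composition_lattice(params$max_counts)
  reasons <- .RULE_SETS[[params$rules]](lat$counts)
  out <- vector("list", length(adducts))
  for (i in seq_along(adducts)) {
    ad <- parse_adduct_label(adducts[[i]])
    z <- abs(adduct_charge(ad))
    theo <- (lat$mass + .adduct_mass_shift(ad)) / z
    sel <- if (!is.null(params$tol_da)) {
      abs(theo - mz) <= params$tol_da
    } else {
      abs(1e6 * (mz - theo) / theo) <= params$tol_ppm
    }
    if (!any(sel)) next
    idx <- which(sel)
    comp_str <- apply(lat$counts[idx, , drop = FALSE], 1, function(cnt) {
      format_composition(do.call(glycan_composition, as.list(cnt)))
    })
    out[[i]] <- data.frame(
      composition = comp_str,
      adduct = adducts[[i]],
      theoretical_mz = theo[idx],
      ppm_error = 1e6 * (mz - theo[idx]) / theo[idx],
      total_residues = lat$total[idx],
      plausible = reasons[idx] == "",
      reason = reasons[idx],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(composition = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      total_residues = integer(0), plausible = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  }
  res <- res[order(abs(res$ppm_error), res$total_residues, res$composition), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign compositions to a peak list
#'
#' Batch form of the per-peak search: each peak receives at most one
#' retained assignment — the first candidate, in the deterministic
#' candidate ordering, that survives the plausibility filter. Peaks with
#' no surviving candidate are reported in `unassigned` with a reason,
#' never dropped silently.
#'
#' @param peaks A peak-list data frame with columns `mz`, `intensity`,
#'   `mode`.
#' @param params A [search_params()].
#' @return A list with `assignments` (one row per assigned peak: the peak
#'   columns plus `composition`, `adduct`, `theoretical_mz`, `ppm_error`,
#'   `n_candidates`) and `unassigned` (peak columns plus `reason`).
#' @export
assign_peaklist <- function(peaks, params = search_params()) {
  peaks <- .validate_peaklist(peaks)
  assigned <- vector("list", nrow(peaks))
  missed <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- enumerate_candidates(peaks$mz[i], peaks$mode[i], params)
    hit <- which(cand$plausible)
    if (length(hit) == 0) {
      reason <- if (nrow(cand) == 0) "no candidate within tolerance"
                else "no plausible candidate within tolerance"
      missed[[i]] <- cbind(peaks[i, , drop = FALSE],
                           data.frame(reason = reason))
    } else {
      best <- cand[hit[1], , drop = FALSE]
      assigned[[i]] <- cbind(peaks[i, , drop = FALSE],
                             data.frame(composition = best$composition,
                                        adduct = best$adduct,
                                        theoretical_mz = best$theoretical_mz,
                                        ppm_error = best$ppm_error,
                                        n_candidates = nrow(cand)))
    }
  }
  bindrows <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (length(lst) == 0) return(NULL)
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  a <- bindrows(assigned)
  u <- bindrows(missed)
  if (is.null(a)) {
    a <- data.frame(mz = numeric(0), intensity = numeric(0),
                    mode = character(0), composition = character(0),
                    adduct = character(0), theoretical_mz = numeric(0),
                    ppm_error = numeric(0), n_candidates = integer(0))
  }
  if (is.null(u)) {
    u <- data.frame(mz = numeric(0), intensity = numeric(0),
                    mode = character(0), reason = character(0))
  }
  list(assignments = a, unassigned = u)
}

.validate_peaklist <- function(peaks) {
  if (!is.data.frame(peaks)) stop("peak list must be a data frame")
  need <- c("mz", "intensity", "mode")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0) {
    stop(sprintf("schema error: peak list missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(peaks) > 0) {
    if (any(is.na(peaks$mz)) || any(peaks$mz <= 0)) {
      stop("invalid peak list: m/z must be positive")
    }
    if (any(is.na(peaks$intensity)) || any(peaks$intensity < 0)) {
      stop("invalid peak list: intensities must be >= 0")
    }
    if (!all(peaks$mode %in% c("positive", "negative"))) {
      stop("invalid peak list: mode must be 'positive' or 'negative'")
    }
  }
  peaks[, need, drop = FALSE]
}
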