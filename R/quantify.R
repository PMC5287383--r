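#' Internal-standard reference
#'
#' beta-cyclodextrin is doped into every sample at a fixed amount and
#' observed at the published reference m/z values (`[M+Na]+` 1157.25 in
#' positive mode, `[M-H]-` 1133.25 in negative mode). Matching uses a
#' +/- `window` Da interval around the printed reference values, not the
#' theoretical cyclodextrin mass (which differs by ~0.1 Da).
#'
#' @param mz_positive,mz_negative Reference m/z per mode.
#' @param window Half-width of the match window in Da (> 0).
#' @return An object of class `internal_standard_ref`.
#' @export
internal_standard_ref <- function(mz_positive = 1157.25,
                                  mz_negative = 1133.25,
                                  window = 0.5) {
  if (!is.numeric(window) || window <= 0) stop("window must be > 0")
  structure(list(mz_positive = mz_positive, mz_negative = mz_negative,
                 window = window),
            class = "internal_standard_ref")
}

#' Locate the internal-standard peak
#'
#' Returns the most intense peak of the requested mode within the match
#' window around the mode's reference m/z. A missing internal standard is
#' an error: the sample must be excluded with a logged reason, never
#' silently zeroed.
#'
#' @param peaks Peak-list data frame (`mz`, `intensity`, `mode`).
#' @param mode `"positive"` or `"negative"`.
#' @param ref An [internal_standard_ref()].
#' @return The matching peak as a one-row data frame.
#' @export
locate_internal_standard <- function(peaks, mode = c("positive", "negative"),
                                     ref = internal_standard_ref()) {
  mode <- match.arg(mode)
  peaks <- .validate_peaklist(peaks)
  if (nrow(peaks) == 0) stop("missing internal standard: empty peak list")
  target <- if (mode == "positive") ref$mz_positive else ref$mz_negative
  sel <- peaks$mode == mode & abs(peaks$mz - target) <= ref$window
  if (!any(sel)) {
    stop(sprintf(
      "missing internal standard: no %s-mode peak within %.2f Da of %.2f",
      mode, ref$window, target))
  }
  cand <- peaks[sel, , drop = FALSE]
  cand[which.max(cand$intensity), , drop = FALSE]
}

#' Scale intensities to the internal standard
#'
#' Corrected intensity = 100 x raw / internal-standard intensity, so the
#' internal standard itself maps to 100 and corrected abundances fall in
#' the ~1-150 range of the published tables. Scale-invariant: multiplying
#' all raw intensities (including the standard) by k > 0 leaves corrected
#' values unchanged.
#'
#' @param peaks Peak-list data frame.
#' @param is_peak The internal-standard peak (one row, intensity > 0).
#' @return The peak list with `intensity` replaced by corrected intensity.
#' @export
normalize_intensities <- function(peaks, is_peak) {
  peaks <- .validate_peaklist(peaks)
  is_int <- is_peak$intensity[1]
  if (is.na(is_int) || is_int <= 0) {
    stop("internal standard intensity must be > 0")
  }
  peaks$intensity <- 100 * peaks$intensity / is_int
  peaks
}

#' Normalize a mixed-mode peak list
#'
#' Locates the internal standard separately in each ionization mode present
#' and scales that mode's peaks to it.
#'
#' @inheritParams locate_internal_standard
#' @return Corrected peak list.
#' @export
normalize_peaklist <- function(peaks, ref = internal_standard_ref()) {
  peaks <- .validate_peaklist(peaks)
  parts <- lapply(intersect(c("positive", "negative"), unique(peaks$mode)),
                  function(md) {
    sub <- peaks[peaks$mode == md, , drop = FALSE]
    normalize_intensities(sub, locate_internal_standard(sub, md, ref))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Abundance matrix of corrected intensities
#'
#' Samples x glycan-species matrix of internal-standard-corrected
#' intensities; a species absent from a sample is recorded as 0. Species
#' keys are `"<composition> <adduct>"` strings; every sample carries
#' exactly one group label from [group_levels()].
#'
#' @param values Numeric matrix (samples in rows, species in columns),
#'   non-negative, with unique column names and row names equal to
#'   `samples$sample_id`.
#' @param samples Data frame with columns `sample_id`, `group`.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (any(values < 0)) stop("corrected intensities must be >= 0")
  if (anyDuplicated(colnames(values))) stop("species keys must be unique")
  need <- c("sample_id", "group")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("schema error: samples needs columns sample_id, group")
  }
  if (!identical(rownames(values), as.character(samples$sample_id))) {
    stop("row names of values must equal samples$sample_id")
  }
  if (!all(samples$group %in% .GROUP_LEVELS)) {
    stop(sprintf("group labels must be one of: %s",
                 paste(.GROUP_LEVELS, collapse = ", ")))
  }
  structure(list(values = values,
                 samples = data.frame(sample_id = as.character(samples$sample_id),
                                      group = as.character(samples$group),
                                      stringsAsFactors = FALSE)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance matrix> %d samples x %d species (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$samples$group)),
                            as.integer(table(x$samples$group))),
                    collapse = ", ")))
  invisible(x)
}

#' Species key string
#' @param composition Composition string or [glycan_composition()].
#' @param adduct Adduct label or [adduct_spec()].
#' @return `"<composition> <adduct>"`.
#' @export
species_key <- function(composition, adduct) {
  if (inherits(composition, "glycan_composition")) {
    composition <- format_composition(composition)
  }
  if (inherits(adduct, "adduct_spec")) adduct <- format_adduct(adduct)
  paste(composition, adduct)
}

#' Build an abundance matrix from corrected peak lists
#'
#' Two routes from per-sample corrected peak lists to the samples x species
#' matrix. `"targeted"` matches each provided species' theoretical m/z
#' against the sample's peaks (within the search tolerance) and is used
#' when the species panel is known. `"denovo"` runs the full
#' [assign_peaklist()] search per sample and keys species by the assigned
#' (composition, adduct). Intensities of multiple matching peaks are
#' summed; absent species are 0.
#'
#' @param peaklists Named list of corrected peak-list data frames, names
#'   are sample ids.
#' @param manifest Data frame with `sample_id`, `group`.
#' @param method `"targeted"` or `"denovo"`.
#' @param species For `"targeted"`: data frame with columns `composition`,
#'   `adduct` (label strings).
#' @param params A [search_params()].
#' @return An [abundance_matrix()].
#' @export
build_abundance_matrix <- function(peaklists, manifest,
                                   method = c("targeted", "denovo"),
                                   species = NULL,
                                   params = search_params()) {
  method <- match.arg(method)
  if (!all(manifest$sample_id %in% names(peaklists))) {
    stop("manifest sample ids missing from peak lists")
  }
  ids <- as.character(manifest$sample_id)
  if (method == "targeted") {
    if (is.null(species)) stop("targeted matching needs a species table")
    keys <- species_key(species$composition, species$adduct)
    theo <- mapply(function(cs, al) ion_mz(parse_composition(cs), al),
                   species$composition, species$adduct)
    modes <- vapply(species$adduct, adduct_mode, character(1))
    values <- matrix(0, nrow = length(ids), ncol = length(keys),
                     dimnames = list(ids, keys))
    for (sid in ids) {
      pk <- .validate_peaklist(peaklists[[sid]])
      for (j in seq_along(keys)) {
        sel <- pk$mode == modes[j] &
          (if (!is.null(params$tol_da)) abs(pk$mz - theo[j]) <= params$tol_da
           else abs(1e6 * (pk$mz - theo[j]) / theo[j]) <= params$tol_ppm)
        if (any(sel)) values[sid, j] <- sum(pk$intensity[sel])
      }
    }
  } else {
    per_sample <- lapply(ids, function(sid) {
      assign_peaklist(peaklists[[sid]], params)$assignments
    })
    names(per_sample) <- ids
    keys <- unique(unlist(lapply(per_sample, function(a) {
      if (nrow(a) == 0) character(0) else species_key(a$composition, a$adduct)
    })))
    values <- matrix(0, nrow = length(ids), ncol = length(keys),
                     dimnames = list(ids, keys))
    for (sid in ids) {
      a <- per_sample[[sid]]
      if (nrow(a) == 0) next
      k <- species_key(a$composition, a$adduct)
      agg <- tapply(a$intensity, k, sum)
      values[sid, names(agg)] <- as.numeric(agg)
    }
  }
  abundance_matrix(values, manifest)
}

#' Per-group summaries for every species
#'
#' Mean, sample standard deviation (n-1 denominator) and detectability per
#' (species, group). Zeros for absent species are included in the mean and
#' SD — the convention under which a single-nonzero triple like
#' \{22.95, 0, 0\} reproduces the published "7.65 +/- 13.24" style cells.
#' A species is detectable in a group iff any replicate is > 0;
#' undetectable implies mean = SD = 0.
#'
#' @param am An [abundance_matrix()].
#' @return Data frame with columns `species`, `group`, `n`, `mean`, `sd`,
#'   `detectable`.
#' @export
summarize_groups <- function(am) {
  stopifnot(inherits(am, "abundance_matrix"))
  groups <- intersect(.GROUP_LEVELS, unique(am$samples$group))
  out <- list()
  for (g in groups) {
    rows <- am$samples$sample_id[am$samples$group == g]
    sub <- am$values[rows, , drop = FALSE]
    n <- nrow(sub)
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    if (n < 2) sdv <- rep(NA_real_, ncol(sub))
    out[[g]] <- data.frame(species = colnames(sub), group = g, n = n,
                           mean = as.numeric(mu), sd = as.numeric(sdv),
                           detectable = apply(sub > 0, 2, any),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary for one (species, group) cell
#'
#' @param am An [abundance_matrix()].
#' @param species Species key present in the matrix.
#' @param group Group label present in the matrix.
#' @return List with `mean`, `sd`, `n`, `detectable`, `values`.
#' @export
aggregate_group <- function(am, species, group) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (!species %in% colnames(am$values)) {
    stop(sprintf("lookup error: unknown species '%s'", species))
  }
  if (!group %in% am$samples$group) {
    stop(sprintf("lookup error: unknown group '%s'", group))
  }
  v <- am$values[am$samples$sample_id[am$samples$group == group], species]
  list(mean = mean(v), sd = stats::sd(v), n = length(v),
       detectable = any(v > 0), values = as.numeric(v))
}

# Dixon's Q critical values, two-sided r10 statistic (Rorabacher 1991),
# n = 3..10
.DIXON_Q <- list(
  "0.05" = c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
             `7` = 0.568, `8` = 0.526, `9` = 0.493, `10` = 0.466),
  "0.01" = c(`3` = 0.994, `4` = 0.926, `5` = 0.821, `6` = 0.740,
             `7` = 0.680, `8` = 0.634, `9` = 0.598, `10` = 0.568)
)

#' Dixon's Q-test for a single outlier
#'
#' Small-sample outlier screen (3 <= n <= 10): the suspect value is the
#' extreme with the larger gap to its nearest neighbour, Q = gap / range,
#' flagged iff Q exceeds the two-sided critical value Q(n, alpha). At most
#' one value is flagged per call. A zero range yields a no-test result;
#' the flag is invariant under affine transforms of the data.
#'
#' @param values Numeric vector, 3 to 10 values.
#' @param alpha Significance level, 0.05 or 0.01.
#' @return List with `flagged`, `suspect` (index into `values` or `NA`),
#'   `Q`, `critical`, `note`.
#' @examples
#' dixon_outlier_test(c(1.0, 1.1, 5.0))  # Q = 0.975, flagged
#' @export
dixon_outlier_test <- function(values, alpha = 0.05) {
  akey <- format(alpha)
  if (!akey %in% names(.DIXON_Q)) {
    stop("alpha must be 0.05 or 0.01 (tabulated critical values)")
  }
  if (anyNA(values)) stop("insufficient data: missing values")
  n <- length(values)
  if (n < 3) stop("insufficient data: Dixon's Q-test needs n >= 3")
  if (n > 10) stop("Dixon's Q-test (r10) is tabulated for n <= 10")
  rng <- diff(range(values))
  if (rng == 0) {
    return(list(flagged = FALSE, suspect = NA_integer_, Q = NA_real_,
                critical = NA_real_, note = "zero range: no test"))
  }
  s <- sort(values)
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_high >= q_low) {
    Q <- q_high
    suspect <- which(values == s[n])[1]
  } else {
    Q <- q_low
    suspect <- which(values == s[1])[1]
  }
  crit <- .DIXON_Q[[akey]][[as.character(n)]]
  list(flagged = Q > crit, suspect = as.integer(suspect), Q = Q,
       critical = crit, note = "")
}

#' Outlier screen over an abundance matrix
#'
#' Applies [dixon_outlier_test()] to each (species, group) replicate
#' vector. Flagged values are reported only; exclusion is left to the
#' caller.
#'
#' @param am An [abundance_matrix()].
#' @param alpha Significance level.
#' @return Data frame of tested cells with `species`, `group`, `Q`,
#'   `critical`, `flagged`, `suspect_sample`.
#' @export
screen_outliers <- function(am, alpha = 0.05) {
  stopifnot(inherits(am, "abundance_matrix"))
  res <- list()
  for (g in unique(am$samples$group)) {
    ids <- am$samples$sample_id[am$samples$group == g]
    if (length(ids) < 3 || length(ids) > 10) next
    for (sp in colnames(am$values)) {
      v <- am$values[ids, sp]
      d <- dixon_outlier_test(v, alpha)
      res[[length(res) + 1]] <- data.frame(
        species = sp, group = g, Q = d$Q, critical = d$critical,
        flagged = d$flagged,
        suspect_sample = if (is.na(d$suspect)) NA_character_ else ids[d$suspect],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(species = character(0), group = character(0),
                      Q = numeric(0), critical = numeric(0),
                      flagged = logical(0), suspect_sample = character(0))
  }
  rownames(out) <- NULL
  out
}
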