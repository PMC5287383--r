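#' Pooled Student's t-test from summary statistics
#'
#' Two-sample pooled-variance Student's t computed from mean, SD and n of
#' each group (the form needed to recompute the published tables' markers
#' from their printed mean +/- SD cells), with df = n1 + n2 - 2. Both the
#' two-tailed and the one-tailed p (in the direction of the observed
#' difference) are returned: at n = 3 several published markers are
#' reproducible only one-tailed, and the reproduction report lists them.
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `statistic`, `df`, `p_two_tailed`, `p_one_tailed`.
#' @examples
#' students_t_from_summary(69.68, 7.52, 3, 33.75, 2.30, 3)
#' @export
students_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  vals <- c(mean1, sd1, n1, mean2, sd2, n2)
  if (anyNA(vals)) stop("degenerate input: missing summary statistics")
  if (n1 < 2 || n2 < 2) stop("degenerate input: each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("degenerate input: negative SD")
  if (sd1 == 0 && sd2 == 0) stop("degenerate input: both SDs are zero")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = df,
       p_two_tailed = 2 * stats::pt(-abs(t), df),
       p_one_tailed = stats::pt(-abs(t), df))
}

#' Pooled Student's t-test from raw replicates
#'
#' Raw-replicate entry point; agrees exactly with
#' [students_t_from_summary()] applied to the replicate summaries.
#'
#' @param x,y Numeric replicate vectors (each n >= 2).
#' @return As [students_t_from_summary()].
#' @export
students_t <- function(x, y) {
  students_t_from_summary(mean(x), stats::sd(x), length(x),
                          mean(y), stats::sd(y), length(y))
}

#' One-way analysis of variance
#'
#' Classical equal-variance between/within decomposition over two or more
#' replicate groups (via `stats::oneway.test(var.equal = TRUE)`). With
#' exactly two groups, F equals the squared pooled t statistic. All values
#' identical across groups gives a no-test result rather than 0/0.
#'
#' @param groups List of numeric vectors, each with n >= 2.
#' @return List with `statistic` (F), `df` (length 2), `p`, `note`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("one_way_anova needs a list of >= 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs n >= 2")
  }
  values <- unlist(groups, use.names = FALSE)
  if (diff(range(values)) == 0) {
    return(list(statistic = NA_real_, df = c(NA_real_, NA_real_),
                p = NA_real_, note = "all values identical: no test"))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       df = unname(c(fit$parameter[["num df"]], fit$parameter[["denom df"]])),
       p = fit$p.value, note = "")
}

#' Recompute per-species significance from an abundance matrix
#'
#' Pooled Student's t of model vs control and of treated vs model for each
#' species, at level `alpha`. `one_tailed = TRUE` uses the one-tailed p in
#' the direction of the observed difference. No multiple-testing
#' correction is applied by default, mirroring the published analysis;
#' `correct = "BH"` applies Benjamini-Hochberg across species per
#' contrast. Degenerate cells (both SDs zero, or a group with n < 2) give
#' `NA` p and a non-significant call.
#'
#' @param am An [abundance_matrix()].
#' @param alpha Significance level.
#' @param one_tailed Use the one-tailed p.
#' @param correct `"none"` or `"BH"`.
#' @return Data frame with `species`, `p_model_vs_control`,
#'   `p_treated_vs_model`, `sig_model_vs_control`, `sig_treated_vs_model`.
#' @export
significance_from_matrix <- function(am, alpha = 0.05, one_tailed = FALSE,
                                     correct = c("none", "BH")) {
  stopifnot(inherits(am, "abundance_matrix"))
  correct <- match.arg(correct)
  pval <- function(x, y) {
    tryCatch({
      r <- students_t(x, y)
      if (one_tailed) r$p_one_tailed else r$p_two_tailed
    }, error = function(e) NA_real_)
  }
  grp <- function(g) am$samples$sample_id[am$samples$group == g]
  sp <- colnames(am$values)
  p_mc <- vapply(sp, function(s) {
    pval(am$values[grp("model"), s], am$values[grp("control"), s])
  }, numeric(1))
  p_tm <- vapply(sp, function(s) {
    pval(am$values[grp("treated"), s], am$values[grp("model"), s])
  }, numeric(1))
  if (correct == "BH") {
    p_mc <- stats::p.adjust(p_mc, method = "BH")
    p_tm <- stats::p.adjust(p_tm, method = "BH")
  }
  data.frame(species = sp,
             p_model_vs_control = p_mc,
             p_treated_vs_model = p_tm,
             sig_model_vs_control = !is.na(p_mc) & p_mc < alpha,
             sig_treated_vs_model = !is.na(p_tm) & p_tm < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify per-species modulation across the three groups
#'
#' The presence/absence classification generating the headline counts.
#' Categories are multi-label:
#' \describe{
#'   \item{control_only}{detectable in control, not in model}
#'   \item{model_only}{detectable in model, not in control}
#'   \item{treatment_induced}{not detectable in model, detectable in treated}
#'   \item{treatment_suppressed}{detectable in model, not in treated}
#'   \item{significantly_different_model_vs_control}{model vs control
#'     significant (recomputed test or transcribed table marker)}
#'   \item{significantly_changed_by_treatment}{treated vs model significant}
#'   \item{unchanged}{none of the above}
#' }
#'
#' @param summaries Long data frame from [summarize_groups()] (or the
#'   fixture equivalent) with all three groups present per species.
#' @param significance Optional data frame with `species`,
#'   `sig_model_vs_control`, `sig_treated_vs_model` (from
#'   [significance_from_matrix()] or transcribed markers). When `NULL`,
#'   both significance categories are `FALSE`.
#' @param significance_source Provenance string recorded on the result
#'   (`"recomputed"`, `"markers"`, or `"none"`).
#' @return Data frame, one row per species, with logical category columns
#'   and a `categories` summary string; provenance in
#'   `attr(, "significance_source")`.
#' @export
classify_modulation <- function(summaries, significance = NULL,
                                significance_source = if (is.null(significance)) "none" else "recomputed") {
  need <- c("species", "group", "detectable")
  if (!all(need %in% names(summaries))) {
    stop("schema error: summaries needs columns species, group, detectable")
  }
  miss <- setdiff(.GROUP_LEVELS, unique(summaries$group))
  if (length(miss) > 0) {
    stop(sprintf("missing group(s): %s", paste(miss, collapse = ", ")))
  }
  det <- function(g) {
    sub <- summaries[summaries$group == g, ]
    stats::setNames(sub$detectable, sub$species)
  }
  sp <- unique(summaries$species)
  dc <- det("control")[sp]; dm <- det("model")[sp]; dt <- det("treated")[sp]
  if (anyNA(dc) || anyNA(dm) || anyNA(dt)) {
    stop("every species needs a summary in all three groups")
  }
  sig_mc <- sig_tm <- stats::setNames(rep(FALSE, length(sp)), sp)
  if (!is.null(significance)) {
    idx <- match(sp, significance$species)
    sig_mc <- !is.na(idx) & significance$sig_model_vs_control[idx] %in% TRUE
    sig_tm <- !is.na(idx) & significance$sig_treated_vs_model[idx] %in% TRUE
  }
  calls <- data.frame(
    species = sp,
    control_only = dc & !dm,
    model_only = dm & !dc,
    treatment_induced = !dm & dt,
    treatment_suppressed = dm & !dt,
    significantly_different_model_vs_control = as.logical(sig_mc),
    significantly_changed_by_treatment = as.logical(sig_tm),
    row.names = NULL, stringsAsFactors = FALSE)
  catcols <- setdiff(names(calls), "species")
  calls$unchanged <- rowSums(calls[catcols]) == 0
  calls$categories <- apply(calls[c(catcols, "unchanged")], 1, function(r) {
    paste(names(r)[as.logical(r)], collapse = ";")
  })
  attr(calls, "significance_source") <- significance_source
  calls
}

#' Category counts from modulation calls
#'
#' Counts each category plus the union `modulated_by_treatment` =
#' induced or suppressed or significantly changed by treatment — the
#' "modulated by treatment" headline number.
#'
#' @param calls Data frame from [classify_modulation()].
#' @return Named integer vector of counts (including `n_species`).
#' @export
profile_comparison_counts <- function(calls) {
  catcols <- c("control_only", "model_only", "treatment_induced",
               "treatment_suppressed",
               "significantly_different_model_vs_control",
               "significantly_changed_by_treatment", "unchanged")
  if (nrow(calls) == 0) {
    return(stats::setNames(rep(0L, length(catcols) + 2),
                           c("n_species", catcols, "modulated_by_treatment")))
  }
  counts <- vapply(catcols, function(cc) sum(calls[[cc]]), integer(1))
  modulated <- sum(calls$treatment_induced | calls$treatment_suppressed |
                     calls$significantly_changed_by_treatment)
  c(n_species = nrow(calls), counts, modulated_by_treatment = modulated)
}
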