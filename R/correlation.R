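#' Novel-object discrimination index
#'
#' Percentage of exploration time spent with the novel object:
#' `100 * t_novel / (t_novel + t_familiar)`. The same formula serves the
#' short-term (1 h) and long-term (24 h) retention tests. Vectorized.
#'
#' @param t_novel,t_familiar Exploration times in seconds (>= 0).
#' @return Index in percent, in \[0, 100\].
#' @examples
#' discrimination_index(45, 15)  # 75
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  if (anyNA(c(t_novel, t_familiar)) ||
      any(t_novel < 0) || any(t_familiar < 0)) {
    stop("exploration times must be non-negative")
  }
  total <- t_novel + t_familiar
  if (any(total == 0)) {
    stop("undefined index: zero total exploration time")
  }
  100 * t_novel / total
}

#' Two-tailed Pearson correlation with Fisher 95% CI
#'
#' Product-moment correlation with the two-tailed p from
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 df and the 95% confidence
#' interval by the Fisher z transform,
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`. At |r| = 1 the p is 0 and the
#' interval degenerates to r; at n = 3 the interval is undefined (`NA`).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return List with `r`, `n`, `statistic`, `df`, `p`, `ci_lower`,
#'   `ci_upper`.
#' @examples
#' pearson_correlation(1:5, c(2, 1, 4, 3, 6))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient data: Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
    ci <- c(r, r)
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
    ci <- if (n >= 4) {
      tanh(atanh(r) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
    } else {
      c(NA_real_, NA_real_)
    }
  }
  list(r = r, n = n, statistic = t, df = df, p = p,
       ci_lower = ci[1], ci_upper = ci[2])
}

#' Screen glycan abundances against behavioral measures
#'
#' One Pearson correlation per (species, measure) pair, computed across
#' all animals pooled (both strains plus the treated group — pooling is
#' what yields the n = 8-9 of the published correlation figures). Pairs
#' with p < `alpha` are flagged; no multiplicity correction is applied but
#' the number of tests performed is recorded on the result. Pairs that
#' cannot be tested (constant vector) are returned with `NA` and a note.
#'
#' @param am An [abundance_matrix()]; row names are subject ids.
#' @param behavior Data frame with `subject_id`, `group`, and one numeric
#'   column per measure.
#' @param species Species keys to screen (default: all in the matrix).
#' @param measures Measure column names (default: all numeric behavior
#'   columns).
#' @param alpha Flagging level.
#' @return Data frame with `species`, `measure`, `r`, `n`, `p`,
#'   `ci_lower`, `ci_upper`, `flagged`, `note`; the number of tests in
#'   `attr(, "n_tests")`.
#' @export
screen_glycan_behavior <- function(am, behavior, species = NULL,
                                   measures = NULL, alpha = 0.05) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (!"subject_id" %in% names(behavior)) {
    stop("schema error: behavior needs a subject_id column")
  }
  if (is.null(species)) species <- colnames(am$values)
  if (is.null(measures)) {
    measures <- names(behavior)[vapply(behavior, is.numeric, logical(1))]
  }
  subjects <- intersect(rownames(am$values), as.character(behavior$subject_id))
  if (length(subjects) == 0) stop("no overlapping subjects")
  if (length(subjects) < 3) {
    stop("insufficient data: fewer than 3 overlapping subjects")
  }
  beh <- behavior[match(subjects, as.character(behavior$subject_id)), ,
                  drop = FALSE]
  rows <- list()
  for (sp in species) {
    for (ms in measures) {
      x <- am$values[subjects, sp]
      y <- beh[[ms]]
      res <- tryCatch(pearson_correlation(x, y), error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, measure = ms, r = NA_real_, n = length(x),
          p = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
          flagged = FALSE, note = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, measure = ms, r = res$r, n = res$n, p = res$p,
          ci_lower = res$ci_lower, ci_upper = res$ci_upper,
          flagged = res$p < alpha, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_tests") <- sum(out$note == "")
  out
}
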