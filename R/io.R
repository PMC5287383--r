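# Delimited-text I/O. All tabular files are TSV with '#'-prefixed header
# lines carrying the tool version and any caller-supplied metadata;
# readers skip them. Numeric round-trips are lossless well beyond 6
# significant digits.

.write_header <- function(con, meta = NULL) {
  version <- as.character(utils::packageVersion("glycoprofiler"))
  writeLines(sprintf("# glycoprofiler %s", version), con)
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, meta[[key]]), con)
  }
}

.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, meta)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, required, what = "file") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(content) == 0) {
    warning(sprintf("empty %s: %s", what, path))
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(required)),
                                         required))
    return(out)
  }
  df <- tryCatch(
    utils::read.delim(text = paste(content, collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("malformed %s '%s': %s", what, path,
                                     conditionMessage(e))))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(sprintf("schema error: %s '%s' missing column(s) %s",
                 what, path, paste(miss, collapse = ", ")))
  }
  df
}

#' Read a peak list
#'
#' TSV with columns `mz`, `intensity`, `mode` (`positive`/`negative`);
#' `#` lines are ignored. An empty file returns an empty peak list with a
#' warning; a missing required column is a schema error.
#'
#' @param path File path.
#' @return Peak-list data frame.
#' @export
read_peaklist <- function(path) {
  df <- .read_tsv(path, c("mz", "intensity", "mode"), "peak list")
  if (nrow(df) == 0) {
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      mode = character(0)))
  }
  .validate_peaklist(df)
}

#' Write a peak list
#' @param peaks Peak-list data frame.
#' @param path File path.
#' @param meta Optional named list written as `# key: value` header lines.
#' @export
write_peaklist <- function(peaks, path, meta = NULL) {
  .write_tsv(.validate_peaklist(peaks), path, meta)
}

#' Read a sample manifest
#'
#' TSV with columns `sample_id`, `group` (and optionally `path` pointing
#' at the sample's peak list).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  .read_tsv(path, c("sample_id", "group"), "manifest")
}

#' Read a behavior table
#'
#' TSV with `subject_id`, `group` and one numeric column per behavioral
#' measure.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_behavior <- function(path) {
  .read_tsv(path, c("subject_id", "group"), "behavior table")
}

#' Write an assignment table
#' @param assignment Result of [assign_peaklist()].
#' @param path File path for the assignments; unassigned peaks go to
#'   `<path>.unassigned` when any exist.
#' @param meta Optional header metadata.
#' @export
write_assignments <- function(assignment, path, meta = NULL) {
  .write_tsv(assignment$assignments, path, meta)
  if (nrow(assignment$unassigned) > 0) {
    .write_tsv(assignment$unassigned, paste0(path, ".unassigned"), meta)
  }
  invisible(path)
}

#' Write an abundance matrix
#'
#' Layout: `sample_id`, `group`, then one column per species key.
#'
#' @param am An [abundance_matrix()].
#' @param path File path.
#' @param meta Optional header metadata.
#' @export
write_matrix <- function(am, path, meta = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  df <- cbind(am$samples, as.data.frame(am$values, check.names = FALSE))
  .write_tsv(df, path, meta)
}

#' Read an abundance matrix written by [write_matrix()]
#' @param path File path.
#' @return An [abundance_matrix()].
#' @export
read_matrix <- function(path) {
  df <- .read_tsv(path, c("sample_id", "group"), "abundance matrix")
  species <- setdiff(names(df), c("sample_id", "group"))
  values <- as.matrix(df[species])
  rownames(values) <- as.character(df$sample_id)
  abundance_matrix(values, df[c("sample_id", "group")])
}

#' Write a generic report table
#' @param df Data frame.
#' @param path File path.
#' @param meta Optional header metadata.
#' @export
write_report <- function(df, path, meta = NULL) {
  .write_tsv(df, path, meta)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the same delimited-text formats the pipeline consumes: one peak
#' list per sample (`peaks_<sample>.tsv`), `manifest.tsv` (with a `path`
#' column), `behavior.tsv`, and the ground truth in `ground_truth.tsv`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  manifest$path <- file.path(dir, sprintf("peaks_%s.tsv", manifest$sample_id))
  for (i in seq_len(nrow(manifest))) {
    write_peaklist(cohort$peaklists[[manifest$sample_id[i]]], manifest$path[i])
  }
  .write_tsv(manifest, file.path(dir, "manifest.tsv"))
  .write_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  .write_tsv(cohort$truth$species, file.path(dir, "ground_truth.tsv"),
             meta = list(planted_species = cohort$truth$planted$species,
                         planted_measure = cohort$truth$planted$measure,
                         planted_r = cohort$truth$planted$r))
  invisible(dir)
}
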