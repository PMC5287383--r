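# md5 checksums of the shipped transcriptions, verified at load time
.FIXTURE_MD5 <- c(
  table1_cortex.tsv = "c9b9205b627b0318621b4f059158d6fc",
  table2_serum.tsv = "2be775c92c066039f6083b4856d84019"
)

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "glycoprofiler")
  if (!nzchar(path)) stop("corrupted install: fixture file not found: ", file)
  path
}

#' Load a packaged transcription of the published glycan tables
#'
#' Returns the machine-readable transcription of the cortex (43 species)
#' or serum (56 species) table: row number, printed observed m/z, adduct
#' label, composition string, per-group mean/SD (NA = "undetectable") and
#' the printed significance markers. The shipped file's md5 checksum and
#' row count are verified, and every composition and adduct string is
#' parsed, so validation errors are impossible on an intact install.
#' Known inconsistencies are carried as printed and listed in
#' [fixture_flags()], never corrected here.
#'
#' @param which `"cortex"` or `"serum"`.
#' @return Data frame with one row per species and a `species_id` key
#'   column (`"cortex-1"`, ...).
#' @export
load_fixture <- function(which = c("cortex", "serum")) {
  which <- match.arg(which)
  file <- if (which == "cortex") "table1_cortex.tsv" else "table2_serum.tsv"
  path <- .fixture_path(file)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.FIXTURE_MD5[[file]]))) {
    stop("integrity error: checksum mismatch for ", file)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]  # '#' is also the marker glyph
  fix <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = c(
                             no = "integer", observed_mz = "numeric",
                             adduct = "character", composition = "character",
                             control_mean = "numeric", control_sd = "numeric",
                             model_mean = "numeric", model_sd = "numeric",
                             treated_mean = "numeric", treated_sd = "numeric",
                             sig_model_vs_control = "character",
                             sig_treated_vs_model = "character"))
  expected_rows <- if (which == "cortex") 43L else 56L
  if (nrow(fix) != expected_rows) {
    stop("integrity error: expected ", expected_rows, " rows in ", file)
  }
  for (cs in fix$composition) parse_composition(cs)
  for (al in fix$adduct) parse_adduct_label(al)
  fix$sig_model_vs_control[is.na(fix$sig_model_vs_control)] <- ""
  fix$sig_treated_vs_model[is.na(fix$sig_treated_vs_model)] <- ""
  fix$species_id <- paste0(which, "-", fix$no)
  fix
}

#' Known inconsistencies in the shipped tables
#'
#' The printed tables contain internal inconsistencies (a duplicated
#' composition whose printed mass matches a different composition, masses
#' deviating from monoisotopic theory, a narrative count that disagrees
#' with the detectability rules). They are transcribed as printed; this
#' table flags them machine-readably.
#'
#' @return Data frame with `table`, `row`, `issue`, `detail`,
#'   `suggested_composition`.
#' @export
fixture_flags <- function() {
  utils::read.delim(.fixture_path("fixture_flags.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c(table = "character", row = "integer",
                                   issue = "character", detail = "character",
                                   suggested_composition = "character"))
}

#' Long-format group summaries from a fixture table
#'
#' Reshapes a [load_fixture()] table to the (species, group) summary
#' layout of [summarize_groups()]: undetectable cells become mean = SD = 0
#' with `detectable = FALSE`; n is 3 throughout (the published design).
#'
#' @param fix A fixture table.
#' @return Data frame with `species`, `group`, `n`, `mean`, `sd`,
#'   `detectable`.
#' @export
fixture_group_summaries <- function(fix) {
  out <- list()
  for (g in .GROUP_LEVELS) {
    mu <- fix[[paste0(g, "_mean")]]
    sdv <- fix[[paste0(g, "_sd")]]
    det <- !is.na(mu)
    out[[g]] <- data.frame(species = fix$species_id, group = g, n = 3L,
                           mean = ifelse(det, mu, 0),
                           sd = ifelse(det, sdv, 0),
                           detectable = det, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcribed significance markers from a fixture table
#'
#' Converts the printed markers into the significance layout consumed by
#' [classify_modulation()] (marker mode).
#'
#' @param fix A fixture table.
#' @return Data frame with `species`, `sig_model_vs_control`,
#'   `sig_treated_vs_model` (logicals).
#' @export
fixture_markers <- function(fix) {
  data.frame(species = fix$species_id,
             sig_model_vs_control = nzchar(fix$sig_model_vs_control),
             sig_treated_vs_model = nzchar(fix$sig_treated_vs_model),
             stringsAsFactors = FALSE)
}
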