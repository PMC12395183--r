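# Reserved species token marking a community-pooled litter row.
POOLED_TOKEN <- "__community__"

.survey_cols <- c("plot_id", "species", "biomass", "leaf_C", "leaf_N", "leaf_P")
.litter_cols <- c("plot_id", "species", "senesced_N", "senesced_P")
.soil_cols   <- c("plot_id", "elevation", "TN", "TP")

#' Reserved token for community-pooled litter rows
#'
#' Litter collected at the whole-plot level (typical for herbaceous
#' vegetation, where senesced leaves cannot be attributed to species) is
#' stored with this string in the `species` column.
#'
#' @return The reserved token, a length-one character vector.
#' @export
pooled_token <- function() POOLED_TOKEN

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.read_delim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep) || identical(sep, "auto")) sep <- .detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

.apply_header_map <- function(df, header_map) {
  if (is.null(header_map) || length(header_map) == 0L) return(df)
  # header_map: named list/vector, names are canonical, values are user headers
  for (canon in names(header_map)) {
    user <- header_map[[canon]]
    hit <- which(names(df) == user)
    if (length(hit)) names(df)[hit[1L]] <- canon
  }
  df
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.coerce_numeric <- function(df, cols, what) {
  for (col in intersect(cols, names(df))) {
    v <- df[[col]]
    if (is.numeric(v)) next
    suppressWarnings(num <- as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad)) {
      stop(sprintf("%s table: non-numeric value in column '%s' at row %d ('%s')",
                   what, col, bad[1L], as.character(v[bad[1L]])), call. = FALSE)
    }
    df[[col]] <- num
  }
  df
}

#' Read a vegetation survey table
#'
#' Reads the per-species survey table: one row per (plot, species) with dry
#' biomass (g/m2 or a relative share) and green-leaf C, N and P concentrations
#' in g/kg. Extra columns (e.g. `density`, `elevation`) are preserved.
#'
#' @param path Path to a CSV or TSV file (UTF-8, `.` decimal separator).
#' @param sep Field separator; `"auto"` (default) detects comma vs tab.
#' @param header_map Optional named list translating user headers to the
#'   canonical lower-snake-case names, e.g. `list(leaf_N = "N_green")`.
#' @return A `data.frame` with at least columns `plot_id`, `species`,
#'   `biomass`, `leaf_C`, `leaf_N`, `leaf_P`; row order as in the file.
#' @export
read_survey_table <- function(path, sep = "auto", header_map = NULL) {
  df <- .apply_header_map(.read_delim(path, sep), header_map)
  .require_cols(df, .survey_cols, "survey")
  df <- .coerce_numeric(df, c("biomass", "leaf_C", "leaf_N", "leaf_P",
                              "density", "elevation"), "survey")
  df$plot_id <- as.character(df$plot_id)
  df$species <- as.character(df$species)
  df
}

#' Read a leaf-litter table
#'
#' Senesced-leaf N and P concentrations (g/kg), either one row per species
#' or a single pooled row per plot carrying the reserved species token
#' [pooled_token()].
#'
#' @inheritParams read_survey_table
#' @return A `data.frame` with columns `plot_id`, `species`, `senesced_N`,
#'   `senesced_P`.
#' @export
read_litter_table <- function(path, sep = "auto", header_map = NULL) {
  df <- .apply_header_map(.read_delim(path, sep), header_map)
  .require_cols(df, .litter_cols, "litter")
  df <- .coerce_numeric(df, c("senesced_N", "senesced_P"), "litter")
  df$plot_id <- as.character(df$plot_id)
  df$species <- as.character(df$species)
  df
}

#' Read a soil table
#'
#' One row per plot with elevation (m) and total soil N and P (g/kg); optional
#' physicochemical columns (AN, AP in mg/kg; SWC in %; pH; EC; SOC, POC, MAOC
#' in g/kg; TS) are carried through untouched and merely widen which
#' downstream analyses can run.
#'
#' @inheritParams read_survey_table
#' @return A `data.frame` with at least columns `plot_id`, `elevation`,
#'   `TN`, `TP`.
#' @export
read_soil_table <- function(path, sep = "auto", header_map = NULL) {
  df <- .apply_header_map(.read_delim(path, sep), header_map)
  .require_cols(df, .soil_cols, "soil")
  df <- .coerce_numeric(df, c("elevation", "TN", "TP", "AN", "AP", "SWC",
                              "pH", "EC", "SOC", "POC", "MAOC", "TS"), "soil")
  df$plot_id <- as.character(df$plot_id)
  df
}

#' Write a result or input table
#'
#' Plain CSV writer used for all package outputs: UTF-8, `.` decimal, no row
#' names, full `digits = 15` precision so a write/read round trip reproduces
#' values exactly to printed precision.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format(df[[j]], digits = 15, trim = TRUE,
                                           scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.report_row <- function(check, plot_id, detail) {
  data.frame(check = check, plot_id = plot_id, detail = detail,
             stringsAsFactors = FALSE)
}

#' Validate a survey/litter/soil dataset
#'
#' Pure reporting operation: checks cross-table consistency (every surveyed
#' plot has litter and soil rows), positivity of concentrations, duplicate
#' keys, and that pooled and species-level litter rows are not mixed within a
#' plot. Nothing is mutated; an empty report means the dataset is
#' analysis-ready.
#'
#' @param survey Survey table as from [read_survey_table()].
#' @param litter Litter table as from [read_litter_table()].
#' @param soil Soil table as from [read_soil_table()].
#' @return A `data.frame` with columns `check`, `plot_id`, `detail`; zero rows
#'   if and only if no issue was found.
#' @export
validate_dataset <- function(survey, litter, soil) {
  rep <- list()
  plots <- unique(survey$plot_id)

  for (p in setdiff(plots, unique(litter$plot_id)))
    rep[[length(rep) + 1L]] <- .report_row("missing_litter", p, "no litter rows for surveyed plot")
  for (p in setdiff(plots, unique(soil$plot_id)))
    rep[[length(rep) + 1L]] <- .report_row("missing_soil", p, "no soil row for surveyed plot")

  key <- paste(survey$plot_id, survey$species, sep = "\r")
  dup <- unique(key[duplicated(key)])
  for (k in dup) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    rep[[length(rep) + 1L]] <- .report_row("duplicate_key", parts[1L],
                                           sprintf("duplicated (plot, species) = (%s, %s)", parts[1L], parts[2L]))
  }

  bad <- which(!is.na(survey$biomass) & survey$biomass < 0)
  for (i in bad)
    rep[[length(rep) + 1L]] <- .report_row("negative_biomass", survey$plot_id[i],
                                           sprintf("species %s biomass %g", survey$species[i], survey$biomass[i]))
  for (col in c("leaf_C", "leaf_N", "leaf_P")) {
    bad <- which(!is.na(survey[[col]]) & survey[[col]] <= 0)
    for (i in bad)
      rep[[length(rep) + 1L]] <- .report_row("nonpositive_concentration", survey$plot_id[i],
                                             sprintf("survey %s = %g (species %s)", col, survey[[col]][i], survey$species[i]))
  }
  for (col in c("senesced_N", "senesced_P")) {
    bad <- which(!is.na(litter[[col]]) & litter[[col]] <= 0)
    for (i in bad)
      rep[[length(rep) + 1L]] <- .report_row("nonpositive_concentration", litter$plot_id[i],
                                             sprintf("litter %s = %g (species %s)", col, litter[[col]][i], litter$species[i]))
  }
  for (col in c("TN", "TP")) {
    bad <- which(!is.na(soil[[col]]) & soil[[col]] <= 0)
    for (i in bad)
      rep[[length(rep) + 1L]] <- .report_row("nonpositive_concentration", soil$plot_id[i],
                                             sprintf("soil %s = %g", col, soil[[col]][i]))
  }

  # pooled and species rows are mutually exclusive within a plot
  for (p in unique(litter$plot_id)) {
    sp <- litter$species[litter$plot_id == p]
    if (any(sp == POOLED_TOKEN) && any(sp != POOLED_TOKEN))
      rep[[length(rep) + 1L]] <- .report_row("mixed_litter_mode", p,
                                             "plot mixes pooled and species-level litter rows")
  }

  if (length(rep)) do.call(rbind, rep) else
    data.frame(check = character(), plot_id = character(), detail = character(),
               stringsAsFactors = FALSE)
}

#' Read a flat YAML configuration file
#'
#' Configuration is a flat key-value YAML document, optionally grouped under
#' the sections `input`, `resorption`, `homeostasis`, `gradient` and
#' `simulate`. Returns the parsed list unchanged; callers pick the keys they
#' understand.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
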