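.stage_record <- function(name, status, detail = "", outputs = character()) {
  list(name = name, status = status, detail = detail, outputs = outputs)
}

# Collect warnings raised by expr into the shared warning log.
.with_warnings <- function(expr, log_env, stage) {
  withCallingHandlers(expr, warning = function(w) {
    log_env$warnings <- rbind(log_env$warnings,
                              data.frame(stage = stage,
                                         message = conditionMessage(w),
                                         stringsAsFactors = FALSE))
    invokeRestart("muffleWarning")
  })
}

#' Run the full stoichiometry pipeline
#'
#' Orchestrates every stage end-to-end: community traits, resorption,
#' control-strategy classification, homeostasis, nutrient limitation and
#' elevation gradients, writing one CSV per stage plus `warnings.csv` (every
#' warning any stage raised, so excluded species or flagged plots are never
#' silent) and a JSON run manifest. Inputs are either the three tables of a
#' simulated dataset (`sim`) or file paths. A failing stage is recorded in
#' the manifest and its downstream-dependent stages are skipped; stages with
#' missing inputs (e.g. no soil table) are skipped with a logged reason.
#' Analysis stages are deterministic: rerunning on identical inputs
#' reproduces every result table byte for byte.
#'
#' @param out_dir Output directory, created if needed.
#' @param sim Optional `"stoich_sim"` object; its tables are used directly
#'   and also written to `out_dir`.
#' @param survey,litter,soil Paths to input tables (ignored when `sim` is
#'   given). `litter` and `soil` may be `NULL`, skipping the stages that
#'   need them.
#' @param mlcf Mass loss correction factor.
#' @param pooling Litter pooling mode, see [community_resorption()].
#' @param alpha Significance level for CIs and homeostasis.
#' @param diversity_weight Abundance column for diversity indices, see
#'   [community_traits()].
#' @param gradient_responses Columns fitted against elevation.
#' @param criterion Model-selection criterion, see [select_best()].
#' @return The run manifest (list), invisibly. Side effects: result tables,
#'   `warnings.csv` and `run_manifest.json` under `out_dir`.
#' @export
run_all <- function(out_dir, sim = NULL, survey = NULL, litter = NULL,
                    soil = NULL, mlcf = 0.762,
                    pooling = c("auto", "pooled", "species"), alpha = 0.05,
                    diversity_weight = c("density", "biomass"),
                    gradient_responses = c("LTC", "LTN", "LTP", "ratio_CN",
                                           "ratio_CP", "ratio_NP", "NRE",
                                           "PRE", "ratio_NRE_PRE", "shannon"),
                    criterion = "aicc") {
  pooling <- match.arg(pooling)
  diversity_weight <- match.arg(diversity_weight)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_env <- new.env()
  log_env$warnings <- data.frame(stage = character(), message = character(),
                                 stringsAsFactors = FALSE)
  stages <- list()
  outputs <- character()
  emit <- function(df, file) {
    write_table(df, file.path(out_dir, file))
    outputs <<- c(outputs, file)
    file
  }

  ## resolve inputs
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "stoich_sim"))
    survey_df <- sim$survey; litter_df <- sim$litter; soil_df <- sim$soil
    write_dataset(sim, out_dir)
    outputs <- c(outputs, "survey.csv", "litter.csv", "soil.csv", "truth.json")
  } else {
    if (is.null(survey)) stop("either `sim` or `survey` must be supplied", call. = FALSE)
    survey_df <- read_survey_table(survey)
    litter_df <- if (!is.null(litter)) read_litter_table(litter)
    soil_df <- if (!is.null(soil)) read_soil_table(soil)
  }

  traits <- NULL
  resorp <- NULL

  ## stage: community traits
  stages$traits <- tryCatch({
    traits <- .with_warnings(
      community_traits(survey_df, diversity_weight = diversity_weight,
                       elevations = soil_df),
      log_env, "traits")
    .stage_record("traits", "completed",
                  outputs = emit(traits, "community_traits.csv"))
  }, error = function(e) .stage_record("traits", "failed", conditionMessage(e)))

  ## stage: resorption
  stages$resorption <- if (is.null(traits)) {
    .stage_record("resorption", "skipped", "traits stage failed")
  } else if (is.null(litter_df)) {
    .stage_record("resorption", "skipped", "no litter table")
  } else tryCatch({
    resorp <- .with_warnings(
      resorption_table(traits, litter_df, mlcf = mlcf, pooling = pooling,
                       survey = survey_df),
      log_env, "resorption")
    .stage_record("resorption", "completed",
                  outputs = emit(resorp, "resorption.csv"))
  }, error = function(e) .stage_record("resorption", "failed", conditionMessage(e)))

  ## stage: control strategy
  stages$strategy <- if (is.null(resorp)) {
    .stage_record("strategy", "skipped", "resorption unavailable")
  } else tryCatch({
    m <- match(resorp$plot_id, traits$plot_id)
    cs <- control_strategy(traits$ratio_NP[m], resorp$resorbed_NP, alpha = alpha)
    tab <- data.frame(omega = cs$omega, lambda = cs$lambda,
                      lambda_lo = cs$lambda_ci[1L], lambda_hi = cs$lambda_ci[2L],
                      linear_slope = cs$linear_slope,
                      linear_slope_lo = cs$linear_slope_ci[1L],
                      linear_slope_hi = cs$linear_slope_ci[2L],
                      r_squared_power = cs$r_squared_power,
                      r_squared_linear = cs$r_squared_linear,
                      n_used = cs$n_used, n_excluded = cs$n_excluded,
                      label = cs$label, stringsAsFactors = FALSE)
    .stage_record("strategy", "completed",
                  outputs = emit(tab, "control_strategy.csv"))
  }, error = function(e) .stage_record("strategy", "failed", conditionMessage(e)))

  ## stage: homeostasis
  stages$homeostasis <- if (is.null(traits)) {
    .stage_record("homeostasis", "skipped", "traits stage failed")
  } else if (is.null(soil_df)) {
    .stage_record("homeostasis", "skipped", "no soil table")
  } else tryCatch({
    hm <- homeostasis_table(traits, soil_df, alpha = alpha)
    .stage_record("homeostasis", "completed",
                  outputs = emit(hm, "homeostasis.csv"))
  }, error = function(e) .stage_record("homeostasis", "failed", conditionMessage(e)))

  ## stage: limitation
  stages$limitation <- if (is.null(traits)) {
    .stage_record("limitation", "skipped", "traits stage failed")
  } else tryCatch({
    lim <- limitation_table(traits)
    .stage_record("limitation", "completed",
                  outputs = emit(lim, "limitation.csv"))
  }, error = function(e) .stage_record("limitation", "failed", conditionMessage(e)))

  ## stage: gradient
  stages$gradient <- if (is.null(traits) || !"elevation" %in% names(traits)) {
    .stage_record("gradient", "skipped", "no elevation available")
  } else tryCatch({
    tab <- traits
    if (!is.null(resorp))
      tab <- merge(tab, resorp[c("plot_id", "NRE", "PRE", "ratio_NRE_PRE")],
                   by = "plot_id", all.x = TRUE, sort = FALSE)
    resp <- intersect(gradient_responses, names(tab))
    gr <- .with_warnings(gradient_table(tab, resp, criterion = criterion),
                         log_env, "gradient")
    .stage_record("gradient", "completed",
                  outputs = emit(gr, "gradient_fits.csv"))
  }, error = function(e) .stage_record("gradient", "failed", conditionMessage(e)))

  emit(log_env$warnings, "warnings.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecostoich")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = list(mlcf = mlcf, pooling = pooling, alpha = alpha,
                      diversity_weight = diversity_weight,
                      criterion = criterion),
    stages = stages,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
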