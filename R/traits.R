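#' Community-weighted mean of a trait
#'
#' The biomass-proportion-weighted mean `sum(t_i * w_i / sum(w))`. Weights are
#' normalised internally, so any positive rescaling of `weights` leaves the
#' result unchanged.
#'
#' @param trait_values Numeric vector of species trait values.
#' @param weights Non-negative weights (typically species biomass), same
#'   length as `trait_values`, not all zero.
#' @return The weighted mean, a single number bounded by
#'   `range(trait_values)`.
#' @export
cwm <- function(trait_values, weights) {
  if (length(trait_values) != length(weights))
    stop("trait_values and weights must have equal length", call. = FALSE)
  if (length(trait_values) < 1L)
    stop("at least one species is required", call. = FALSE)
  if (any(weights < 0, na.rm = TRUE))
    stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (!is.finite(s) || s <= 0)
    stop("degenerate weights: sum of weights must be positive", call. = FALSE)
  sum(trait_values * weights) / s
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * ln p_i)` with `p_i = n_i / N`, natural logarithm, where
#' `n_i` is the abundance (individual density or biomass) of species i. Zero
#' abundances are dropped before computing proportions.
#'
#' @param abundances Non-negative abundances, at least one positive.
#' @return Diversity in nats; 0 for a single species, `ln(S)` when all S
#'   species are equally abundant.
#' @export
shannon <- function(abundances) {
  x <- abundances[!is.na(abundances)]
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  x <- x[x > 0]
  if (length(x) < 1L)
    stop("no positive abundances remain after dropping zeros", call. = FALSE)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `E = H' / ln(S)` with S the number of species with positive abundance.
#' Undefined for a single species (`ln 1 = 0`); returned as `NA` rather than
#' an error so one-species plots flow through tables.
#'
#' @inheritParams shannon
#' @return Evenness in `[0, 1]`, or `NA_real_` when `S == 1`.
#' @export
pielou <- function(abundances) {
  x <- abundances[!is.na(abundances)]
  x <- x[x > 0]
  s <- length(x)
  if (s < 1L)
    stop("no positive abundances remain after dropping zeros", call. = FALSE)
  if (s == 1L) return(NA_real_)
  shannon(x) / log(s)
}

#' Aggregate one plot's species observations into community nutrients
#'
#' Computes the community-weighted leaf C, N and P (LTC, LTN, LTP, g/kg) as
#' biomass-proportion-weighted means over the plot's species, and the
#' stoichiometric ratios of those aggregates. Species missing any of the
#' three concentrations (or with non-positive biomass) are excluded from the
#' weighted means with a warning; they still count toward diversity, which is
#' computed elsewhere.
#'
#' @param observations Data frame of one plot's survey rows with columns
#'   `species`, `biomass`, `leaf_C`, `leaf_N`, `leaf_P`.
#' @return A one-row data frame with `LTC`, `LTN`, `LTP`, `ratio_CN`,
#'   `ratio_CP`, `ratio_NP`, `richness`, `total_biomass`, `n_excluded`.
#' @export
community_nutrients <- function(observations) {
  stopifnot(is.data.frame(observations))
  ok <- !is.na(observations$biomass) & observations$biomass > 0 &
    !is.na(observations$leaf_C) & !is.na(observations$leaf_N) &
    !is.na(observations$leaf_P)
  if (!any(ok))
    stop("empty plot: no species with positive biomass and complete leaf traits",
         call. = FALSE)
  if (any(!ok)) {
    warning(sprintf("excluding %d species with missing traits or non-positive biomass: %s",
                    sum(!ok), paste(observations$species[!ok], collapse = ", ")),
            call. = FALSE)
  }
  use <- observations[ok, , drop = FALSE]
  w <- use$biomass
  ltc <- cwm(use$leaf_C, w)
  ltn <- cwm(use$leaf_N, w)
  ltp <- cwm(use$leaf_P, w)
  data.frame(
    LTC = ltc, LTN = ltn, LTP = ltp,
    ratio_CN = ltc / ltn, ratio_CP = ltc / ltp, ratio_NP = ltn / ltp,
    richness = nrow(observations),
    total_biomass = sum(observations$biomass, na.rm = TRUE),
    n_excluded = sum(!ok),
    stringsAsFactors = FALSE
  )
}

#' Community trait table for all plots
#'
#' Applies [community_nutrients()], [shannon()] and [pielou()] per plot.
#' Diversity is weighted by the `density` column when present and
#' `diversity_weight = "density"` (the Magurran convention, using individual
#' counts), otherwise by biomass share.
#'
#' @param survey Survey table as from [read_survey_table()].
#' @param diversity_weight `"density"` (default; falls back to biomass when no
#'   density column exists) or `"biomass"`.
#' @param elevations Optional named vector or data frame (`plot_id`,
#'   `elevation`) supplying plot elevations, e.g. from the soil table.
#' @return A data frame with one row per plot: identifiers, elevation (if
#'   known), LTC/LTN/LTP, ratios, `shannon`, `pielou`, `richness`,
#'   `total_biomass`.
#' @export
community_traits <- function(survey, diversity_weight = c("density", "biomass"),
                             elevations = NULL) {
  diversity_weight <- match.arg(diversity_weight)
  use_density <- diversity_weight == "density" && "density" %in% names(survey)
  plots <- unique(survey$plot_id)
  rows <- lapply(plots, function(p) {
    obs <- survey[survey$plot_id == p, , drop = FALSE]
    nut <- community_nutrients(obs)
    ab <- if (use_density) obs$density else obs$biomass
    cbind(data.frame(plot_id = p, stringsAsFactors = FALSE),
          nut,
          data.frame(shannon = shannon(ab), pielou = pielou(ab)))
  })
  out <- do.call(rbind, rows)

  elev <- NULL
  if (!is.null(elevations)) {
    if (is.data.frame(elevations)) {
      elev <- elevations$elevation[match(out$plot_id, elevations$plot_id)]
    } else {
      elev <- unname(elevations[out$plot_id])
    }
  } else if ("elevation" %in% names(survey)) {
    first <- survey[!duplicated(survey$plot_id), c("plot_id", "elevation")]
    elev <- first$elevation[match(out$plot_id, first$plot_id)]
  }
  if (!is.null(elev)) out <- cbind(out[1L], elevation = elev, out[-1L])
  rownames(out) <- NULL
  out
}
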