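#' Nutrient resorption efficiency with mass-loss correction
#'
#' `NuRE = (1 - (senesced / green) * MLCF) * 100`, the percentage of a
#' nutrient withdrawn from leaves before abscission. The mass loss correction
#' factor (MLCF) accounts for leaf dry mass lost during senescence, which
#' concentrates nutrients in the remaining tissue and would otherwise inflate
#' apparent resorption; 0.762 is the correction used for the communities this
#' package targets (Vergutz et al. supply growth-form-specific values).
#'
#' @param green Green-leaf nutrient concentration (g/kg), > 0.
#' @param senesced Senesced-leaf concentration (g/kg), >= 0.
#' @param mlcf Mass loss correction factor in (0, 1]; default 0.762.
#' @return Resorption efficiency in percent (vectorised). 100 when
#'   `senesced = 0`; can be negative (nutrient accretion) when senesced
#'   concentrations exceed `green / mlcf`.
#' @export
nure <- function(green, senesced, mlcf = 0.762) {
  if (any(!is.finite(green) | green <= 0))
    stop("green-leaf concentration must be positive", call. = FALSE)
  if (any(senesced < 0, na.rm = TRUE))
    stop("senesced concentration must be non-negative", call. = FALSE)
  if (any(!is.finite(mlcf) | mlcf <= 0 | mlcf > 1))
    stop("mlcf must lie in (0, 1]", call. = FALSE)
  (1 - (senesced / green) * mlcf) * 100
}

#' Ratio of absolute resorbed N to resorbed P
#'
#' `(LTN - LTN_s * MLCF) / (LTP - LTP_s * MLCF)`: the amounts of N and P
#' withdrawn per unit leaf mass, as a ratio. Undefined (returned as `NA`) when
#' either resorbed amount is non-positive, i.e. when the community accreted
#' rather than resorbed that nutrient.
#'
#' @param LTN,LTP Green-leaf community N and P (g/kg), > 0.
#' @param LTN_s,LTP_s Senesced-leaf community N and P (g/kg), > 0.
#' @inheritParams nure
#' @return The resorbed N:P ratio (vectorised), or `NA_real_` where undefined.
#' @export
resorbed_np <- function(LTN, LTP, LTN_s, LTP_s, mlcf = 0.762) {
  if (any(c(LTN, LTP, LTN_s, LTP_s) <= 0, na.rm = TRUE))
    stop("all concentrations must be positive", call. = FALSE)
  num <- LTN - LTN_s * mlcf
  den <- LTP - LTP_s * mlcf
  out <- num / den
  out[num <= 0 | den <= 0] <- NA_real_
  out
}

.community_senesced <- function(litter, survey_plot, pooling) {
  pooled <- litter$species == POOLED_TOKEN
  mode <- switch(pooling,
                 auto = if (any(pooled)) "pooled" else "species",
                 pooling)
  if (mode == "pooled") {
    if (!any(pooled)) stop("pooling = 'pooled' but no pooled litter row", call. = FALSE)
    row <- litter[pooled, , drop = FALSE][1L, ]
    return(c(N = row$senesced_N, P = row$senesced_P))
  }
  sp <- litter[!pooled, , drop = FALSE]
  if (nrow(sp) == 0L) stop("no species-level litter rows", call. = FALSE)
  w <- NULL
  if (!is.null(survey_plot)) {
    w <- survey_plot$biomass[match(sp$species, survey_plot$species)]
  }
  if (is.null(w) || any(is.na(w))) {
    warning("litter species absent from survey; using unweighted mean of senesced concentrations",
            call. = FALSE)
    w <- rep(1, nrow(sp))
  }
  c(N = cwm(sp$senesced_N, w), P = cwm(sp$senesced_P, w))
}

#' Community-level resorption efficiencies for one plot
#'
#' Pools the plot's litter to community senesced N and P — either the pooled
#' row (herbaceous plots, where litter is collected unclassified) or a
#' biomass-proportion-weighted mean over species-level rows (shrub plots) —
#' then computes NRE and PRE via [nure()], their ratio, and the resorbed N:P
#' ratio via [resorbed_np()].
#'
#' @param green One-row community sample with columns `LTN`, `LTP` (and
#'   optionally `plot_id`), as produced by [community_nutrients()].
#' @param litter Litter rows for this plot.
#' @param mlcf Mass loss correction factor; default 0.762.
#' @param pooling `"auto"` (pooled row if present, else species-weighted),
#'   `"pooled"`, or `"species"`.
#' @param survey_plot Optional survey rows for the plot, supplying biomass
#'   weights for species-level litter; without them an unweighted mean is
#'   used with a warning.
#' @return A one-row data frame: `plot_id`, `NRE`, `PRE`, `ratio_NRE_PRE`,
#'   `resorbed_NP`, `flags` (`;`-joined, empty when clean).
#' @export
community_resorption <- function(green, litter, mlcf = 0.762,
                                 pooling = c("auto", "pooled", "species"),
                                 survey_plot = NULL) {
  pooling <- match.arg(pooling)
  if (nrow(litter) == 0L) stop("litter is empty for this plot", call. = FALSE)
  sen <- .community_senesced(litter, survey_plot, pooling)
  nre <- nure(green$LTN, sen[["N"]], mlcf)
  pre <- nure(green$LTP, sen[["P"]], mlcf)
  rnp <- resorbed_np(green$LTN, green$LTP, sen[["N"]], sen[["P"]], mlcf)
  flags <- character()
  if (nre <= 0 || pre <= 0) flags <- c(flags, "negative-resorption")
  if (is.na(rnp)) flags <- c(flags, "undefined-resorbed-ratio", "excluded-from-fit")
  ratio <- if (pre > 0) nre / pre else NA_real_
  data.frame(
    plot_id = if ("plot_id" %in% names(green)) green$plot_id else NA_character_,
    NRE = nre, PRE = pre, ratio_NRE_PRE = ratio, resorbed_NP = rnp,
    senesced_N = sen[["N"]], senesced_P = sen[["P"]],
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Resorption table for all plots
#'
#' Joins the community trait table with the litter table and applies
#' [community_resorption()] per plot.
#'
#' @param traits Community trait table from [community_traits()].
#' @param litter Litter table from [read_litter_table()].
#' @inheritParams community_resorption
#' @param survey Optional full survey table (for biomass weights).
#' @return Data frame with one row per plot that has litter.
#' @export
resorption_table <- function(traits, litter, mlcf = 0.762,
                             pooling = c("auto", "pooled", "species"),
                             survey = NULL) {
  pooling <- match.arg(pooling)
  plots <- intersect(traits$plot_id, unique(litter$plot_id))
  rows <- lapply(plots, function(p) {
    community_resorption(
      traits[traits$plot_id == p, , drop = FALSE],
      litter[litter$plot_id == p, , drop = FALSE],
      mlcf = mlcf, pooling = pooling,
      survey_plot = if (!is.null(survey)) survey[survey$plot_id == p, , drop = FALSE]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the community nutrient-resorption control strategy
#'
#' Fits two regressions of the resorbed N:P ratio on the green-leaf N:P
#' ratio: a power law `resorbed = omega * ratio^lambda` via ordinary least
#' squares on log10-log10 axes (lambda = slope, omega = 10^intercept), and a
#' plain linear regression on the original scale. Each slope gets a t-based
#' 95% confidence interval; the strategy label follows from whether the CIs
#' contain 1:
#'
#' * both CIs contain 1 — `"stoichiometric control"`: N and P are resorbed in
#'   proportion to green-leaf stoichiometry;
#' * the power-law CI excludes 1 — `"nutrient limitation control"`: the
#'   scarcer element is preferentially resorbed;
#' * the power-law CI contains 1 but the linear CI excludes it —
#'   `"joint regulation"`.
#'
#' Points with undefined (non-positive) resorbed N:P are excluded from both
#' fits and counted in `n_excluded`; logs are undefined there.
#'
#' @param ratio_np Green-leaf community N:P ratios.
#' @param resorbed Resorbed N:P ratios (may contain `NA` for undefined
#'   points).
#' @param alpha Significance level for the CIs; default 0.05 (95% CIs).
#' @return An object of class `"control_strategy"`: list with `omega`,
#'   `lambda`, `lambda_ci`, `linear_slope`, `linear_slope_ci`,
#'   `r_squared_power`, `r_squared_linear`, `n_used`, `n_excluded`, `label`,
#'   `alpha`, and the two `lm` fits (`fit_power`, `fit_linear`).
#' @export
control_strategy <- function(ratio_np, resorbed, alpha = 0.05) {
  if (length(ratio_np) != length(resorbed))
    stop("ratio_np and resorbed must have equal length", call. = FALSE)
  ok <- is.finite(ratio_np) & is.finite(resorbed) & ratio_np > 0 & resorbed > 0
  n_used <- sum(ok)
  n_excluded <- length(ok) - n_used
  if (n_used < 3L)
    stop(sprintf("insufficient data: %d usable points (>= 3 required)", n_used),
         call. = FALSE)
  x <- ratio_np[ok]; y <- resorbed[ok]
  d <- data.frame(lx = log10(x), ly = log10(y), x = x, y = y)
  fp <- stats::lm(ly ~ lx, data = d)
  fl <- stats::lm(y ~ x, data = d)
  ci_p <- stats::confint(fp, level = 1 - alpha)["lx", ]
  ci_l <- stats::confint(fl, level = 1 - alpha)["x", ]
  lambda <- unname(stats::coef(fp)[2L])
  omega <- unname(10^stats::coef(fp)[1L])
  slope <- unname(stats::coef(fl)[2L])
  power_has_1 <- ci_p[1L] <= 1 && 1 <= ci_p[2L]
  linear_has_1 <- ci_l[1L] <= 1 && 1 <= ci_l[2L]
  label <- if (!power_has_1) "nutrient limitation control"
    else if (linear_has_1) "stoichiometric control"
    else "joint regulation"
  structure(list(
    omega = omega, lambda = lambda, lambda_ci = unname(ci_p),
    linear_slope = slope, linear_slope_ci = unname(ci_l),
    r_squared_power = summary(fp)$r.squared,
    r_squared_linear = summary(fl)$r.squared,
    n_used = n_used, n_excluded = n_excluded,
    label = label, alpha = alpha,
    fit_power = fp, fit_linear = fl
  ), class = "control_strategy")
}

#' @export
print.control_strategy <- function(x, ...) {
  cat("Nutrient resorption control strategy\n")
  cat(sprintf("  power law : resorbed N:P = %.4g * (N:P)^%.4g\n", x$omega, x$lambda))
  cat(sprintf("  lambda    : %.4f  [%.4f, %.4f]  R^2 = %.3f\n",
              x$lambda, x$lambda_ci[1L], x$lambda_ci[2L], x$r_squared_power))
  cat(sprintf("  lin slope : %.4f  [%.4f, %.4f]  R^2 = %.3f\n",
              x$linear_slope, x$linear_slope_ci[1L], x$linear_slope_ci[2L],
              x$r_squared_linear))
  cat(sprintf("  n used = %d, excluded = %d\n", x$n_used, x$n_excluded))
  cat(sprintf("  strategy  : %s\n", x$label))
  invisible(x)
}

#' @export
coef.control_strategy <- function(object, ...) {
  c(omega = object$omega, lambda = object$lambda,
    linear_slope = object$linear_slope)
}

#' @export
confint.control_strategy <- function(object, parm, level = 0.95, ...) {
  out <- rbind(stats::confint(object$fit_power, "lx", level = level),
               stats::confint(object$fit_linear, "x", level = level))
  dimnames(out) <- list(c("lambda", "linear_slope"),
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %"))
  out
}

#' @export
summary.control_strategy <- function(object, ...) {
  list(power = summary(object$fit_power), linear = summary(object$fit_linear),
       label = object$label)
}

#' @export
plot.control_strategy <- function(x, ...) {
  d <- x$fit_power$model
  graphics::plot(d$lx, d$ly, xlab = "log10 green-leaf N:P",
                 ylab = "log10 resorbed N:P",
                 main = sprintf("lambda = %.3f (%s)", x$lambda, x$label), ...)
  graphics::abline(x$fit_power, col = "tomato", lwd = 2)
  graphics::abline(stats::coef(x$fit_power)[1L], 1, lty = 2, col = "grey40")
  invisible(x)
}
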