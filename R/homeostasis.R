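#' Persson classification of the homeostasis index
#'
#' Applies the banded classification of the homeostasis coefficient H: when
#' the underlying regression is not significant (`p_value > alpha`) the trait
#' does not track the soil at all and the state is `"absolute steady state"`;
#' otherwise `H >= 4` is `"steady state"`, `2 <= H < 4` `"weak steady state"`,
#' `1.33 <= H < 2` `"weak sensitive state"` and `H < 1.33`
#' `"sensitive state"`. Band endpoints are inclusive on the left.
#'
#' @param H Homeostasis index, positive (may be `Inf`).
#' @param p_value P-value of the log-log regression slope.
#' @param alpha Significance level; default 0.05.
#' @return The state label, a character scalar.
#' @export
classify_homeostasis <- function(H, p_value, alpha = 0.05) {
  if (is.na(H) || H <= 0) stop("H must be positive (or Inf)", call. = FALSE)
  if (is.na(p_value) || p_value > alpha) return("absolute steady state")
  # band comparisons tolerate ~1e-9 relative float error so a fitted H that
  # lands exactly on an edge classifies deterministically
  ge <- function(a, b) a >= b - 1e-9 * b
  if (ge(H, 4)) "steady state"
  else if (ge(H, 2)) "weak steady state"
  else if (ge(H, 1.33)) "weak sensitive state"
  else "sensitive state"
}

#' Fit the stoichiometric homeostasis index H
#'
#' Fits `lg y = lg c + lg x / H` by ordinary least squares of `log10(y)` on
#' `log10(x)`, where `x` is the soil stoichiometry (a concentration or a
#' ratio) and `y` the matching plant community value. The slope is `1/H`:
#' small slopes mean strong internal regulation (large H). When the
#' regression is not significant at `alpha`, or the fitted slope is
#' non-positive, the plant trait is taken to be decoupled from the soil and H
#' is flagged infinite with the label `"absolute steady state"`. The base of
#' the logarithm cancels from the slope, so any fixed base yields the same H;
#' base 10 is the convention in this literature.
#'
#' @param soil_x Positive soil values (one per plot).
#' @param plant_y Positive plant community values, same length.
#' @param alpha Significance level; default 0.05.
#' @param trait Optional trait name (e.g. `"N"`, `"P"`, `"N:P"`) carried into
#'   the result.
#' @return An object of class `"homeostasis_fit"`: list with `trait`, `H`
#'   (positive or `Inf`), `c`, `slope` (= 1/H when finite), `p_value`,
#'   `r_squared`, `n`, `label`, `alpha` and the underlying `lm` in `fit`.
#' @export
fit_homeostasis <- function(soil_x, plant_y, alpha = 0.05, trait = NA_character_) {
  if (length(soil_x) != length(plant_y))
    stop("soil_x and plant_y must have equal length", call. = FALSE)
  ok <- is.finite(soil_x) & is.finite(plant_y)
  soil_x <- soil_x[ok]; plant_y <- plant_y[ok]
  if (length(soil_x) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  if (any(soil_x <= 0) || any(plant_y <= 0))
    stop("soil and plant values must be positive", call. = FALSE)
  if (stats::sd(soil_x) == 0)
    stop("degenerate regressor: soil_x is constant", call. = FALSE)
  d <- data.frame(lx = log10(soil_x), ly = log10(plant_y))
  fit <- stats::lm(ly ~ lx, data = d)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  p <- sm$coefficients["lx", "Pr(>|t|)"]
  cc <- unname(10^stats::coef(fit)[1L])
  if (p > alpha || slope <= 0) {
    H <- Inf
    label <- "absolute steady state"
  } else {
    H <- 1 / slope
    label <- classify_homeostasis(H, p, alpha)
  }
  structure(list(
    trait = trait, H = H, c = cc, slope = slope, p_value = p,
    r_squared = sm$r.squared, n = length(soil_x), label = label,
    alpha = alpha, fit = fit
  ), class = "homeostasis_fit")
}

#' @export
print.homeostasis_fit <- function(x, ...) {
  cat("Stoichiometric homeostasis fit")
  if (!is.na(x$trait)) cat(" (", x$trait, ")", sep = "")
  cat("\n")
  cat(sprintf("  H = %s, c = %.4g, slope = %.4g\n",
              if (is.finite(x$H)) sprintf("%.4g", x$H) else "Inf", x$c, x$slope))
  cat(sprintf("  p = %.4g, R^2 = %.3f, n = %d\n", x$p_value, x$r_squared, x$n))
  cat(sprintf("  state: %s\n", x$label))
  invisible(x)
}

#' @export
coef.homeostasis_fit <- function(object, ...) {
  c(H = object$H, c = object$c, slope = object$slope)
}

#' @export
plot.homeostasis_fit <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d$lx, d$ly, xlab = "log10 soil stoichiometry",
                 ylab = "log10 plant stoichiometry",
                 main = sprintf("H = %s (%s)",
                                if (is.finite(x$H)) sprintf("%.3g", x$H) else "Inf",
                                x$label), ...)
  if (x$p_value <= x$alpha) graphics::abline(x$fit, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Classify nutrient limitation from the leaf N:P ratio
#'
#' Threshold classification of which nutrient limits growth:
#' * `guesewell_10_20`: N:P < 10 N-limited, 10-20 co-limited, > 20 P-limited;
#' * `koerselman_14_16`: N:P < 14 N-limited, 14-16 co-limited, > 16 P-limited.
#'
#' Interval endpoints belong to the co-limited class (closed interval).
#'
#' @param ratio_NP Positive leaf N:P ratio(s).
#' @param scheme `"guesewell_10_20"` (default) or `"koerselman_14_16"`.
#' @return Character vector of labels: `"N-limited"`, `"co-limited"`,
#'   `"P-limited"`.
#' @export
classify_limitation <- function(ratio_NP, scheme = c("guesewell_10_20", "koerselman_14_16")) {
  scheme <- match.arg(scheme)
  if (any(ratio_NP <= 0, na.rm = TRUE))
    stop("ratio_NP must be positive", call. = FALSE)
  th <- switch(scheme,
               guesewell_10_20 = c(10, 20),
               koerselman_14_16 = c(14, 16))
  ifelse(is.na(ratio_NP), NA_character_,
         ifelse(ratio_NP < th[1L], "N-limited",
                ifelse(ratio_NP > th[2L], "P-limited", "co-limited")))
}

#' Homeostasis table across traits
#'
#' Fits [fit_homeostasis()] for leaf N vs soil TN, leaf P vs soil TP and leaf
#' N:P vs soil TN:TP on plot-matched pairs.
#'
#' @param traits Community trait table from [community_traits()].
#' @param soil Soil table from [read_soil_table()].
#' @param which Traits to fit, subset of `c("N", "P", "NP")`.
#' @param alpha Significance level.
#' @return Data frame with one row per trait: `trait`, `H`, `c`, `slope`,
#'   `p_value`, `r_squared`, `n`, `label`.
#' @export
homeostasis_table <- function(traits, soil, which = c("N", "P", "NP"),
                              alpha = 0.05) {
  m <- match(traits$plot_id, soil$plot_id)
  ok <- !is.na(m)
  tr <- traits[ok, , drop = FALSE]
  so <- soil[m[ok], , drop = FALSE]
  pick <- list(
    N  = list(x = so$TN, y = tr$LTN, name = "N"),
    P  = list(x = so$TP, y = tr$LTP, name = "P"),
    NP = list(x = so$TN / so$TP, y = tr$ratio_NP, name = "N:P")
  )
  rows <- lapply(which, function(w) {
    p <- pick[[w]]
    f <- fit_homeostasis(p$x, p$y, alpha = alpha, trait = p$name)
    data.frame(trait = p$name, H = f$H, c = f$c, slope = f$slope,
               p_value = f$p_value, r_squared = f$r_squared, n = f$n,
               label = f$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Limitation table for all plots
#'
#' Per-plot nutrient-limitation calls under both threshold schemes.
#'
#' @param traits Community trait table from [community_traits()].
#' @return Data frame: `plot_id`, `ratio_NP`, `guesewell_10_20`,
#'   `koerselman_14_16`.
#' @export
limitation_table <- function(traits) {
  data.frame(
    plot_id = traits$plot_id,
    ratio_NP = traits$ratio_NP,
    guesewell_10_20 = classify_limitation(traits$ratio_NP, "guesewell_10_20"),
    koerselman_14_16 = classify_limitation(traits$ratio_NP, "koerselman_14_16"),
    stringsAsFactors = FALSE
  )
}
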