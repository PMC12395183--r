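# Multiply two polynomials given as coefficient vectors (lowest degree first).
.poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Convert coefficients fitted on z = (x - m)/s back to the raw-x scale.
.unscale_coefs <- function(beta, m, s) {
  out <- numeric(length(beta))
  base <- c(-m / s, 1 / s)          # z as a polynomial in x
  pw <- 1                           # z^0
  for (j in seq_along(beta)) {      # j-1 = power
    out[seq_along(pw)] <- out[seq_along(pw)] + beta[j] * pw
    if (j < length(beta)) pw <- .poly_mult(pw, base)
  }
  out
}

.aicc <- function(fit) {
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1L  # + residual variance
  # A numerically perfect fit has no defined likelihood scale: every order
  # that interpolates the data ties at -Inf and the tie-break picks the
  # lowest order.
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((fit$model[[1L]] - mean(fit$model[[1L]]))^2)
  if (rss <= 1e-12 * max(tss, .Machine$double.eps)) return(-Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

.overall_p <- function(fit) {
  fs <- summary(fit)$fstatistic
  if (is.null(fs)) return(NA_real_)
  unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
}

#' Fit polynomial elevation trends of order 1 to `max_order`
#'
#' Fits first-, second- and third-order polynomial regressions of a response
#' against elevation and reports each fit's coefficients, R-squared, adjusted
#' R-squared, AICc and overall-F p-value. Elevation is centred and scaled
#' internally for numerical conditioning (raw cubic powers of metres are
#' badly conditioned); reported coefficients are transformed back to the
#' original elevation scale, so `sum(coef * elev^(0:order))` reproduces the
#' fitted values.
#'
#' @param elevation Elevations (m).
#' @param y Response values, same length.
#' @param max_order Highest polynomial order to fit (default 3). Orders whose
#'   parameter count would leave no residual degree of freedom (`n <
#'   order + 2`) are dropped with a warning.
#' @param response Optional response name carried into the fits.
#' @return An object of class `"gradient_fits"`: a list of `"gradient_fit"`
#'   objects (fields `response`, `order`, `coefficients` intercept-first on
#'   the raw scale, `r_squared`, `adj_r_squared`, `aicc`, `p_value`, `n`,
#'   `fit`).
#' @export
fit_polynomials <- function(elevation, y, max_order = 3, response = NA_character_) {
  ok <- is.finite(elevation) & is.finite(y)
  elevation <- elevation[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3L) stop("at least 3 complete observations are required", call. = FALSE)
  if (stats::sd(elevation) == 0)
    stop("constant elevation: gradient fit is undefined", call. = FALSE)
  orders <- seq_len(max_order)
  feasible <- orders[n >= orders + 2L]
  if (length(feasible) < length(orders))
    warning(sprintf("n = %d supports only orders up to %d; higher orders dropped",
                    n, max(feasible)), call. = FALSE)
  m <- mean(elevation); s <- stats::sd(elevation)
  z <- (elevation - m) / s
  fits <- lapply(feasible, function(ord) {
    fit <- stats::lm(y ~ stats::poly(z, ord, raw = TRUE))
    sm <- summary(fit)
    structure(list(
      response = response,
      order = ord,
      coefficients = .unscale_coefs(unname(stats::coef(fit)), m, s),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      aicc = .aicc(fit),
      p_value = .overall_p(fit),
      n = n,
      fit = fit
    ), class = "gradient_fit")
  })
  structure(fits, class = "gradient_fits")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("order-%d polynomial%s: R^2 = %.3f, adj R^2 = %.3f, AICc = %.2f, p = %.3g, n = %d\n",
              x$order,
              if (is.na(x$response)) "" else paste0(" for ", x$response),
              x$r_squared, x$adj_r_squared, x$aicc, x$p_value, x$n))
  cat("  coefficients (raw scale, intercept first): ",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.gradient_fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' @export
coef.gradient_fit <- function(object, ...) object$coefficients

#' @export
predict.gradient_fit <- function(object, elevation, ...) {
  drop(outer(elevation, seq_along(object$coefficients) - 1L, `^`) %*%
         object$coefficients)
}

#' Select the best polynomial order
#'
#' Picks the fit minimising AICc (default; appropriate at the small plot
#' counts typical of gradient studies) or maximising adjusted R-squared. Ties
#' are broken toward the lower order.
#'
#' @param fits A `"gradient_fits"` list from [fit_polynomials()].
#' @param criterion `"aicc"` or `"adj_r_squared"`.
#' @return The selected `"gradient_fit"`.
#' @export
select_best <- function(fits, criterion = c("aicc", "adj_r_squared")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0L) stop("no fits to select from", call. = FALSE)
  score <- vapply(fits, function(f)
    if (criterion == "aicc") f$aicc else -f$adj_r_squared, numeric(1))
  ords <- vapply(fits, function(f) f$order, numeric(1))
  best <- order(score, ords)[1L]
  fits[[best]]
}

#' Pairwise correlation screen
#'
#' Pearson or Spearman correlations between all numeric columns, with
#' pairwise-complete handling of missing values, raw p-values and
#' Benjamini-Hochberg adjusted p-values. Cells with fewer than 3 complete
#' pairs are `NA`.
#'
#' @param table Data frame of plot-level variables; non-numeric columns are
#'   dropped.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `"cor_screen"`: list of square matrices `r`,
#'   `p`, `p_adj`, `n`, plus `method`.
#' @export
correlation_screen <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- table[vapply(table, is.numeric, logical(1))]
  if (ncol(num) < 2L) stop("need at least two numeric columns", call. = FALSE)
  k <- ncol(num); nm <- names(num)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(num[[i]], num[[j]])
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    ct <- suppressWarnings(
      stats::cor.test(num[[i]][ok], num[[j]][ok], method = method, exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  p_adj <- p
  up <- upper.tri(p)
  p_adj[up] <- stats::p.adjust(p[up], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(r = r, p = p, p_adj = p_adj, n = nmat, method = method),
            class = "cor_screen")
}

#' @export
print.cor_screen <- function(x, digits = 2, ...) {
  cat(sprintf("%s correlation screen (%d variables)\n",
              x$method, ncol(x$r)))
  print(round(x$r, digits))
  invisible(x)
}

#' Best-model gradient table for standard responses
#'
#' Convenience wrapper: for each named response column, fit polynomial orders
#' 1-3 against elevation and keep the best model per [select_best()].
#'
#' @param table Plot-level data frame containing `elevation` and the
#'   responses.
#' @param responses Character vector of column names to fit.
#' @param criterion Selection criterion, see [select_best()].
#' @param max_order Highest order to fit.
#' @return Data frame with one row per response: `response`, `order`,
#'   `b0`..`b3` (unused higher coefficients `NA`), `r_squared`,
#'   `adj_r_squared`, `aicc`, `p_value`, `n`.
#' @export
gradient_table <- function(table, responses, criterion = "aicc", max_order = 3) {
  rows <- lapply(responses, function(resp) {
    fits <- fit_polynomials(table$elevation, table[[resp]],
                            max_order = max_order, response = resp)
    best <- select_best(fits, criterion = criterion)
    cf <- rep(NA_real_, max_order + 1L)
    cf[seq_along(best$coefficients)] <- best$coefficients
    out <- data.frame(response = resp, order = best$order,
                      stringsAsFactors = FALSE)
    for (i in seq_len(max_order + 1L)) out[[paste0("b", i - 1L)]] <- cf[i]
    out$r_squared <- best$r_squared
    out$adj_r_squared <- best$adj_r_squared
    out$aicc <- best$aicc
    out$p_value <- best$p_value
    out$n <- best$n
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
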