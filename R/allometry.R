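# Allometric models G(T) = a_G * T^b_G and D(T) = a_D * T^b_D relating the
# average genome length (kbp) and capsid diameter (nm) to the icosahedral
# architecture index T.  Fitting follows the original protocol: per-T
# arithmetic averages first (to de-bias oversampled architectures such as
# T = 7), then base-10 logs of both axes, then ordinary least squares.

.fit_variables <- c("genome_kbp", "diameter_nm")

.new_allometric_fit <- function(variable, log10_a, se_log10_a, b, se_b,
                                n, r_squared, residual_sd, mean_log10_t,
                                sxx, df, x = NULL, y = NULL) {
  structure(list(
    variable = variable,
    log10_a = log10_a, se_log10_a = se_log10_a,
    b = b, se_b = se_b,
    n = n, r_squared = r_squared,
    residual_sd = residual_sd, mean_log10_t = mean_log10_t,
    sxx = sxx, df = df, x = x, y = y
  ), class = "allometric_fit")
}

.has_residual_stats <- function(fit) {
  !is.na(fit$residual_sd) && !is.na(fit$sxx) && !is.na(fit$df) &&
    !is.na(fit$mean_log10_t) && fit$df >= 1
}

#' Fit an allometric power law to (T, value) data
#'
#' Values are first averaged (arithmetically, in linear space) within each
#' distinct T, then both axes are logged base 10 and an ordinary
#' least-squares line is fitted, giving `log10(value) = log10_a + b*log10(T)`.
#'
#' @param t Architecture index for each observation (positive).
#' @param value Genome length in kbp or capsid diameter in nm (positive).
#' @param variable `"genome_kbp"` or `"diameter_nm"`.
#' @return An `"allometric_fit"` with parameters, standard errors,
#'   `r_squared`, and the residual statistics (`residual_sd`,
#'   `mean_log10_t`, `sxx`, `df`) needed for interval prediction.
#' @examples
#' t <- rep(c(4, 7, 9), each = 2)
#' fit <- fit_allometric(t, 2.34 * t^1.5, "genome_kbp")
#' fit$b  # 1.5
#' @export
fit_allometric <- function(t, value, variable = c("genome_kbp", "diameter_nm")) {
  variable <- match.arg(variable)
  stopifnot(length(t) == length(value), length(t) > 0)
  if (any(!is.finite(t)) || any(!is.finite(value))) {
    stop("t and value must be finite")
  }
  if (any(t <= 0) || any(value <= 0)) {
    stop("t and value must be positive (the model is a log-log power law)")
  }
  means <- tapply(value, factor(signif(t, 12)), mean)
  td <- as.numeric(names(means))
  if (length(td) < 3L) stop("need at least 3 distinct T values to fit")
  x <- log10(td)
  y <- log10(as.numeric(means))
  fit <- stats::lm(y ~ x)
  # noiseless synthetic inputs fit exactly; the perfect-fit warning from
  # summary.lm is expected there
  sm <- suppressWarnings(summary(fit))
  .new_allometric_fit(
    variable = variable,
    log10_a = unname(coef(fit)[1]), se_log10_a = sm$coefficients[1, 2],
    b = unname(coef(fit)[2]), se_b = sm$coefficients[2, 2],
    n = length(td), r_squared = sm$r.squared,
    residual_sd = sm$sigma, mean_log10_t = mean(x),
    sxx = sum((x - mean(x))^2), df = length(td) - 2L,
    x = x, y = y
  )
}

#' Build an evaluation-only fit from published parameters
#'
#' Wraps printed model parameters (e.g. `log10_a = 0.37`, `b = 1.47` for the
#' genome model) into a fit usable by [predict_mean()] and [inverse_t()].
#' Interval prediction and residual diagnostics require residual statistics
#' from a fresh fit and raise a capability error.
#'
#' @param log10_a Base-10 log of the pre-factor (kbp or nm units).
#' @param b Allometric exponent.
#' @param variable `"genome_kbp"` or `"diameter_nm"`.
#' @param se_log10_a,se_b Optional standard errors.
#' @return An `"allometric_fit"` without residual statistics.
#' @examples
#' g <- from_printed_params(0.37, 1.47, "genome_kbp")
#' predict_mean(g, 1)  # 2.34 kbp
#' @export
from_printed_params <- function(log10_a, b,
                                variable = c("genome_kbp", "diameter_nm"),
                                se_log10_a = NA_real_, se_b = NA_real_) {
  variable <- match.arg(variable)
  stopifnot(is.finite(log10_a), is.finite(b))
  .new_allometric_fit(variable, log10_a, se_log10_a, b, se_b,
                      n = NA_integer_, r_squared = NA_real_,
                      residual_sd = NA_real_, mean_log10_t = NA_real_,
                      sxx = NA_real_, df = NA_integer_)
}

#' Published allometric model parameters
#'
#' Loads the packaged parameter file holding the published fitted values
#' for the genome-length and capsid-diameter models
#' (`log10 a_G = 0.37 +/- 0.10`, `b_G = 1.47 +/- 0.09`;
#' `log10 a_D = 1.38 +/- 0.34`, `b_D = 0.52 +/- 0.03`).
#'
#' @param path Optional path to an alternative JSON parameter file.
#' @return Named list of two `"allometric_fit"` objects: `genome_kbp` and
#'   `diameter_nm`.
#' @export
printed_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "printed_params.json", package = "capsidkit")
  }
  pp <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(pp), function(v) {
    p <- pp[[v]]
    from_printed_params(p$log10_a, p$b, v,
                        se_log10_a = p$se_log10_a %||% NA_real_,
                        se_b = p$se_b %||% NA_real_)
  })
  stats::setNames(out, names(pp))
}

#' Model-mean prediction
#'
#' Evaluates `10^log10_a * t^b` in the fit's units (kbp for the genome model,
#' nm for the diameter model).
#'
#' @param fit An `"allometric_fit"`.
#' @param t Architecture index (positive; vectorized).
#' @return Predicted mean value(s).
#' @examples
#' predict_mean(from_printed_params(0.37, 1.47, "genome_kbp"), 3)  # 11.78 kbp
#' @export
predict_mean <- function(fit, t) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be positive")
  10^fit$log10_a * t^fit$b
}

#' Coefficient of variation of the fitted parameters
#'
#' @param fit An `"allometric_fit"` carrying standard errors.
#' @return Named vector `c(intercept = se_log10_a/|log10_a|, exponent =
#'   se_b/|b|)`; e.g. 0.09/1.47 = 6.1\% for the published genome exponent.
#' @export
coef_cv <- function(fit) {
  stopifnot(inherits(fit, "allometric_fit"))
  c(intercept = fit$se_log10_a / abs(fit$log10_a),
    exponent = fit$se_b / abs(fit$b))
}

#' Confidence or prediction interval on the model mean
#'
#' Standard linear-regression interval computed on the log10 scale at
#' `x0 = log10(t)` and back-transformed: the half-width is
#' `qt((1+level)/2, df) * residual_sd * sqrt(m + 1/n + (x0-mean_x)^2/sxx)`
#' with `m = 0` for the mean response and `m = 1` for a new observation.
#' Back-transforming by `10^(.)` makes the interval asymmetric around the
#' mean on the linear scale.
#'
#' @inheritParams predict_mean
#' @param level Coverage level, default 0.95.
#' @param kind `"mean_response"` (default) or `"new_observation"`.
#' @return A data frame with columns `t`, `mean`, `lower`, `upper`, `level`,
#'   `kind`.
#' @export
predict_interval <- function(fit, t, level = 0.95,
                             kind = c("mean_response", "new_observation")) {
  stopifnot(inherits(fit, "allometric_fit"))
  kind <- match.arg(kind)
  if (!.has_residual_stats(fit)) {
    stop("interval prediction needs residual statistics from a fresh fit; ",
         "evaluation-only fits built from printed parameters cannot produce intervals")
  }
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be positive")
  stopifnot(level > 0, level < 1)
  x0 <- log10(t)
  yhat <- fit$log10_a + fit$b * x0
  extra <- if (kind == "new_observation") 1 else 0
  half <- stats::qt((1 + level) / 2, fit$df) * fit$residual_sd *
    sqrt(extra + 1 / fit$n + (x0 - fit$mean_log10_t)^2 / fit$sxx)
  data.frame(t = t, mean = 10^yhat, lower = 10^(yhat - half),
             upper = 10^(yhat + half), level = level, kind = kind,
             stringsAsFactors = FALSE)
}

#' Invert the allometric model
#'
#' Continuous architecture index implied by a genome length or diameter:
#' `(value / 10^log10_a)^(1/b)`.
#'
#' @inheritParams predict_mean
#' @param value Positive value in the fit's units (vectorized).
#' @return Continuous T value(s).
#' @export
inverse_t <- function(fit, value) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (any(!is.finite(value)) || any(value <= 0)) stop("value must be positive")
  (value / 10^fit$log10_a)^(1 / fit$b)
}

#' Residual diagnostics of a fresh allometric fit
#'
#' Reports, on the log10 scale of the fitted line: standardized residuals,
#' leverage values, a Shapiro-Wilk normality p-value of the raw residuals,
#' and a heteroscedasticity flag (correlation between absolute residuals and
#' fitted values, flagged when the two-sided p-value falls below 0.05).
#'
#' @param fit A fresh `"allometric_fit"` (one carrying its data).
#' @return List with `residuals`, `standardized`, `leverage`, `fitted`,
#'   `normality_p`, `het_cor`, `heteroscedastic`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (is.null(fit$x) || !.has_residual_stats(fit)) {
    stop("residual diagnostics need a fresh fit carrying its data")
  }
  lmfit <- stats::lm(fit$y ~ fit$x)
  res <- stats::residuals(lmfit)
  std <- stats::rstandard(lmfit)
  lev <- stats::hatvalues(lmfit)
  fitted <- stats::fitted(lmfit)
  normality_p <- if (length(res) >= 3 && stats::sd(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  het <- if (stats::sd(abs(res)) > 0 && stats::sd(fitted) > 0) {
    stats::cor.test(abs(res), fitted)
  } else NULL
  list(
    residuals = res, standardized = std, leverage = lev, fitted = fitted,
    normality_p = normality_p,
    het_cor = if (is.null(het)) NA_real_ else unname(het$estimate),
    heteroscedastic = if (is.null(het)) FALSE else het$p.value < 0.05
  )
}

#' Theoretical allometric exponents from the scaling argument
#'
#' The structural analysis of tailed phage capsids supports two conserved
#' quantities: the genome packing density (so genome length scales with
#' interior volume, `G ~ D^3`) and the exposed surface per major capsid
#' protein (so the T-number scales with surface, `T ~ D^2`). Chaining the two
#' gives `G ~ T^(3/2)` and `D ~ T^(1/2)`. This function derives the
#' exponents numerically by constructing exact quasi-spherical capsids under
#' those two constraints and reading off the log-log slopes.
#'
#' @return Named vector `c(b_g = 1.5, b_d = 0.5)` (up to numerical round-off).
#' @export
theoretical_exponents <- function() {
  t <- c(1, 3, 4, 7, 9, 12, 13, 16, 25, 27)
  area_per_mcp <- 30    # nm^2, constant by assumption
  density <- 0.5        # bp/nm^3, constant by assumption
  surface <- area_per_mcp * 60 * t     # T proportional to capsid surface
  d <- sqrt(surface / pi)              # quasi-spherical shell
  g <- density * (pi * d^3 / 6) / 1000 # kbp
  b_d <- unname(coef(stats::lm(log10(d) ~ log10(t)))[2])
  b_g <- unname(coef(stats::lm(log10(g) ~ log10(t)))[2])
  c(b_g = b_g, b_d = b_d)
}

#' Serialize / deserialize an allometric fit as JSON
#'
#' @param fit An `"allometric_fit"`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly for the writer; an `"allometric_fit"` for the
#'   reader.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "allometric_fit"))
  jsonlite::write_json(fit[c("variable", "log10_a", "se_log10_a", "b", "se_b",
                             "n", "r_squared", "residual_sd", "mean_log10_t",
                             "sxx", "df")],
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(z) if (is.null(z) || length(z) == 0) NA_real_ else as.numeric(z)
  .new_allometric_fit(p$variable, num(p$log10_a), num(p$se_log10_a),
                      num(p$b), num(p$se_b), num(p$n), num(p$r_squared),
                      num(p$residual_sd), num(p$mean_log10_t), num(p$sxx),
                      num(p$df))
}

#' @export
print.allometric_fit <- function(x, ...) {
  unit <- if (x$variable == "genome_kbp") "kbp" else "nm"
  cat(sprintf("Allometric fit: %s = 10^%.3f * T^%.3f  [%s]\n",
              sub("_.*", "", x$variable), x$log10_a, x$b, unit))
  cat(sprintf("  log10(a) = %.3f +/- %s, b = %.3f +/- %s\n",
              x$log10_a,
              if (is.na(x$se_log10_a)) "NA" else sprintf("%.3f", x$se_log10_a),
              x$b, if (is.na(x$se_b)) "NA" else sprintf("%.3f", x$se_b)))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  n = %d distinct T, R^2 = %.4f, residual sd = %.4f (log10)\n",
                x$n, x$r_squared, x$residual_sd))
  } else {
    cat("  evaluation-only fit (no residual statistics)\n")
  }
  invisible(x)
}
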