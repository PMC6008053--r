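# Pulse-chase puncta decay fitting and cross-modality half-life correlation.

#' Fit first-order decay to a puncta time course
#'
#' Computes the mean puncta count per cell for each chase day (cells with
#' zero puncta included) and fits `ln(mean)` against chase day by ordinary
#' least squares with a free intercept: unlike the fraction-based SILAC fit,
#' the initial puncta number is not normalised, so the intercept absorbs it.
#' The rate constant is the negative slope and the half-life `ln(2)/k`.
#' A nonlinear least-squares fit of `n0 * exp(-k t)` to the day means is
#' available via `method = "nls"`.
#'
#' @param puncta data.frame with columns `cell_id`, `chase_days`,
#'   `puncta_count` and optionally `target`.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return list of class `puncta_fit`: `target`, `day_means` (chase_days,
#'   mean_count, n_cells), `k_per_day`, `half_life_days`, `r_squared`,
#'   `n0_fit`, `method`.
#' @examples
#' pt <- simulate_puncta(1, chase_days = 0:3, n_cells = 500, n0 = 100, seed = 1)
#' fit_puncta_decay(pt)$half_life_days
#' @export
fit_puncta_decay <- function(puncta, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  puncta <- as.data.frame(puncta)
  need <- c("cell_id", "chase_days", "puncta_count")
  miss <- setdiff(need, names(puncta))
  if (length(miss))
    stop_format("format error: puncta table lacks column(s): %s",
                paste(miss, collapse = ", "))
  dt <- as.data.table(puncta)
  dm <- dt[, .(mean_count = mean(puncta_count), n_cells = .N),
           by = chase_days]
  setorder(dm, chase_days)
  bad <- dm$mean_count <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " chase day(s) with non-positive mean count",
            call. = FALSE)
    dm <- dm[!bad]
  }
  if (nrow(dm) < 3L)
    stop_format("need >= 3 chase days with positive mean counts")

  if (method == "loglinear") {
    fit <- lm(log(mean_count) ~ chase_days, data = dm)
    k <- -unname(coef(fit)[2L])
    n0 <- exp(unname(coef(fit)[1L]))
    r2 <- summary(fit)$r.squared
  } else {
    start_fit <- lm(log(mean_count) ~ chase_days, data = dm)
    nfit <- stats::nls(mean_count ~ n0 * exp(-k * chase_days), data = dm,
                       start = list(n0 = exp(coef(start_fit)[1L]),
                                    k = max(1e-6, -coef(start_fit)[2L])))
    k <- unname(coef(nfit)["k"])
    n0 <- unname(coef(nfit)["n0"])
    res <- dm$mean_count - predict(nfit)
    r2 <- 1 - sum(res^2) / sum((dm$mean_count - mean(dm$mean_count))^2)
  }
  if (!is.finite(k) || k <= 0) {
    warning("fitted rate constant is not positive; no half-life assigned",
            call. = FALSE)
    half_life <- NA_real_
  } else {
    half_life <- log(2) / k
  }
  structure(list(
    target = if ("target" %in% names(puncta)) puncta$target[1L] else NA_character_,
    day_means = as.data.frame(dm),
    k_per_day = k,
    half_life_days = half_life,
    r_squared = r2,
    n0_fit = n0,
    method = method
  ), class = "puncta_fit")
}

#' @export
print.puncta_fit <- function(x, ...) {
  cat(sprintf("puncta decay fit (%s): %s\n", x$method,
              ifelse(is.na(x$target), "unnamed target", x$target)))
  cat(sprintf("  k = %.4f /day, t1/2 = %.2f days, R^2 = %.3f\n",
              x$k_per_day, x$half_life_days, x$r_squared))
  cat(sprintf("  %d chase days, %d-%d cells/day\n", nrow(x$day_means),
              min(x$day_means$n_cells), max(x$day_means$n_cells)))
  invisible(x)
}

#' Correlate half-lives measured by two modalities
#'
#' Pearson correlation (with two-sided p-value) between half-lives of the
#' same proteins measured by two methods, e.g. imaging-based pulse-chase
#' versus mass spectrometry.
#'
#' @param a,b numeric vectors of matched half-lives (>= 3 pairs).
#' @return list: `r`, `p_value`, `n`.
#' @examples
#' correlate_halflives(c(1, 2, 3), c(2, 1, 3))  # r = 0.5
#' @export
correlate_halflives <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop_format("vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop_format("need >= 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0)
    stop_format("zero variance in one of the half-life vectors")
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
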