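# Per-protein half-life determination: peptide filtering, Tukey-fence
# outlier removal, monotonic-decay exclusion, k-means censoring of
# fast-turnover proteins, and no-intercept log-linear decay fitting.

#' Filter peptides for half-life fitting
#'
#' Within each biological replicate, retains only peptides that are
#' quantified (a non-excluded old fraction) at every design timepoint and
#' whose mean old fraction at t0 exceeds `t0_threshold`. Peptides mapping to
#' more than one protein group (";"-separated identifiers) are dropped.
#' Replicates are then merged: all retained measurements are pooled.
#'
#' @param frac_table peptide table with `fraction_old`/`excluded` columns
#'   from [compute_old_fractions()].
#' @param timepoints design timepoints (days); defaults to those present.
#' @param t0_threshold minimum mean old fraction at t0 (default 0.9).
#' @return The filtered table (same columns).
#' @export
filter_peptides <- function(frac_table,
                            timepoints = sort(unique(frac_table$timepoint)),
                            t0_threshold = 0.9) {
  dt <- as.data.table(as.data.frame(frac_table))
  if (!"fraction_old" %in% names(dt))
    stop_format("run compute_old_fractions() first")
  if (!"condition" %in% names(dt)) dt[, condition := "default"]
  dt <- dt[excluded == FALSE & !is.na(fraction_old)]
  dt <- dt[!grepl(";", protein_group, fixed = TRUE)]
  if (!nrow(dt)) return(as.data.frame(dt))

  keys <- c("condition", "replicate", "sequence")
  stats <- dt[, .(n_tp = uniqueN(timepoint),
                  t0_mean = mean(fraction_old[timepoint == 0])),
              by = keys]
  ok <- stats[n_tp == length(timepoints) & !is.nan(t0_mean) &
                t0_mean > t0_threshold, ..keys]
  out <- merge(dt, ok, by = keys)
  setorder(out, condition, protein_group, sequence, replicate, injection,
           timepoint)
  as.data.frame(out)
}

tukey_keep <- function(x, k = 1.5) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  x >= q[1] - k * iqr & x <= q[2] + k * iqr
}

#' Tukey-fence outlier removal
#'
#' Removes values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' computed by linear interpolation between order statistics (R quantile
#' type 7). Applied per protein and timepoint across pooled peptide
#' measurements.
#'
#' @param values numeric vector (length >= 1).
#' @param k fence multiplier (default 1.5).
#' @return The retained values.
#' @examples
#' remove_outliers(c(0.88, 0.90, 0.91, 0.92, 0.20))
#' @export
remove_outliers <- function(values, k = 1.5) {
  if (!length(values)) stop_format("need at least one value")
  values[tukey_keep(values, k = k)]
}

#' Check for continuous decay across timepoints
#'
#' A protein's per-timepoint mean old fractions must be non-increasing
#' (within an additive tolerance) for a first-order decay fit to be
#' meaningful; profiles that rise again are excluded.
#'
#' @param means per-timepoint mean old fractions, ordered by increasing
#'   timepoint.
#' @param tolerance maximal allowed rise between consecutive timepoints
#'   (default 0.05).
#' @return `TRUE` if the profile decays monotonically within tolerance.
#' @examples
#' check_monotonic_decay(c(1, 0.8, 0.6, 0.4))
#' check_monotonic_decay(c(1, 0.7, 0.9, 0.5))
#' @export
check_monotonic_decay <- function(means, tolerance = 0.05) {
  means <- as.numeric(means)
  if (length(means) < 2L) return(TRUE)
  all(diff(means) <= tolerance)
}

#' Censor fast-turnover proteins by k-means clustering
#'
#' Clusters per-protein mean old-fraction profiles with k-means and censors
#' every protein in a cluster whose centroid retains at most
#' `censor_threshold` of pre-existing protein at the chase timepoint closest
#' to one day. Such proteins decay too fast for a reliable exponential fit
#' within the sampling design and are assigned a half-life of "<1 day". When
#' clustering is not possible (fewer distinct profiles than clusters) the
#' direct per-protein rule is applied instead.
#'
#' @param profile_means numeric matrix: rows = proteins (rownames = protein
#'   group), columns = timepoints (numeric colnames), entries = mean old
#'   fraction.
#' @param k_clusters number of k-means clusters (default 6).
#' @param censor_threshold centroid old fraction at ~1 day at or below which
#'   a cluster is censored (default 0.5).
#' @param seed seed for the k-means initialisation.
#' @return Character vector of censored protein groups.
#' @export
cluster_fast_turnover <- function(profile_means, k_clusters = 6,
                                  censor_threshold = 0.5, seed = 1L) {
  stopifnot(is.matrix(profile_means))
  tp <- as.numeric(colnames(profile_means))
  if (anyNA(tp)) stop_format("profile_means must have numeric timepoint colnames")
  chase <- which(tp > 0)
  if (!length(chase)) stop_format("no chase timepoints in profile matrix")
  day1 <- chase[which.min(abs(tp[chase] - 1))]

  direct_rule <- function() {
    rownames(profile_means)[profile_means[, day1] <= censor_threshold]
  }
  n_distinct <- nrow(unique(profile_means))
  if (nrow(profile_means) < k_clusters || n_distinct < k_clusters)
    return(direct_rule())
  km <- tryCatch(
    with_seed(seed, kmeans(profile_means, centers = k_clusters,
                           nstart = 10, iter.max = 100)),
    error = function(e) NULL)
  if (is.null(km)) return(direct_rule())
  fast_clusters <- which(km$centers[, day1] <= censor_threshold)
  rownames(profile_means)[km$cluster %in% fast_clusters]
}

#' Fit a first-order decay to pooled old-fraction measurements
#'
#' Least-squares fit of `ln(%old) = -k t` with no intercept (the curve is
#' forced through `%old = 1` at `t = 0`). The rate constant is the negative
#' slope; its standard error and the uncentered coefficient of determination
#' `R^2 = 1 - RSS / sum(y^2)` are reported, and the half-life is
#' `ln(2) / k`.
#'
#' @param timepoint numeric vector of times (days); alternatively a
#'   data.frame with columns `timepoint` and `fraction_old`.
#' @param fraction_old old fractions (> 0) matching `timepoint`.
#' @return One-row data.frame: `k_per_day`, `se_k`, `r_squared`,
#'   `half_life_days`, `censored` (always `FALSE` here), `n_points`, and a
#'   `reason` column that is `NA` for a valid fit or `"nonpositive_rate"`
#'   when the fitted slope does not decay.
#' @examples
#' t <- c(0, 1, 3, 7)
#' fit_halflife(t, exp(-0.2 * t))
#' @export
fit_halflife <- function(timepoint, fraction_old = NULL) {
  if (is.data.frame(timepoint)) {
    fraction_old <- timepoint$fraction_old
    timepoint <- timepoint$timepoint
  }
  keep <- !is.na(fraction_old) & fraction_old > 0
  t <- timepoint[keep]
  y <- log(fraction_old[keep])
  if (length(t) < 3L)
    stop_format("need >= 3 positive pooled points to fit a half-life")
  fit <- lm.fit(x = matrix(t, ncol = 1L), y = y)
  slope <- unname(fit$coefficients[1L])
  k <- -slope
  n <- length(y)
  rss <- sum(fit$residuals^2)
  se_k <- sqrt(rss / (n - 1L) / sum(t^2))
  tss <- sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  ok <- is.finite(k) && k > 0
  data.frame(
    k_per_day = if (ok) k else NA_real_,
    se_k = if (ok) se_k else NA_real_,
    r_squared = if (ok) r2 else NA_real_,
    half_life_days = if (ok) log(2) / k else NA_real_,
    censored = FALSE,
    n_points = n,
    reason = if (ok) NA_character_ else "nonpositive_rate",
    stringsAsFactors = FALSE
  )
}

#' Run the full half-life pipeline
#'
#' Chains the stages in the order: old-fraction computation, peptide
#' filtering, replicate merge, per-timepoint Tukey outlier removal,
#' monotonic-decay exclusion, fast-turnover censoring, and no-intercept
#' log-linear fitting. Runs independently per condition. Every exclusion is
#' counted in the returned log.
#'
#' @param peptides peptide table (PeptideTable layout).
#' @param purity per-sample purity table from [estimate_purity()], a pooled
#'   purity table, or a single numeric `P_H`.
#' @param exponent_rule correction exponent rule, see [fraction_old()].
#' @param t0_threshold minimum mean t0 old fraction, see [filter_peptides()].
#' @param monotonic_tolerance see [check_monotonic_decay()].
#' @param k_clusters,censor_threshold,cluster_seed see
#'   [cluster_fast_turnover()].
#' @param include_t0 include t0 points in the fit (default `TRUE`; they do
#'   not affect the no-intercept slope but enter the error estimates).
#' @return A list of class `halflife_result`:
#'   * `halflives`: per-protein records (protein_group, condition,
#'     n_peptides, n_points, k_per_day, se_k, r_squared, half_life_days,
#'     censored),
#'   * `profiles`: retained peptide-level old fractions per protein and
#'     timepoint,
#'   * `profile_means`: per-protein per-timepoint means,
#'   * `exclusions`: per-stage counts of removed rows/peptides/proteins.
#' @examples
#' prot <- generate_proteome(30, silac_config(seed = 11))
#' ex <- simulate_silac_experiment(prot)
#' pur <- estimate_purity(ex$label_counts)
#' res <- run_pipeline(ex$peptides, pur)
#' head(res$halflives)
#' @export
run_pipeline <- function(peptides, purity,
                         exponent_rule = c("MC+1", "MC"),
                         t0_threshold = 0.9,
                         monotonic_tolerance = 0.05,
                         k_clusters = 6,
                         censor_threshold = 0.5,
                         cluster_seed = 1L,
                         include_t0 = TRUE) {
  exponent_rule <- match.arg(exponent_rule)
  log_rows <- list()
  note <- function(stage, unit, n_before, n_after) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, unit = unit, n_before = n_before, n_after = n_after,
      n_removed = n_before - n_after, stringsAsFactors = FALSE)
  }

  frac <- compute_old_fractions(peptides, purity, exponent_rule = exponent_rule)
  note("negative_or_missing_fraction", "measurements",
       nrow(frac), sum(!frac$excluded))

  timepoints <- sort(unique(frac$timepoint))
  filt <- filter_peptides(frac, timepoints = timepoints,
                          t0_threshold = t0_threshold)
  note("peptide_filter", "measurements", sum(!frac$excluded), nrow(filt))
  dt <- as.data.table(filt)
  if (!nrow(dt)) {
    msg("no peptides survive filtering")
    return(structure(list(
      halflives = data.frame(),
      profiles = as.data.frame(dt),
      profile_means = data.frame(),
      exclusions = do.call(rbind, log_rows)), class = "halflife_result"))
  }

  dt[, keep := tukey_keep(fraction_old),
     by = .(condition, protein_group, timepoint)]
  note("tukey_outliers", "measurements", nrow(dt), sum(dt$keep))
  dt <- dt[keep == TRUE][, keep := NULL]

  means <- dt[, .(mean_old = mean(fraction_old)),
              by = .(condition, protein_group, timepoint)]
  setorder(means, condition, protein_group, timepoint)

  # proteins must retain t0 plus at least two chase timepoints
  cover <- means[, .(n_tp = .N), by = .(condition, protein_group)]
  full <- cover[n_tp == length(timepoints)]
  note("timepoint_coverage", "proteins", nrow(cover), nrow(full))
  means <- merge(means, full[, .(condition, protein_group)],
                 by = c("condition", "protein_group"))

  mono <- means[, .(monotonic = check_monotonic_decay(
    mean_old[order(timepoint)], tolerance = monotonic_tolerance)),
    by = .(condition, protein_group)]
  note("monotonic_decay", "proteins", nrow(mono), sum(mono$monotonic))

  records <- list()
  for (cond in unique(means$condition)) {
    m_c <- means[condition == cond]
    mono_c <- mono[condition == cond & monotonic == TRUE, protein_group]
    m_c <- m_c[protein_group %in% mono_c]
    if (!nrow(m_c)) next
    wide <- dcast(m_c, protein_group ~ timepoint, value.var = "mean_old")
    pg <- wide$protein_group
    mat <- as.matrix(wide, rownames = "protein_group")
    censored_pg <- cluster_fast_turnover(mat, k_clusters = k_clusters,
                                         censor_threshold = censor_threshold,
                                         seed = cluster_seed)

    pts <- dt[condition == cond & protein_group %in% pg]
    if (!include_t0) pts <- pts[timepoint != 0]
    n_pep <- pts[, .(n_peptides = uniqueN(sequence)), by = protein_group]

    uncens <- pts[!protein_group %in% censored_pg]
    fits <- if (nrow(uncens)) {
      f <- uncens[, fit_halflife(timepoint, fraction_old), by = protein_group]
      bad <- f[!is.na(reason)]
      if (nrow(bad))
        msg("condition %s: %d protein(s) unfittable (%s), excluded",
            cond, nrow(bad), paste(unique(bad$reason), collapse = ", "))
      f[is.na(reason)][, reason := NULL]
    } else {
      data.table(protein_group = character(), k_per_day = numeric(),
                 se_k = numeric(), r_squared = numeric(),
                 half_life_days = numeric(), censored = logical(),
                 n_points = integer())
    }

    if (length(censored_pg)) {
      cens_pts <- pts[protein_group %in% censored_pg,
                      .(n_points = .N), by = protein_group]
      cens <- data.table(protein_group = cens_pts$protein_group,
                         k_per_day = NA_real_, se_k = NA_real_,
                         r_squared = NA_real_, half_life_days = NA_real_,
                         censored = TRUE, n_points = cens_pts$n_points)
      fits <- rbind(fits, cens, use.names = TRUE)
    }
    fits <- merge(fits, n_pep, by = "protein_group")
    fits[, condition := cond]
    records[[cond]] <- fits
  }
  halflives <- if (length(records)) {
    out <- rbindlist(records, use.names = TRUE)
    setcolorder(out, c("protein_group", "condition", "n_peptides", "n_points",
                       "k_per_day", "se_k", "r_squared", "half_life_days",
                       "censored"))
    setorder(out, condition, protein_group)
    as.data.frame(out)
  } else data.frame()
  note("fit", "proteins", nrow(mono), nrow(halflives))

  structure(list(
    halflives = halflives,
    profiles = as.data.frame(dt),
    profile_means = as.data.frame(means),
    exclusions = do.call(rbind, log_rows)
  ), class = "halflife_result")
}

#' @export
print.halflife_result <- function(x, ...) {
  cat("dynamic SILAC half-life pipeline result\n")
  if (nrow(x$halflives)) {
    tab <- table(x$halflives$condition, x$halflives$censored)
    for (cond in rownames(tab)) {
      fitted <- x$halflives[x$halflives$condition == cond &
                              !x$halflives$censored, ]
      cat(sprintf("  %s: %d proteins (%d censored '<1 day'); median t1/2 %.2f d\n",
                  cond, sum(x$halflives$condition == cond),
                  sum(x$halflives$condition == cond & x$halflives$censored),
                  median(fitted$half_life_days)))
    }
  } else cat("  no proteins fitted\n")
  invisible(x)
}
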