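# Label-incorporation kinetics: per-sample heavy-incorporation probability
# from missed-cleavage species counts, and conversion of heavy/light ratios
# into corrected fractions of pre-existing protein.

#' Estimate heavy-incorporation probability from label-species counts
#'
#' Because the medium retains residual light amino acids, a nascent protein
#' incorporates a heavy Arg/Lys only with probability `P(H) < 1`. For
#' missed-cleavage peptides (two labelable residues) the mixed (LH) and
#' all-heavy (HH) nascent species are observable, and with `P(L) + P(H) = 1`
#' the class probabilities `2 P(L) P(H)` and `P(H)^2` give the closed form
#' `P(H) = (2 HH/LH) / (1 + 2 HH/LH)`. The all-light nascent class cancels
#' and need not be observed.
#'
#' @param counts data.frame of per-sample counts with columns `LH_count` and
#'   `HH_count` plus any sample-identifier columns; rows with
#'   `timepoint == 0` are dropped (no nascent label at t0).
#' @param pooled if `TRUE`, counts are summed over all samples and a single
#'   pooled estimate is returned (useful for low-count samples).
#' @return The input identifier columns plus `LH_count`, `HH_count`, `P_H`
#'   and `P_L`. When `pooled = TRUE`, a single-row data.frame.
#' @examples
#' estimate_purity(data.frame(LH_count = 1000, HH_count = 2000))  # P_H = 0.8
#' @export
estimate_purity <- function(counts, pooled = FALSE) {
  counts <- as.data.frame(counts)
  if (!all(c("LH_count", "HH_count") %in% names(counts)))
    stop_format("format error: counts must have columns LH_count and HH_count")
  if ("timepoint" %in% names(counts) && any(counts$timepoint == 0)) {
    n0 <- sum(counts$timepoint == 0)
    msg("dropping %d t0 row(s) from label counts (no nascent label at t0)", n0)
    counts <- counts[counts$timepoint != 0, , drop = FALSE]
  }
  if (!nrow(counts)) stop_format("no usable label-count rows")
  if (any(counts$LH_count < 0 | counts$HH_count < 0) ||
      any(counts$LH_count != floor(counts$LH_count)) ||
      any(counts$HH_count != floor(counts$HH_count)))
    stop_format("format error: LH/HH counts must be non-negative integers")
  if (pooled) {
    counts <- data.frame(LH_count = sum(counts$LH_count),
                         HH_count = sum(counts$HH_count))
  }
  LH <- counts$LH_count
  HH <- counts$HH_count
  if (any(LH + HH == 0))
    stop_format("cannot estimate purity: sample with LH_count + HH_count == 0")
  P_H <- numeric(length(LH))
  sat <- LH == 0 & HH > 0
  if (any(sat)) {
    warning("purity estimate saturated at P_H = 1 for ",
            sum(sat), " sample(s) with LH_count = 0", call. = FALSE)
    P_H[sat] <- 1
  }
  ok <- !sat
  r <- HH[ok] / LH[ok]
  P_H[ok] <- 2 * r / (1 + 2 * r)
  counts$P_H <- P_H
  counts$P_L <- 1 - P_H
  counts
}

#' Fraction of remaining light peptide from a heavy/light ratio
#'
#' `%L = 1 / (1 + H/L)`. For peptides detected exclusively in their light
#' form (no ratio computed; the t0 situation) the fraction is 1.
#'
#' @param ratio_HL non-negative heavy/light ratio(s); may be `NA` where
#'   `light_only` is `TRUE`.
#' @param light_only logical, recycled; overrides the ratio with 1.
#' @return numeric vector of light fractions in `[0, 1]`.
#' @examples
#' fraction_light(c(0, 1, 3))       # 1, 0.5, 0.25
#' fraction_light(NA, light_only = TRUE)
#' @export
fraction_light <- function(ratio_HL, light_only = FALSE) {
  light_only <- rep_len(as.logical(light_only), length(ratio_HL))
  if (any(!is.na(ratio_HL) & ratio_HL < 0))
    stop_format("value error: ratio_HL must be non-negative")
  out <- ifelse(light_only, 1, 1 / (1 + ratio_HL))
  as.numeric(out)
}

#' Correct the light fraction for incomplete heavy labeling
#'
#' Converts the fraction of light peptide into the fraction of pre-existing
#' (old) peptide: part of the light signal comes from nascent protein that
#' incorporated residual light label. The correction is
#' `%old = 1 - (1 - %L) / P(H)^n`, where `n` counts labelable residues:
#' `n = missed_cleavages + 1` under the default `"MC+1"` rule (the number of
#' Arg/Lys in the peptide), or `n = missed_cleavages` under the `"MC"` rule.
#' Negative corrected values are flagged excluded rather than clamped.
#'
#' @param fraction_light light fraction(s) in `[0, 1]`.
#' @param purity heavy-incorporation probability: a number in (0, 1], a
#'   single row from [estimate_purity()], or a numeric vector recycled
#'   against `fraction_light`.
#' @param missed_cleavages integer count(s) of missed cleavages.
#' @param exponent_rule `"MC+1"` (default) or `"MC"`.
#' @return data.frame with columns `fraction_old`, `excluded`, `reason`.
#' @examples
#' fraction_old(0.6, 0.8, missed_cleavages = 0)  # 0.5
#' @export
fraction_old <- function(fraction_light, purity, missed_cleavages,
                         exponent_rule = c("MC+1", "MC")) {
  exponent_rule <- match.arg(exponent_rule)
  if (is.data.frame(purity)) purity <- purity$P_H
  purity <- as.numeric(purity)
  if (any(is.na(fraction_light) | fraction_light < 0 | fraction_light > 1))
    stop_format("value error: fraction_light must be in [0, 1]")
  if (any(is.na(purity) | purity < 0 | purity > 1))
    stop_format("value error: purity must be in [0, 1]")
  if (any(purity == 0))
    stop_format("correction undefined: P_H = 0")
  if (any(missed_cleavages < 0))
    stop_format("value error: missed_cleavages must be >= 0")
  n <- missed_cleavages + as.integer(exponent_rule == "MC+1")
  old <- 1 - (1 - fraction_light) / purity^n
  excluded <- old < 0
  data.frame(fraction_old = old,
             excluded = excluded,
             reason = ifelse(excluded, "negative_after_correction", NA_character_),
             stringsAsFactors = FALSE)
}

#' Compute corrected old fractions for a peptide table
#'
#' Joins each measurement with its sample's heavy-incorporation probability
#' and applies [fraction_light()] and [fraction_old()]. At `t = 0` no nascent
#' protein exists, so the old fraction equals the light fraction (1 for
#' light-only detections) and no purity estimate is required.
#'
#' @param peptides a peptide table (see [read_peptide_table()]).
#' @param purity per-sample purity table from [estimate_purity()] (matched on
#'   condition, replicate, injection, timepoint), a pooled single-row purity
#'   table, or a single numeric `P_H`.
#' @param exponent_rule passed to [fraction_old()].
#' @return The peptide table with added columns `fraction_light`,
#'   `fraction_old`, `excluded`, `exclude_reason`.
#' @export
compute_old_fractions <- function(peptides, purity,
                                  exponent_rule = c("MC+1", "MC")) {
  exponent_rule <- match.arg(exponent_rule)
  dt <- as.data.table(as.data.frame(peptides))
  need <- c("sequence", "protein_group", "missed_cleavages", "ratio_HL",
            "timepoint")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_format("format error: peptide table lacks column(s): %s",
                paste(miss, collapse = ", "))
  if (!"light_only" %in% names(dt))
    dt[, light_only := is.na(ratio_HL) & timepoint == 0]

  # resolve a per-row P_H
  if (is.numeric(purity) && length(purity) == 1L) {
    dt[, P_H := purity]
  } else {
    pur <- as.data.table(as.data.frame(purity))
    if (!"P_H" %in% names(pur))
      stop_format("purity table lacks column P_H (use estimate_purity())")
    keys <- intersect(c("condition", "replicate", "injection", "timepoint"),
                      names(pur))
    if (length(keys) == 0L || nrow(pur) == 1L) {
      dt[, P_H := pur$P_H[1L]]
    } else {
      dt <- merge(dt, pur[, c(keys, "P_H"), with = FALSE],
                  by = keys, all.x = TRUE)
      if (anyNA(dt[timepoint != 0, P_H])) {
        bad <- unique(dt[timepoint != 0 & is.na(P_H), ..keys])
        stop_format("no purity estimate for %d sample(s), e.g. %s",
                    nrow(bad), paste(unlist(bad[1L]), collapse = "/"))
      }
    }
  }

  frL <- fraction_light(dt$ratio_HL, dt$light_only)
  dt[, fraction_light := frL]
  dt[, `:=`(fraction_old = NA_real_, excluded = FALSE,
            exclude_reason = NA_character_)]

  # t0: no nascent protein, old fraction is the light fraction
  dt[timepoint == 0 & !is.na(fraction_light), fraction_old := fraction_light]

  chase <- dt$timepoint != 0 & !is.na(dt$fraction_light)
  if (any(chase)) {
    corr <- fraction_old(dt$fraction_light[chase], dt$P_H[chase],
                         dt$missed_cleavages[chase],
                         exponent_rule = exponent_rule)
    dt[chase, `:=`(fraction_old = corr$fraction_old,
                   excluded = corr$excluded,
                   exclude_reason = corr$reason)]
  }
  missing_ratio <- is.na(dt$fraction_light)
  if (any(missing_ratio))
    dt[missing_ratio, `:=`(excluded = TRUE, exclude_reason = "missing_ratio")]
  dt[, P_H := NULL]
  as.data.frame(dt)
}
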