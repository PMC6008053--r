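# Cross-condition turnover comparison: direction-consistency screening,
# per-timepoint t-tests with Bonferroni correction and a >=2-of-3 verdict
# rule, a paired peptide-level decay-difference test, and a Monte-Carlo
# audit of the family-wise error rate.

safe_p <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_)
}

#' Compare protein turnover between two culture conditions
#'
#' For every protein quantified in both profile tables, the per-timepoint
#' mean old fractions must be strictly greater (or strictly smaller) in
#' condition A than in B at every chase timepoint; proteins with an
#' inconsistent direction are excluded from testing. For the remaining
#' proteins a two-sided t-test (Welch by default) compares the old-fraction
#' values at each chase timepoint, with Bonferroni correction over the total
#' number of tests performed (tested proteins x chase timepoints). A protein
#' is called significant if at least `min_significant` chase timepoints pass
#' the corrected threshold and its direction is consistent.
#'
#' @param profilesA,profilesB data.frames with columns `protein_group`,
#'   `timepoint`, `fraction_old` (the retained peptide-level values from
#'   [run_pipeline()]'s `profiles`, one condition each).
#' @param alpha family-wise significance level (default 0.05).
#' @param var_equal use the pooled-variance Student t-test instead of Welch.
#' @param min_significant minimum number of significant chase timepoints for
#'   a positive verdict (default 2, the ">= 2 of 3" rule).
#' @param min_values minimum old-fraction values per protein, timepoint and
#'   condition (default 2; proteins below it are skipped).
#' @return data.frame with one row per shared protein: `direction`
#'   (`faster_in_A` / `faster_in_B` / `inconsistent`), one `p_<t>d` column
#'   and one `sig_<t>d` flag per chase timepoint, and `significant`. The
#'   Bonferroni denominator is attached as attribute `n_tests`.
#' @export
compare_culture_turnover <- function(profilesA, profilesB, alpha = 0.05,
                                     var_equal = FALSE, min_significant = 2,
                                     min_values = 2) {
  a <- as.data.table(as.data.frame(profilesA))
  b <- as.data.table(as.data.frame(profilesB))
  for (nm in c("protein_group", "timepoint", "fraction_old")) {
    if (!nm %in% names(a) || !nm %in% names(b))
      stop_format("profile tables need column %s", nm)
  }
  chase_tp <- sort(intersect(unique(a$timepoint), unique(b$timepoint)))
  chase_tp <- chase_tp[chase_tp > 0]
  if (!length(chase_tp)) stop_format("no shared chase timepoints")
  a <- a[timepoint %in% chase_tp]
  b <- b[timepoint %in% chase_tp]

  cnt_a <- a[, .(nA = .N), by = .(protein_group, timepoint)]
  cnt_b <- b[, .(nB = .N), by = .(protein_group, timepoint)]
  cnt <- merge(cnt_a, cnt_b, by = c("protein_group", "timepoint"))
  full <- cnt[, .(ok = .N == length(chase_tp) && all(nA >= min_values) &&
                    all(nB >= min_values)), by = protein_group]
  shared <- full[ok == TRUE, protein_group]
  if (!length(shared)) {
    warning("no shared proteins with sufficient values in both conditions",
            call. = FALSE)
    return(data.frame())
  }

  ma <- a[protein_group %in% shared,
          .(meanA = mean(fraction_old)), by = .(protein_group, timepoint)]
  mb <- b[protein_group %in% shared,
          .(meanB = mean(fraction_old)), by = .(protein_group, timepoint)]
  m <- merge(ma, mb, by = c("protein_group", "timepoint"))
  dir_tab <- m[, .(direction =
    if (all(meanA < meanB)) "faster_in_A"
    else if (all(meanA > meanB)) "faster_in_B"
    else "inconsistent"), by = protein_group]

  tested <- dir_tab[direction != "inconsistent", protein_group]
  n_tests <- length(tested) * length(chase_tp)

  pvals <- matrix(NA_real_, nrow = length(shared), ncol = length(chase_tp),
                  dimnames = list(sort(shared), paste0("p_", chase_tp, "d")))
  for (pg in tested) {
    for (j in seq_along(chase_tp)) {
      xa <- a[protein_group == pg & timepoint == chase_tp[j], fraction_old]
      xb <- b[protein_group == pg & timepoint == chase_tp[j], fraction_old]
      pvals[pg, j] <- safe_p(t.test(xa, xb, var.equal = var_equal)$p.value)
    }
  }

  thr <- if (n_tests > 0) alpha / n_tests else 0
  sig_mat <- !is.na(pvals) & pvals < thr
  colnames(sig_mat) <- paste0("sig_", chase_tp, "d")

  out <- data.frame(protein_group = rownames(pvals), stringsAsFactors = FALSE)
  out <- merge(out, as.data.frame(dir_tab), by = "protein_group")
  out <- cbind(out, pvals[out$protein_group, , drop = FALSE],
               sig_mat[out$protein_group, , drop = FALSE])
  out$significant <- out$direction != "inconsistent" &
    rowSums(sig_mat[out$protein_group, , drop = FALSE]) >= min_significant
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  attr(out, "alpha") <- alpha
  out
}

#' Paired peptide-level decay comparison between two conditions
#'
#' For each peptide, the relative decay is the difference between its mean
#' old fraction at `t_ref` (default 0) and at `t_late` (default 7 days).
#' Peptides with a negative decay in either condition are removed. Peptides
#' are matched by sequence across conditions and a paired two-sided t-test
#' per protein compares the matched decay values, Bonferroni-corrected over
#' the number of proteins tested.
#'
#' @param fracA,fracB peptide tables with old fractions (from
#'   [compute_old_fractions()], exclusions applied), one condition each.
#' @param alpha family-wise significance level.
#' @param t_ref,t_late the two design timepoints (days).
#' @param min_peptides minimum matched peptides per protein (default 2).
#' @return data.frame per tested protein: `n_peptides`, `mean_decay_A`,
#'   `mean_decay_B`, `p_value`, `significant`; proteins skipped for too few
#'   matched peptides are listed in attribute `skipped`.
#' @export
compare_paired_decay <- function(fracA, fracB, alpha = 0.05,
                                 t_ref = 0, t_late = 7, min_peptides = 2) {
  decay_table <- function(x) {
    dt <- as.data.table(as.data.frame(x))
    if ("excluded" %in% names(dt)) dt <- dt[excluded == FALSE]
    dt <- dt[timepoint %in% c(t_ref, t_late) & !is.na(fraction_old)]
    w <- dt[, .(v = mean(fraction_old)), by = .(protein_group, sequence, timepoint)]
    wide <- dcast(w, protein_group + sequence ~ timepoint, value.var = "v")
    setnames(wide, as.character(c(t_ref, t_late)), c("v_ref", "v_late"),
             skip_absent = TRUE)
    if (!all(c("v_ref", "v_late") %in% names(wide)))
      stop_format("both timepoints %g and %g must be present", t_ref, t_late)
    wide <- wide[!is.na(v_ref) & !is.na(v_late)]
    wide[, decay := v_ref - v_late]
    wide
  }
  da <- decay_table(fracA)
  db <- decay_table(fracB)
  m <- merge(da[, .(protein_group, sequence, decayA = decay)],
             db[, .(protein_group, sequence, decayB = decay)],
             by = c("protein_group", "sequence"))
  # negative relative decay in either condition removes the peptide
  m <- m[decayA >= 0 & decayB >= 0]

  counts <- m[, .N, by = protein_group]
  skipped <- counts[N < min_peptides, protein_group]
  tested <- counts[N >= min_peptides, protein_group]
  if (!length(tested)) {
    warning("no proteins with enough matched peptides", call. = FALSE)
    out <- data.frame()
    attr(out, "skipped") <- skipped
    return(out)
  }
  res <- m[protein_group %in% tested, .(
    n_peptides = .N,
    mean_decay_A = mean(decayA),
    mean_decay_B = mean(decayB),
    p_value = safe_p(t.test(decayA, decayB, paired = TRUE)$p.value)
  ), by = protein_group]
  res[, significant := !is.na(p_value) & p_value < alpha / length(tested)]
  out <- as.data.frame(res)
  attr(out, "n_tests") <- length(tested)
  attr(out, "skipped") <- skipped
  out
}

# generate peptide-level old-fraction values for one condition:
# truth exp(-k t), log-normal noise applied to the implied heavy/light ratio
simulate_profile_values <- function(k, timepoints, n_values, noise_log_sd) {
  grid <- expand.grid(protein = seq_along(k), timepoint = timepoints,
                      value = seq_len(n_values))
  f <- exp(-k[grid$protein] * grid$timepoint)
  ratio <- (1 / f - 1) * exp(rnorm(nrow(grid), 0, noise_log_sd))
  data.frame(protein_group = sprintf("PG%05d", grid$protein),
             timepoint = grid$timepoint,
             fraction_old = 1 / (1 + ratio),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo audit of the comparison procedure
#'
#' Simulates pairs of matched condition datasets at the peptide-value level
#' and runs [compare_culture_turnover()] on each pair. With
#' `effect_multiplier = 1` (null), reports the family-wise error rate: the
#' fraction of simulations in which any protein is called significant. With
#' an effect on the first `n_affected` proteins, additionally reports power:
#' the mean fraction of affected proteins detected.
#'
#' @param n_sim number of simulated dataset pairs.
#' @param alpha family-wise level passed to the comparison.
#' @param n_proteins proteins per dataset.
#' @param n_values old-fraction values per protein and timepoint.
#' @param chase_timepoints chase times, days.
#' @param effect_multiplier rate-constant multiplier in condition B for
#'   affected proteins.
#' @param n_affected number of affected proteins (0 for a pure null).
#' @param noise_log_sd measurement noise on the implied heavy/light ratio.
#' @param halflife_median_days,halflife_log_sd half-life distribution.
#' @param seed integer seed.
#' @return list with `fwer`, `power` (`NA` when nothing is affected),
#'   `n_sim`, `alpha`.
#' @export
type_one_error_audit <- function(n_sim = 200, alpha = 0.05, n_proteins = 20,
                                 n_values = 20, chase_timepoints = c(1, 3, 7),
                                 effect_multiplier = 1, n_affected = 0,
                                 noise_log_sd = 0.05,
                                 halflife_median_days = 5.4,
                                 halflife_log_sd = 0.55, seed = 1L) {
  if (!is_count(n_sim) || n_sim < 1) stop_format("n_sim must be >= 1")
  if (n_affected > n_proteins) stop_format("n_affected exceeds n_proteins")
  affected <- sprintf("PG%05d", seq_len(n_affected))
  with_seed(seed, {
    any_fp <- logical(n_sim)
    det <- numeric(n_sim)
    for (s in seq_len(n_sim)) {
      k <- log(2) / (halflife_median_days * exp(rnorm(n_proteins, 0, halflife_log_sd)))
      kB <- k
      if (n_affected > 0) kB[seq_len(n_affected)] <- k[seq_len(n_affected)] * effect_multiplier
      pa <- simulate_profile_values(k, chase_timepoints, n_values, noise_log_sd)
      pb <- simulate_profile_values(kB, chase_timepoints, n_values, noise_log_sd)
      cmp <- compare_culture_turnover(pa, pb, alpha = alpha)
      sig <- if (nrow(cmp)) cmp$protein_group[cmp$significant] else character(0)
      any_fp[s] <- length(setdiff(sig, affected)) > 0
      det[s] <- if (n_affected > 0) mean(affected %in% sig) else NA_real_
    }
  })
  list(fwer = mean(any_fp),
       power = if (n_affected > 0) mean(det) else NA_real_,
       n_sim = n_sim, alpha = alpha)
}
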