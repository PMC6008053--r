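# Protein-complex half-life cohesion: within-complex standard deviations,
# a size-matched resampling null, and a Mann-Whitney comparison.

#' Within-complex standard deviation of half-lives
#'
#' Computes the sample standard deviation (n-1 denominator) of the measured
#' half-lives of each complex's members. Complexes with fewer than
#' `min_members` annotated members or fewer than `min_measured` measured
#' half-lives are dropped; censored ("<1 day") members carry no numeric
#' half-life and are excluded from the SD.
#'
#' @param halflives data.frame with columns `protein_group`,
#'   `half_life_days` and optionally `censored`.
#' @param complexes data.frame with columns `complex_id`, `protein_group`
#'   (one member per row; memberships may overlap).
#' @param min_members minimum annotated complex size (default 5).
#' @param min_measured minimum measured half-lives (default 3).
#' @return data.frame: `complex_id`, `n_members`, `n_measured`, `sd_days`,
#'   plus Spearman correlation of size vs SD in attribute
#'   `size_sd_spearman` (NA when fewer than 3 complexes).
#' @examples
#' hl <- data.frame(protein_group = c("a", "b", "c", "d", "e"),
#'                  half_life_days = c(4, 6, 8, 5, 5))
#' cx <- data.frame(complex_id = "C1", protein_group = c("a", "b", "c", "d", "e"))
#' complex_sd(hl, cx)
#' @export
complex_sd <- function(halflives, complexes, min_members = 5, min_measured = 3) {
  hl <- as.data.frame(halflives)
  cx <- as.data.frame(complexes)
  if (!all(c("protein_group", "half_life_days") %in% names(hl)))
    stop_format("halflives needs columns protein_group, half_life_days")
  if (!all(c("complex_id", "protein_group") %in% names(cx)))
    stop_format("complexes needs columns complex_id, protein_group")
  if (!nrow(hl)) stop_format("half-life map is empty")
  if ("censored" %in% names(hl)) hl <- hl[!hl$censored, , drop = FALSE]
  hl <- hl[!is.na(hl$half_life_days), , drop = FALSE]

  cxd <- as.data.table(cx)
  sizes <- cxd[, .(n_members = uniqueN(protein_group)), by = complex_id]
  measured <- merge(cxd, as.data.table(hl[, c("protein_group", "half_life_days")]),
                    by = "protein_group")
  stats <- measured[, .(n_measured = uniqueN(protein_group),
                        sd_days = sd(half_life_days)), by = complex_id]
  out <- merge(sizes, stats, by = "complex_id", all.x = TRUE)
  out[is.na(n_measured), n_measured := 0L]
  out <- out[n_members >= min_members & n_measured >= min_measured]
  setorder(out, complex_id)
  out <- as.data.frame(out)
  attr(out, "size_sd_spearman") <- if (nrow(out) >= 3 &&
                                       sd(out$n_measured) > 0 &&
                                       sd(out$sd_days) > 0) {
    suppressWarnings(cor(out$n_measured, out$sd_days, method = "spearman"))
  } else NA_real_
  out
}

#' Size-matched resampling null for complex SDs
#'
#' For each of `n_rep` repetitions draws, for every group size in
#' `group_sizes`, a random group of half-lives from the measured population
#' (without replacement within a group by default, independently across
#' groups) and records its sample SD. This is the null distribution of
#' within-group SD for groups of the same number and sizes as the tested
#' complexes.
#'
#' @param halflives numeric vector of measured half-lives (the population).
#' @param group_sizes integer vector of group sizes to match.
#' @param n_rep repetitions (default 1000).
#' @param replace_within draw within a group with replacement (default
#'   `FALSE`).
#' @param seed integer seed.
#' @return numeric vector of `n_rep * length(group_sizes)` null SDs.
#' @export
random_sd_null <- function(halflives, group_sizes, n_rep = 1000,
                           replace_within = FALSE, seed = 1L) {
  halflives <- as.numeric(halflives[!is.na(halflives)])
  group_sizes <- as.integer(group_sizes)
  if (!length(halflives)) stop_format("empty half-life population")
  if (!length(group_sizes) || any(group_sizes < 2))
    stop_format("group sizes must be >= 2")
  if (!replace_within && max(group_sizes) > length(halflives))
    stop_format("population (%d) smaller than largest group (%d)",
                length(halflives), max(group_sizes))
  with_seed(seed, {
    out <- numeric(n_rep * length(group_sizes))
    idx <- 1L
    for (r in seq_len(n_rep)) {
      for (s in group_sizes) {
        g <- sample(halflives, s, replace = replace_within)
        out[idx] <- sd(g)
        idx <- idx + 1L
      }
    }
    out
  })
}

#' Mann-Whitney comparison of complex SDs against the resampling null
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the within-complex SD
#' distribution against the size-matched null SDs, using the tie-corrected
#' normal approximation.
#'
#' @param complex_sds numeric vector (or the `sd_days` column of a
#'   [complex_sd()] result).
#' @param null_sds numeric vector from [random_sd_null()].
#' @return list: `statistic` (U), `p_value`, `median_complex`,
#'   `median_null`.
#' @export
cohesion_test <- function(complex_sds, null_sds) {
  if (is.data.frame(complex_sds)) complex_sds <- complex_sds$sd_days
  complex_sds <- as.numeric(complex_sds[!is.na(complex_sds)])
  null_sds <- as.numeric(null_sds[!is.na(null_sds)])
  if (!length(complex_sds) || !length(null_sds))
    stop_format("both SD samples must be non-empty")
  if (length(unique(c(complex_sds, null_sds))) == 1L) {
    # fully tied samples: U sits at its expectation, no evidence either way
    return(list(statistic = length(complex_sds) * length(null_sds) / 2,
                p_value = 1,
                median_complex = median(complex_sds),
                median_null = median(null_sds)))
  }
  wt <- suppressWarnings(wilcox.test(complex_sds, null_sds,
                                     alternative = "two.sided",
                                     exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       median_complex = median(complex_sds),
       median_null = median(null_sds))
}
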