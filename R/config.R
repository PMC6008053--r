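#' Configuration for the dynamic SILAC simulator and experiment design
#'
#' Bundles the experimental design (timepoints, replicates, injections,
#' conditions) with the generative parameters of the synthetic-data module.
#' Defaults describe a pulsed-labeling design in mature primary cultures:
#' chase timepoints 0/1/3/7 days, three biological replicates measured in
#' triplicate injections, a 4:1 final heavy:light medium (heavy-incorporation
#' probability 0.8), and a right-skewed log-normal half-life distribution with
#' median 5.4 days.
#'
#' @param timepoints numeric vector of sampling times in days; must contain 0.
#' @param n_replicates number of biological replicates.
#' @param n_injections number of technical injections per sample.
#' @param p_heavy probability that a single Arg/Lys incorporated into a
#'   nascent protein is heavy; `0.8` corresponds to a 4:1 heavy:light medium.
#' @param halflife_median_days median of the log-normal half-life
#'   distribution, days.
#' @param halflife_log_sd standard deviation of log half-life.
#' @param peptides_per_protein_mean mean of the shifted-geometric (minimum 1)
#'   peptides-per-protein distribution.
#' @param missed_cleavage_prob probability that a peptide carries one missed
#'   tryptic cleavage (two labelable residues).
#' @param ratio_noise_log_sd standard deviation of multiplicative log-normal
#'   noise applied to the true heavy/light quotient.
#' @param dropout_prob mean probability that a single peptide measurement is
#'   missing from a given injection.
#' @param condition_multipliers named numeric vector of per-condition
#'   multipliers applied to the reference rate constant (e.g.
#'   `c(mixed = 1, glia_enriched = 1.4)`).
#' @param n_complexes number of multi-protein complexes to assign.
#' @param complex_size_range integer range (min, max) of complex sizes.
#' @param complex_icc intra-class correlation of log rate constants within a
#'   complex, in `[0, 1]`.
#' @param label_events_per_sample number of nascent missed-cleavage peptide
#'   labeling events simulated per chase sample for label-species counting.
#' @param seed integer seed from which all simulator streams are derived.
#' @return An object of class `silac_config` (a validated list).
#' @examples
#' cfg <- silac_config()
#' cfg$p_heavy
#' @export
silac_config <- function(timepoints = c(0, 1, 3, 7),
                         n_replicates = 3,
                         n_injections = 3,
                         p_heavy = 0.8,
                         halflife_median_days = 5.4,
                         halflife_log_sd = 0.55,
                         peptides_per_protein_mean = 6,
                         missed_cleavage_prob = 0.2,
                         ratio_noise_log_sd = 0.1,
                         dropout_prob = 0.1,
                         condition_multipliers = c(mixed = 1),
                         n_complexes = 0,
                         complex_size_range = c(5, 10),
                         complex_icc = 0.5,
                         label_events_per_sample = 2000,
                         seed = 1L) {
  timepoints <- sort(unique(as.numeric(timepoints)))
  if (!0 %in% timepoints)
    stop_format("config error: timepoints must include 0 (pre-switch sample)")
  if (length(timepoints) < 3)
    stop_format("config error: need t0 plus at least two chase timepoints")
  for (nm in c("p_heavy", "missed_cleavage_prob", "dropout_prob", "complex_icc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_format("config error: %s must be a probability in [0, 1]", nm)
  }
  if (p_heavy <= 0)
    stop_format("config error: p_heavy must be > 0 (some heavy label present)")
  for (nm in c("halflife_median_days", "peptides_per_protein_mean")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_format("config error: %s must be positive", nm)
  }
  if (peptides_per_protein_mean < 1)
    stop_format("config error: peptides_per_protein_mean must be >= 1")
  for (nm in c("halflife_log_sd", "ratio_noise_log_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_format("config error: %s must be non-negative", nm)
  }
  if (!is_count(n_replicates) || n_replicates < 1 ||
      !is_count(n_injections) || n_injections < 1)
    stop_format("config error: n_replicates and n_injections must be positive integers")
  if (!is_count(n_complexes))
    stop_format("config error: n_complexes must be a non-negative integer")
  complex_size_range <- as.integer(complex_size_range)
  if (length(complex_size_range) != 2L || any(complex_size_range < 1) ||
      complex_size_range[1] > complex_size_range[2])
    stop_format("config error: complex_size_range must be an increasing pair of positive integers")
  if (is.null(names(condition_multipliers)) || any(names(condition_multipliers) == "") ||
      anyDuplicated(names(condition_multipliers)))
    stop_format("config error: condition_multipliers must have unique names")
  if (!is.numeric(condition_multipliers) || any(condition_multipliers <= 0))
    stop_format("config error: condition multipliers must be positive")
  if (!is_count(label_events_per_sample) || label_events_per_sample < 1)
    stop_format("config error: label_events_per_sample must be a positive integer")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_format("config error: seed must be an integer")

  structure(list(
    timepoints = timepoints,
    n_replicates = as.integer(n_replicates),
    n_injections = as.integer(n_injections),
    p_heavy = p_heavy,
    halflife_median_days = halflife_median_days,
    halflife_log_sd = halflife_log_sd,
    peptides_per_protein_mean = peptides_per_protein_mean,
    missed_cleavage_prob = missed_cleavage_prob,
    ratio_noise_log_sd = ratio_noise_log_sd,
    dropout_prob = dropout_prob,
    condition_multipliers = condition_multipliers,
    n_complexes = as.integer(n_complexes),
    complex_size_range = complex_size_range,
    complex_icc = complex_icc,
    label_events_per_sample = as.integer(label_events_per_sample),
    seed = seed
  ), class = "silac_config")
}

#' @export
print.silac_config <- function(x, ...) {
  cat("dynamic SILAC simulation config\n")
  cat("  timepoints (d):", paste(x$timepoints, collapse = ", "), "\n")
  cat("  replicates x injections:", x$n_replicates, "x", x$n_injections, "\n")
  cat("  conditions:", paste(sprintf("%s (x%g)", names(x$condition_multipliers),
                                     x$condition_multipliers), collapse = ", "), "\n")
  cat("  p_heavy:", x$p_heavy,
      " half-life median:", x$halflife_median_days, "d",
      " log-sd:", x$halflife_log_sd, "\n")
  cat("  ratio noise log-sd:", x$ratio_noise_log_sd,
      " dropout:", x$dropout_prob, "\n")
  if (x$n_complexes > 0)
    cat("  complexes:", x$n_complexes, "of size",
        paste(x$complex_size_range, collapse = "-"),
        " ICC:", x$complex_icc, "\n")
  invisible(x)
}
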