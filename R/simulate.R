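# Synthetic-data generator: ground-truth proteome, forward model of the
# dynamic SILAC measurement, label-species counts, and puncta time courses.

# deterministic synthetic tryptic peptide sequences: unique body encoded in a
# K/R-free alphabet, an internal K for missed-cleavage peptides, C-terminal R
.aa_body <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]

synth_peptide_sequences <- function(idx, missed_cleavages) {
  base <- length(.aa_body)
  width <- 7L
  m <- matrix("", nrow = length(idx), ncol = width)
  rem <- idx - 1L
  for (j in seq_len(width)) {
    m[, width - j + 1L] <- .aa_body[rem %% base + 1L]
    rem <- rem %/% base
  }
  body1 <- apply(m[, 1:3, drop = FALSE], 1L, paste, collapse = "")
  body2 <- apply(m[, 4:7, drop = FALSE], 1L, paste, collapse = "")
  paste0(body1, ifelse(missed_cleavages > 0, "K", ""), body2, "R")
}

#' Construct a ground-truth proteome object by hand
#'
#' Builds the `true_proteome` container consumed by
#' [simulate_silac_experiment()] from explicit per-protein rate constants and
#' per-peptide annotations, bypassing the random generator. Useful for exact
#' closed-form checks.
#'
#' @param ground_truth data.frame with columns `protein_group`, `condition`,
#'   `k_true` (per day) and optionally `complex_id`.
#' @param peptides data.frame with columns `protein_group`, `sequence`,
#'   `missed_cleavages`, and optionally `detectability` (default 1).
#' @param config a [silac_config()].
#' @return An object of class `true_proteome`.
#' @export
true_proteome <- function(ground_truth, peptides, config = silac_config()) {
  ground_truth <- as.data.frame(ground_truth)
  peptides <- as.data.frame(peptides)
  need_gt <- c("protein_group", "condition", "k_true")
  if (!all(need_gt %in% names(ground_truth)))
    stop_format("ground_truth must have columns: %s", paste(need_gt, collapse = ", "))
  if (any(ground_truth$k_true <= 0))
    stop_format("k_true must be positive")
  if (!"complex_id" %in% names(ground_truth)) ground_truth$complex_id <- NA_character_
  ground_truth$half_life_true_days <- log(2) / ground_truth$k_true
  need_pep <- c("protein_group", "sequence", "missed_cleavages")
  if (!all(need_pep %in% names(peptides)))
    stop_format("peptides must have columns: %s", paste(need_pep, collapse = ", "))
  if (any(peptides$missed_cleavages < 0))
    stop_format("missed_cleavages must be >= 0")
  if (!"detectability" %in% names(peptides)) peptides$detectability <- 1
  structure(list(ground_truth = ground_truth, peptides = peptides,
                 config = config),
            class = "true_proteome")
}

#' Generate a ground-truth proteome
#'
#' Draws per-protein degradation rate constants from a right-skewed
#' log-normal half-life distribution, assigns proteins to multi-protein
#' complexes whose members share a common component of log rate constant
#' (intra-class correlation `complex_icc`), applies the per-condition rate
#' multipliers, and generates peptides (count, missed cleavages,
#' detectability) for each protein.
#'
#' @param n_proteins number of protein groups to generate.
#' @param config a [silac_config()].
#' @return An object of class `true_proteome`: a list with data.frames
#'   `ground_truth` (protein_group, condition, k_true, half_life_true_days,
#'   complex_id) and `peptides` (protein_group, sequence, missed_cleavages,
#'   detectability), plus the config used.
#' @examples
#' prot <- generate_proteome(50, silac_config(seed = 7))
#' median(prot$ground_truth$half_life_true_days)
#' @export
generate_proteome <- function(n_proteins, config = silac_config()) {
  if (!inherits(config, "silac_config")) stop_format("config must be a silac_config")
  if (!is_count(n_proteins) || n_proteins < 1)
    stop_format("n_proteins must be a positive integer")

  with_seed(config$seed, {
    sizes <- integer(0)
    if (config$n_complexes > 0) {
      sizes <- sample(seq(config$complex_size_range[1], config$complex_size_range[2]),
                      config$n_complexes, replace = TRUE)
      if (sum(sizes) > n_proteins)
        stop_format("config error: complex memberships (%d) exceed n_proteins (%d)",
                    sum(sizes), n_proteins)
    }
    complex_id <- rep(NA_character_, n_proteins)
    if (length(sizes)) {
      complex_id[seq_len(sum(sizes))] <-
        rep(sprintf("CPX%03d", seq_along(sizes)), times = sizes)
    }

    # shared + individual normal components on log half-life
    icc <- config$complex_icc
    z_ind <- rnorm(n_proteins)
    z <- z_ind
    if (length(sizes)) {
      z_cpx <- rnorm(length(sizes))
      member <- seq_len(sum(sizes))
      z[member] <- sqrt(icc) * rep(z_cpx, times = sizes) +
        sqrt(1 - icc) * z_ind[member]
    }
    half_life <- config$halflife_median_days * exp(config$halflife_log_sd * z)
    k_ref <- log(2) / half_life

    protein_group <- sprintf("PG%05d", seq_len(n_proteins))
    conds <- names(config$condition_multipliers)
    ground_truth <- data.frame(
      protein_group = rep(protein_group, times = length(conds)),
      condition = rep(conds, each = n_proteins),
      k_true = as.vector(outer(k_ref, config$condition_multipliers)),
      complex_id = rep(complex_id, times = length(conds)),
      stringsAsFactors = FALSE
    )
    ground_truth$half_life_true_days <- log(2) / ground_truth$k_true

    mean_pep <- config$peptides_per_protein_mean
    n_pep <- if (mean_pep > 1) 1L + rgeom(n_proteins, prob = 1 / mean_pep)
             else rep(1L, n_proteins)
    total <- sum(n_pep)
    mc <- rbinom(total, 1L, config$missed_cleavage_prob)
    d <- config$dropout_prob
    detectability <- if (d > 0) {
      kappa <- 20
      rbeta(total, shape1 = (1 - d) * kappa, shape2 = d * kappa)
    } else rep(1, total)
    peptides <- data.frame(
      protein_group = rep(protein_group, times = n_pep),
      sequence = synth_peptide_sequences(seq_len(total), mc),
      missed_cleavages = mc,
      detectability = detectability,
      stringsAsFactors = FALSE
    )
    true_proteome(ground_truth, peptides, config)
  })
}

#' Simulate a dynamic SILAC experiment
#'
#' Forward model of the measurement. For each peptide, condition, replicate,
#' injection and timepoint `t`, the true pre-existing fraction is
#' `f = exp(-k_true * t)`. Nascent molecules incorporate a heavy residue
#' independently with probability `p_heavy` per Arg/Lys (a peptide with `MC`
#' missed cleavages carries `MC + 1` such residues). The visible light
#' channel contains old molecules plus nascent all-light molecules; the
#' visible heavy channel contains nascent all-heavy molecules. Mixed-label
#' species of missed-cleavage peptides are invisible to the ratio channel
#' (only all-light/all-heavy SILAC partners are quantified) but are counted
#' into the label-species table. The emitted ratio is the heavy/light
#' quotient times multiplicative log-normal noise; measurements drop out
#' independently with each peptide's detectability. At `t = 0` no heavy
#' signal exists and peptides are flagged `light_only`.
#'
#' @param proteome a `true_proteome` from [generate_proteome()] or
#'   [true_proteome()].
#' @param config a [silac_config()]; defaults to the one stored in the
#'   proteome.
#' @return A list of class `silac_experiment` with data.frames `peptides`
#'   (PeptideTable layout), `label_counts` (per-sample LH/HH counts, t0
#'   excluded) and `ground_truth`.
#' @examples
#' prot <- generate_proteome(20, silac_config(seed = 2))
#' ex <- simulate_silac_experiment(prot)
#' head(ex$peptides)
#' @export
simulate_silac_experiment <- function(proteome, config = proteome$config) {
  if (!inherits(proteome, "true_proteome"))
    stop_format("proteome must be a true_proteome object")
  if (!inherits(config, "silac_config")) stop_format("config must be a silac_config")

  pep <- as.data.table(proteome$peptides)
  pep[, pep_id := .I]
  gt <- as.data.table(proteome$ground_truth)

  design <- CJ(pep_id = pep$pep_id,
               condition = names(config$condition_multipliers),
               replicate = sprintf("R%d", seq_len(config$n_replicates)),
               injection = sprintf("I%d", seq_len(config$n_injections)),
               timepoint = config$timepoints)
  dt <- merge(design, pep, by = "pep_id")
  dt <- merge(dt, gt[, .(protein_group, condition, k_true)],
              by = c("protein_group", "condition"))
  setorder(dt, condition, pep_id, replicate, injection, timepoint)

  p <- config$p_heavy
  dt[, `:=`(f_old = exp(-k_true * timepoint), n_res = missed_cleavages + 1L)]
  dt[, `:=`(light = f_old + (1 - f_old) * (1 - p)^n_res,
            heavy = (1 - f_old) * p^n_res)]

  with_seed(config$seed + 1L, {
    noise <- exp(rnorm(nrow(dt), 0, config$ratio_noise_log_sd))
    detected <- runif(nrow(dt)) < dt$detectability
  })
  dt[, ratio_HL := heavy / light * noise]
  dt[, light_only := heavy == 0]
  dt[light_only == TRUE, ratio_HL := NA_real_]
  dt <- dt[detected]

  peptides <- as.data.frame(dt[, .(sequence, protein_group, missed_cleavages,
                                   ratio_HL, light_only, timepoint, replicate,
                                   injection, condition)])

  label_counts <- simulate_label_counts(config, seed = config$seed + 2L)

  structure(list(peptides = peptides,
                 label_counts = label_counts,
                 ground_truth = proteome$ground_truth),
            class = "silac_experiment")
}

#' Simulate label-species counts for missed-cleavage peptides
#'
#' For every chase sample (condition x replicate x injection x timepoint > 0)
#' draws `label_events_per_sample` nascent missed-cleavage peptide labeling
#' events. Each of the two labelable residues is heavy independently with
#' probability `p_heavy`, so events fall into all-light (LL), mixed (LH) and
#' all-heavy (HH) classes with probabilities `(1-p)^2`, `2p(1-p)`, `p^2`.
#' Only LH and HH are observable (all-light nascent peptides are
#' indistinguishable from pre-existing ones) and are reported.
#'
#' @param config a [silac_config()].
#' @param seed integer seed (default derived from the config seed).
#' @return data.frame with columns condition, replicate, injection,
#'   timepoint, LH_count, HH_count.
#' @export
simulate_label_counts <- function(config = silac_config(),
                                  seed = config$seed + 2L) {
  if (!inherits(config, "silac_config")) stop_format("config must be a silac_config")
  samples <- CJ(condition = names(config$condition_multipliers),
                replicate = sprintf("R%d", seq_len(config$n_replicates)),
                injection = sprintf("I%d", seq_len(config$n_injections)),
                timepoint = setdiff(config$timepoints, 0))
  p <- config$p_heavy
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  with_seed(seed, {
    draws <- rmultinom(nrow(samples), size = config$label_events_per_sample,
                       prob = probs)
  })
  out <- as.data.frame(samples)
  out$LH_count <- draws[2L, ]
  out$HH_count <- draws[3L, ]
  out
}

#' Simulate a pulse-chase puncta time course
#'
#' Emulates counting of labelled puncta per cell after a metabolic pulse:
#' per-cell counts at chase time `t` are Poisson with mean
#' `n0 * exp(-log(2) * t / true_half_life)`.
#'
#' @param true_half_life true half-life of the target protein, days.
#' @param chase_days numeric vector of chase times, days (>= 0).
#' @param n_cells number of cells imaged per chase day.
#' @param n0 mean initial puncta count per cell.
#' @param target protein name carried into the output table.
#' @param seed integer seed.
#' @return data.frame with columns cell_id, chase_days, puncta_count, target.
#' @examples
#' pt <- simulate_puncta(1.9, chase_days = 0:3, n_cells = 25, n0 = 80, seed = 5)
#' aggregate(puncta_count ~ chase_days, pt, mean)
#' @export
simulate_puncta <- function(true_half_life, chase_days = c(0, 1, 2, 3),
                            n_cells = 30, n0 = 100, target = "protein",
                            seed = 1L) {
  if (!is.numeric(true_half_life) || true_half_life <= 0)
    stop_format("config error: true_half_life must be positive")
  if (!is.numeric(n0) || n0 <= 0)
    stop_format("config error: n0 must be positive")
  if (!is_count(n_cells) || n_cells < 1)
    stop_format("config error: n_cells must be a positive integer")
  chase_days <- as.numeric(chase_days)
  if (any(chase_days < 0) || anyDuplicated(chase_days) ||
      is.unsorted(chase_days, strictly = TRUE))
    stop_format("chase_days must be strictly increasing and non-negative")

  mu <- n0 * exp(-log(2) * chase_days / true_half_life)
  with_seed(seed, {
    counts <- rpois(n_cells * length(chase_days), rep(mu, each = n_cells))
  })
  data.frame(
    cell_id = sprintf("d%g_c%03d", rep(chase_days, each = n_cells),
                      rep(seq_len(n_cells), times = length(chase_days))),
    chase_days = rep(chase_days, each = n_cells),
    puncta_count = counts,
    target = target,
    stringsAsFactors = FALSE
  )
}
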