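# shared fixtures, all built in code at test time

# a minimal noiseless experiment with known rates, one condition
make_exact_experiment <- function(k = c(0.2, 0.1), n_peptides = 2,
                                  config = silac_config(
                                    p_heavy = 1, ratio_noise_log_sd = 0,
                                    dropout_prob = 0, seed = 99L)) {
  pg <- sprintf("PG%05d", seq_along(k))
  gt <- data.frame(protein_group = rep(pg, 1),
                   condition = "mixed", k_true = k)
  peps <- data.frame(
    protein_group = rep(pg, each = n_peptides),
    sequence = paste0("PEPTIDE", seq_len(length(k) * n_peptides), "R"),
    missed_cleavages = 0L
  )
  prot <- true_proteome(gt, peps, config)
  simulate_silac_experiment(prot, config)
}

# hand-written MaxQuant-style peptide TSV with decoy/contaminant rows
write_maxquant_fixture <- function(path) {
  lines <- c(
    paste("Sequence", "Proteins", "Missed cleavages", "Ratio H/L",
          "timepoint", "replicate", "injection", "condition",
          "Reverse", "Potential contaminant", sep = "\t"),
    "AAAAK\tPG1\t0\t0.5\t1\tR1\tI1\tmixed\t\t",
    "CCCCK\tPG1\t1\t1.2\t1\tR1\tI1\tmixed\t\t",
    "DDDDR\tPG2\t0\t0.8\t1\tR1\tI1\tmixed\t\t",
    "EEEEK\tREV__PG9\t0\t0.3\t1\tR1\tI1\tmixed\t+\t",
    "FFFFR\tCON__ALB\t0\t2.0\t1\tR1\tI1\tmixed\t\t+"
  )
  writeLines(lines, path)
  path
}

make_native_peptides <- function() {
  data.frame(
    sequence = c("AAAK", "AAAK", "CCCR", "DDDR", "EEEK"),
    protein_group = c("PG1", "PG1", "PG1", "PG2", "PG2"),
    missed_cleavages = c(0L, 0L, 1L, 0L, 0L),
    ratio_HL = c(NA, 0.25, 0.5, 1, NA),
    light_only = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    timepoint = c(0, 1, 1, 3, 0),
    replicate = "R1",
    injection = c("I1", "I1", "I1", "I1", "I2"),
    condition = "mixed",
    stringsAsFactors = FALSE
  )
}

# peptide-level %old profile values around exp(-k t) with lognormal ratio noise
make_profile_values <- function(k, timepoints = c(1, 3, 7), n_values = 20,
                                noise_log_sd = 0.05, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(protein = seq_along(k), timepoint = timepoints,
                      i = seq_len(n_values))
  f <- exp(-k[grid$protein] * grid$timepoint)
  ratio <- (1 / f - 1) * exp(rnorm(nrow(grid), 0, noise_log_sd))
  data.frame(protein_group = sprintf("PG%05d", grid$protein),
             timepoint = grid$timepoint,
             fraction_old = 1 / (1 + ratio))
}
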