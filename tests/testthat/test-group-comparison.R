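# cross-condition turnover comparison and its error-rate calibration

test_that("identical condition tables produce no significant calls", {
  prof <- make_profile_values(k = log(2) / c(2, 5, 9), seed = 3)
  cmp <- compare_culture_turnover(prof, prof)
  expect_equal(sum(cmp$significant), 0L)
  # equal means in the two tables can never be direction-consistent
  expect_true(all(cmp$direction == "inconsistent"))
})

test_that("a 1.4x rate effect is detected at all three chase timepoints", {
  set.seed(11)
  k <- log(2) / (5.4 * exp(rnorm(12, 0, 0.55)))
  kB <- k
  kB[1:4] <- k[1:4] * 1.4
  pa <- make_profile_values(k, seed = 21)
  pb <- make_profile_values(kB, seed = 22)
  cmp <- compare_culture_turnover(pa, pb)
  affected <- sprintf("PG%05d", 1:4)
  hit <- cmp[cmp$protein_group %in% affected, ]
  expect_true(all(hit$significant))
  expect_true(all(hit$direction == "faster_in_B"))
  expect_true(all(hit$sig_1d & hit$sig_3d & hit$sig_7d))
  expect_equal(sum(cmp$significant[!cmp$protein_group %in% affected]), 0L)
})

test_that("direction-inconsistent proteins are excluded from testing", {
  vals <- rbind(
    data.frame(protein_group = "PG1", timepoint = rep(c(1, 3, 7), each = 4),
               fraction_old = c(0.9, 0.9, 0.91, 0.92,   # above B at 1d
                                0.5, 0.5, 0.52, 0.51,   # below B at 3d
                                0.3, 0.31, 0.3, 0.32)),
    make_profile_values(log(2) / 4, n_values = 4, seed = 5))
  valsB <- rbind(
    data.frame(protein_group = "PG1", timepoint = rep(c(1, 3, 7), each = 4),
               fraction_old = c(0.7, 0.71, 0.7, 0.72,
                                0.65, 0.66, 0.64, 0.66,
                                0.2, 0.21, 0.2, 0.22)),
    make_profile_values(log(2) / 4, n_values = 4, seed = 6))
  cmp <- compare_culture_turnover(vals, valsB)
  row <- cmp[cmp$protein_group == "PG1", ]
  expect_equal(row$direction, "inconsistent")
  expect_true(all(is.na(row[, grepl("^p_", names(cmp))])))
  expect_false(row$significant)
})

test_that("swapping the condition tables flips directions and keeps p-values", {
  set.seed(9)
  k <- log(2) / (5.4 * exp(rnorm(8, 0, 0.4)))
  pa <- make_profile_values(k, seed = 31)
  pb <- make_profile_values(k * 1.3, seed = 32)
  ab <- compare_culture_turnover(pa, pb)
  ba <- compare_culture_turnover(pb, pa)
  ba <- ba[match(ab$protein_group, ba$protein_group), ]
  flip <- c(faster_in_A = "faster_in_B", faster_in_B = "faster_in_A",
            inconsistent = "inconsistent")
  expect_equal(unname(flip[ab$direction]), ba$direction)
  pcols <- grepl("^p_", names(ab))
  expect_equal(ab[, pcols], ba[, pcols], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ab$significant, ba$significant)
})

test_that("verdicts are invariant to row order", {
  set.seed(17)
  k <- log(2) / c(3, 6, 10)
  pa <- make_profile_values(k, seed = 41)
  pb <- make_profile_values(k * 1.5, seed = 42)
  cmp1 <- compare_culture_turnover(pa, pb)
  perm <- sample(nrow(pa))
  cmp2 <- compare_culture_turnover(pa[perm, ], pb[rev(seq_len(nrow(pb))), ])
  cmp2 <- cmp2[match(cmp1$protein_group, cmp2$protein_group), ]
  expect_equal(cmp1$significant, cmp2$significant)
  expect_equal(cmp1$direction, cmp2$direction)
})

test_that("paired decay test detects a doubled rate and removes negative decays", {
  set.seed(19)
  n_pep <- 15
  k <- log(2) / c(4, 6, 8)
  build <- function(kvec, seed) {
    set.seed(seed)
    rows <- expand.grid(protein = seq_along(kvec), pep = seq_len(n_pep),
                        timepoint = c(0, 7))
    f <- ifelse(rows$timepoint == 0, 1, exp(-kvec[rows$protein] * 7))
    noise <- exp(rnorm(nrow(rows), 0, 0.05))
    frac <- ifelse(rows$timepoint == 0, 1,
                   1 / (1 + (1 / f - 1) * noise))
    data.frame(protein_group = sprintf("PG%05d", rows$protein),
               sequence = sprintf("PEP%02d_%02d", rows$protein, rows$pep),
               timepoint = rows$timepoint, fraction_old = frac)
  }
  fa <- build(k, 51)
  kB <- k; kB[1] <- k[1] * 2
  fb <- build(kB, 52)
  res <- compare_paired_decay(fa, fb)
  expect_true(res$significant[res$protein_group == "PG00001"])
  expect_equal(sum(res$significant), 1L)

  # identical tables: nothing significant
  res0 <- compare_paired_decay(fa, fa)
  expect_equal(sum(res0$significant), 0L)

  # a peptide with negative decay in one condition is dropped from the pairing
  fa2 <- fa
  neg <- fa2$sequence == "PEP01_01" & fa2$timepoint == 7
  fa2$fraction_old[neg] <- 1.0  # decay at t0 minus 7d becomes negative
  fa2$fraction_old[fa2$sequence == "PEP01_01" & fa2$timepoint == 0] <- 0.9
  res2 <- compare_paired_decay(fa2, fb)
  expect_equal(res2$n_peptides[res2$protein_group == "PG00001"], n_pep - 1L)
})

test_that("proteins with too few matched peptides are skipped with a record", {
  fa <- data.frame(protein_group = "PG1", sequence = "ONLYONEK",
                   timepoint = c(0, 7), fraction_old = c(1, 0.5))
  expect_warning(res <- compare_paired_decay(fa, fa), "enough matched")
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped"), "PG1")
})

test_that("the family-wise error audit is calibrated and alpha = 0 silences everything", {
  audit <- type_one_error_audit(n_sim = 50, n_proteins = 10, n_values = 10,
                                seed = 61)
  expect_lte(audit$fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
  zero <- type_one_error_audit(n_sim = 10, alpha = 0, n_proteins = 5,
                               n_values = 8, seed = 62)
  expect_equal(zero$fwer, 0)
  pw <- type_one_error_audit(n_sim = 20, n_proteins = 10, n_values = 20,
                             effect_multiplier = 1.4, n_affected = 3,
                             seed = 63)
  expect_gt(pw$power, 0.9)
})
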