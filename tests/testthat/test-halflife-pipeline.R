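# peptide filtering, outlier removal, monotonicity, censoring, decay fitting

make_frac_row <- function(sequence, protein_group, timepoint, injection,
                          fraction_old, replicate = "R1",
                          condition = "mixed") {
  data.frame(sequence = sequence, protein_group = protein_group,
             missed_cleavages = 0L, ratio_HL = NA_real_, light_only = FALSE,
             timepoint = timepoint, replicate = replicate,
             injection = injection, condition = condition,
             fraction_light = fraction_old, fraction_old = fraction_old,
             excluded = FALSE, exclude_reason = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("peptide filter enforces timepoint coverage, t0 purity and uniqueness", {
  tps <- c(0, 1, 3, 7)
  full <- do.call(rbind, lapply(tps, function(t)
    make_frac_row("GOODK", "PG1", t, "I1", exp(-0.1 * t) + (t == 0) * 0)))
  missing_tp <- do.call(rbind, lapply(c(0, 1, 3), function(t)
    make_frac_row("PARTIALK", "PG1", t, "I1", exp(-0.1 * t))))
  low_t0 <- do.call(rbind, lapply(tps, function(t)
    make_frac_row("LOWK", "PG2", t, "I1", ifelse(t == 0, 0.85, exp(-0.1 * t)))))
  shared <- do.call(rbind, lapply(tps, function(t)
    make_frac_row("SHAREDK", "PG1;PG2", t, "I1", exp(-0.1 * t))))
  tab <- rbind(full, missing_tp, low_t0, shared)
  out <- filter_peptides(tab, timepoints = tps)
  expect_setequal(unique(out$sequence), "GOODK")
  # clean peptide with t0 mean 0.97 is retained
  ok <- do.call(rbind, lapply(tps, function(t)
    make_frac_row("FINEK", "PG3", t, "I1", ifelse(t == 0, 0.97, exp(-0.1 * t)))))
  expect_equal(nrow(filter_peptides(rbind(tab, ok), timepoints = tps)), 8L)
})

test_that("Tukey fences remove only values outside 1.5 IQR (type-7 quartiles)", {
  x <- c(0.88, 0.90, 0.91, 0.92, 0.20)
  expect_setequal(remove_outliers(x), c(0.88, 0.90, 0.91, 0.92))
  expect_equal(remove_outliers(rep(0.7, 6)), rep(0.7, 6))
  expect_equal(sort(remove_outliers(c(0.1, 0.9))), c(0.1, 0.9))
  expect_error(remove_outliers(numeric(0)), "at least one")
})

test_that("fence filtering matches a brute-force check on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    x <- runif(sample(2:30, 1))
    q1 <- quantile(x, 0.25, names = FALSE)
    q3 <- quantile(x, 0.75, names = FALSE)
    brute <- x[x >= q1 - 1.5 * (q3 - q1) & x <= q3 + 1.5 * (q3 - q1)]
    expect_identical(remove_outliers(x), brute)
  }
})

test_that("monotonic decay check honours the additive tolerance", {
  expect_true(check_monotonic_decay(c(1.0, 0.8, 0.6, 0.4)))
  expect_false(check_monotonic_decay(c(1.0, 0.7, 0.9, 0.5), tolerance = 0.05))
  expect_true(check_monotonic_decay(c(1.0, 0.80, 0.81, 0.5), tolerance = 0.05))
})

test_that("fast-turnover censoring separates well-separated populations", {
  tps <- c(0, 1, 3, 7)
  k <- c(rep(1.5, 20), rep(0.1, 40))
  means <- t(vapply(k, function(ki) exp(-ki * tps), numeric(4)))
  rownames(means) <- sprintf("PG%05d", seq_along(k))
  colnames(means) <- tps
  cens <- cluster_fast_turnover(means, k_clusters = 6, seed = 3)
  expect_setequal(cens, sprintf("PG%05d", 1:20))
  # direct-rule fallback with fewer profiles than clusters
  small <- means[c(1, 30), , drop = FALSE]
  expect_equal(cluster_fast_turnover(small, k_clusters = 6),
               rownames(small)[1])
  # slow protein with %old(1d) = 0.95 is never censored
  expect_false("PG00060" %in% cens)
})

test_that("no-intercept fit recovers exact and definitional cases", {
  t <- c(0, 1, 3, 7)
  fit <- fit_halflife(t, exp(-0.2 * t))
  expect_equal(fit$k_per_day, 0.2, tolerance = 1e-12)
  expect_equal(fit$half_life_days, log(2) / 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$se_k, 0, tolerance = 1e-12)
  fit1 <- fit_halflife(t, exp(-log(2) * t))
  expect_equal(fit1$half_life_days, 1, tolerance = 1e-12)
  expect_equal(fit1$k_per_day * fit1$half_life_days, log(2))
})

test_that("fit matches the normal-equations oracle on noisy points", {
  set.seed(7)
  t <- sample(c(1, 3, 7), 50, replace = TRUE)
  y_true <- exp(-0.128 * t)
  frac <- 1 / (1 + (1 / y_true - 1) * exp(rnorm(50, 0, 0.1)))
  fit <- fit_halflife(t, frac)
  oracle_slope <- sum(t * log(frac)) / sum(t^2)
  expect_equal(fit$k_per_day, -oracle_slope, tolerance = 1e-10)
  expect_equal(fit$half_life_days, log(2) / -oracle_slope, tolerance = 1e-10)
})

test_that("fit is invariant to point order and duplication shrinks the error", {
  set.seed(15)
  t <- rep(c(0, 1, 3, 7), each = 5)
  frac <- pmin(1, exp(-0.2 * t) * exp(rnorm(length(t), 0, 0.05)))
  fit <- fit_halflife(t, frac)
  perm <- sample(seq_along(t))
  fit_perm <- fit_halflife(t[perm], frac[perm])
  expect_equal(fit$k_per_day, fit_perm$k_per_day, tolerance = 1e-12)
  fit_dup <- fit_halflife(c(t, t), c(frac, frac))
  expect_equal(fit_dup$k_per_day, fit$k_per_day, tolerance = 1e-12)
  expect_lt(fit_dup$se_k, fit$se_k)
})

test_that("non-decaying profiles are flagged instead of fitted", {
  t <- c(0, 1, 3, 7, 1, 3, 7)
  fit <- fit_halflife(t, c(1, 1.01, 1.05, 1.1, 1.0, 1.04, 1.12))
  expect_true(is.na(fit$k_per_day))
  expect_equal(fit$reason, "nonpositive_rate")
  expect_error(fit_halflife(c(0, 1), c(1, 0.5)), ">= 3")
})

test_that("half-life is strictly decreasing in the rate constant", {
  ks <- seq(0.05, 2, length.out = 40)
  hls <- log(2) / ks
  expect_true(all(diff(hls) < 0))
  t <- c(0, 1, 3, 7)
  fitted <- vapply(ks, function(k) fit_halflife(t, exp(-k * t))$half_life_days,
                   numeric(1))
  expect_true(all(diff(fitted) < 0))
})

test_that("noiseless pipeline recovers every rate constant to 1e-9", {
  cfg <- silac_config(seed = 23L, p_heavy = 1, ratio_noise_log_sd = 0,
                      dropout_prob = 0)
  prot <- generate_proteome(100, cfg)
  ex <- simulate_silac_experiment(prot)
  res <- run_pipeline(ex$peptides, purity = 1)
  hl <- res$halflives[!res$halflives$censored, ]
  gt <- ex$ground_truth
  k_true <- gt$k_true[match(hl$protein_group, gt$protein_group)]
  expect_gt(nrow(hl), 90)
  expect_lt(max(abs(hl$k_per_day - k_true)), 1e-9)
})

test_that("a table failing the t0 filter yields an empty result with a logged exclusion", {
  tps <- c(0, 1, 3, 7)
  # heavy signal already at t0: the old fraction there is only 0.5
  frac <- ifelse(tps == 0, 0.5, exp(-0.1 * tps))
  tab <- data.frame(sequence = "DIRTYK", protein_group = "PG1",
                    missed_cleavages = 0L, ratio_HL = (1 - frac) / frac,
                    light_only = FALSE, timepoint = tps, replicate = "R1",
                    injection = "I1", condition = "mixed")
  res <- suppressMessages(run_pipeline(tab, purity = 1))
  expect_equal(nrow(res$halflives), 0L)
  excl <- res$exclusions
  expect_gt(excl$n_removed[excl$stage == "peptide_filter"], 0)
})

test_that("censored records carry no rate constant in pipeline output", {
  cfg <- silac_config(seed = 29L, p_heavy = 1, ratio_noise_log_sd = 0,
                      dropout_prob = 0, halflife_median_days = 0.8,
                      halflife_log_sd = 0.1)
  prot <- generate_proteome(30, cfg)
  ex <- simulate_silac_experiment(prot)
  res <- run_pipeline(ex$peptides, purity = 1)
  cens <- res$halflives[res$halflives$censored, ]
  expect_gt(nrow(cens), 0)
  expect_true(all(is.na(cens$k_per_day)))
  expect_true(all(is.na(cens$half_life_days)))
  fitted <- res$halflives[!res$halflives$censored, ]
  if (nrow(fitted))
    expect_equal(fitted$half_life_days * fitted$k_per_day,
                 rep(log(2), nrow(fitted)), tolerance = 1e-12)
})
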