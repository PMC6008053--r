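# ground-truth generator and forward model of the dynamic SILAC measurement

test_that("generated half-life distribution matches the configured median", {
  cfg <- silac_config(seed = 21L)
  prot <- generate_proteome(2000, cfg)
  hl <- prot$ground_truth$half_life_true_days
  expect_lt(abs(median(hl) / cfg$halflife_median_days - 1), 0.05)
  expect_true(all(prot$ground_truth$k_true > 0))
  # right-skewed span: some fast and some very slow proteins
  expect_gt(mean(hl) , median(hl))
  expect_gt(max(hl), 20)
})

test_that("zero log-sd collapses all half-lives onto the median", {
  cfg <- silac_config(halflife_log_sd = 0, seed = 4L)
  prot <- generate_proteome(50, cfg)
  expect_equal(prot$ground_truth$half_life_true_days,
               rep(5.4, 50), tolerance = 1e-12)
})

test_that("the generator is deterministic given the seed", {
  cfg <- silac_config(seed = 77L, n_complexes = 5)
  p1 <- generate_proteome(100, cfg)
  p2 <- generate_proteome(100, cfg)
  expect_identical(p1$ground_truth, p2$ground_truth)
  expect_identical(p1$peptides, p2$peptides)
  e1 <- simulate_silac_experiment(p1)
  e2 <- simulate_silac_experiment(p2)
  expect_identical(e1$peptides, e2$peptides)
  expect_identical(e1$label_counts, e2$label_counts)
})

test_that("noiseless forward model reproduces the closed-form ratio", {
  # k = 0.2/d, t = 1 d, full heavy incorporation, fully tryptic peptide:
  # H/L = (1 - e^-0.2) / e^-0.2
  ex <- make_exact_experiment(k = 0.2, n_peptides = 1)
  row <- subset(ex$peptides, timepoint == 1)[1, ]
  expect_equal(row$ratio_HL, (1 - exp(-0.2)) / exp(-0.2), tolerance = 1e-12)
  expect_equal(row$ratio_HL, 0.2214, tolerance = 1e-4)
})

test_that("t0 peptides are light-only with no ratio", {
  ex <- make_exact_experiment(k = c(0.5, 0.05))
  t0 <- subset(ex$peptides, timepoint == 0)
  expect_true(all(t0$light_only))
  expect_true(all(is.na(t0$ratio_HL)))
  expect_false(any(subset(ex$peptides, timepoint > 0)$light_only))
})

test_that("label-species counts follow the two-residue binomial model", {
  cfg <- silac_config(seed = 31L, label_events_per_sample = 5000)
  lc <- simulate_label_counts(cfg)
  # 27 chase samples x 5000 events
  expect_equal(nrow(lc), 27L)
  LH <- sum(lc$LH_count); HH <- sum(lc$HH_count)
  expect_gt(LH + HH, 10000)
  # HH/LH ~ p^2 / (2 p (1-p)) = 2 at p = 0.8, within binomial error
  expect_equal(HH / LH, 2, tolerance = 0.05)

  # all-heavy fraction among doubly-labeled nascent events -> p_heavy^2
  n_events <- 1e5
  cfg2 <- silac_config(seed = 8L, label_events_per_sample = ceiling(n_events / 27))
  lc2 <- simulate_label_counts(cfg2)
  total <- 27 * cfg2$label_events_per_sample
  p_hat <- sum(lc2$HH_count) / total
  p_true <- 0.8^2
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / total))
})

test_that("condition multiplier scales true half-lives exactly", {
  cfg <- silac_config(seed = 13L,
                      condition_multipliers = c(mixed = 1, glia_enriched = 1.4))
  prot <- generate_proteome(40, cfg)
  gt <- prot$ground_truth
  ref <- gt[gt$condition == "mixed", ]
  fast <- gt[gt$condition == "glia_enriched", ]
  fast <- fast[match(ref$protein_group, fast$protein_group), ]
  expect_equal(fast$half_life_true_days, ref$half_life_true_days / 1.4,
               tolerance = 1e-12)
})

test_that("within-complex rate constants share the configured common component", {
  cfg <- silac_config(seed = 19L, n_complexes = 60,
                      complex_size_range = c(5, 8), complex_icc = 0.8)
  prot <- generate_proteome(600, cfg)
  gt <- subset(prot$ground_truth, !is.na(complex_id))
  logk <- log(gt$k_true)
  within_var <- mean(tapply(logk, gt$complex_id, var))
  total_var <- var(logk)
  icc_hat <- 1 - within_var / total_var
  expect_gt(icc_hat, 0.6)  # close to 0.8 given 60 complexes
})

test_that("puncta simulation has Poisson means n0 * 2^(-t / t_half)", {
  pt <- simulate_puncta(1, chase_days = 0:3, n_cells = 3000, n0 = 100, seed = 6)
  means <- tapply(pt$puncta_count, pt$chase_days, mean)
  expect_equal(as.numeric(means), c(100, 50, 25, 12.5), tolerance = 0.03)
  expect_identical(pt, simulate_puncta(1, chase_days = 0:3, n_cells = 3000,
                                       n0 = 100, seed = 6))
  expect_error(simulate_puncta(2, n0 = -1), "n0")
  one_day <- simulate_puncta(3, chase_days = 0, n_cells = 2000, n0 = 80, seed = 2)
  expect_equal(mean(one_day$puncta_count), 80, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(silac_config(timepoints = c(1, 3, 7)), "include 0")
  expect_error(silac_config(p_heavy = 1.2), "probability")
  expect_error(silac_config(halflife_median_days = -1), "positive")
  expect_error(silac_config(condition_multipliers = c(1, 1.4)), "names")
  cfg <- silac_config(n_complexes = 100, complex_size_range = c(5, 5))
  expect_error(generate_proteome(50, cfg), "exceed")
})
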