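# Generators: determinism, null behaviour, and recoverability of the
# planted truth by the downstream stage.

test_that("all generators are deterministic given config and seed", {
  cfg <- screen_sim_config(n_strains = 50, depth = 1e4, seed = 7)
  expect_identical(simulate_screen_counts(cfg)$counts,
                   simulate_screen_counts(cfg)$counts)
  g <- growth_sim_config(noise_sd = 0.02, seed = 5)
  expect_identical(simulate_growth_curves(g, c(0, 1, 10))$readings,
                   simulate_growth_curves(g, c(0, 1, 10))$readings)
  s <- spheroid_sim_config(noise_sd = 0.05, seed = 3)
  expect_identical(simulate_spheroid_plate(s)$area_end,
                   simulate_spheroid_plate(s)$area_end)
  f <- fluctuation_sim_config(mu = 2e-8, seed = 11)
  expect_identical(simulate_fluctuation(f), simulate_fluctuation(f))
  expect_identical(simulate_conservation(100, 4, 10, seed = 2),
                   simulate_conservation(100, 4, 10, seed = 2))
})

test_that("screen counts: null model has drug/control ratios near 1", {
  cfg <- screen_sim_config(n_strains = 300, dispersion = 1e-13,
                           depth = 5e6, seed = 1)
  tab <- simulate_screen_counts(cfg)
  cond <- tab$sample_meta$condition
  ratio <- rowMeans(tab$counts[, cond == "drug"]) /
    rowMeans(tab$counts[, cond == "control"])
  expect_lt(max(abs(ratio - 1)), 0.1)
})

test_that("screen config validates planted ids and parameters", {
  expect_error(screen_sim_config(n_strains = 10,
                                 planted_resistors = data.frame(
                                   strain = 11, log2fc = 5)),
               "within the library")
  expect_error(screen_sim_config(depth = -1), "depth")
  expect_error(
    screen_sim_config(n_strains = 10,
                      planted_resistors = data.frame(strain = c(2, 2),
                                                     log2fc = c(1, 2))),
    "unique")
})

test_that("simulated reads round-trip through count_barcodes", {
  db <- simulate_barcode_db(30, seed = 2)
  set.seed(21)
  cnts <- stats::setNames(rpois(30, 30), names(db))
  reads <- simulate_screen_reads(cnts, db, error_rate = 0, seed = 5)
  expect_length(reads, sum(cnts))
  res <- count_barcodes(reads, db)
  expect_equal(res$counts, cnts)
  expect_equal(res$unassigned, 0L)
  # all-zero counts give an empty read set
  zero <- stats::setNames(integer(30), names(db))
  expect_length(simulate_screen_reads(zero, db), 0)
  # unknown barcode id is an input error
  expect_error(simulate_screen_reads(c(nope = 5L), db), "unknown")
})

test_that("reads with 1% errors are recovered within 2% with rescue", {
  db <- simulate_barcode_db(40, seed = 3)
  set.seed(31)
  cnts <- stats::setNames(rpois(40, 60), names(db))
  reads <- simulate_screen_reads(cnts, db, error_rate = 0.01, seed = 6)
  res <- count_barcodes(reads, db, max_mismatch = 1)
  expect_lt(sum(abs(res$counts - cnts)) / sum(cnts), 0.02)
})

test_that("growth curves obey the Hill plateau scaling", {
  g <- growth_sim_config(noise_sd = 0, ic50_true = 10, hill = 3, seed = 1)
  ps <- simulate_growth_curves(g, c(0, 10, 40))
  resp <- relative_growth(ps, 720)
  expect_equal(resp$response[resp$dose_um == 0], 1.0, tolerance = 1e-9)
  # dose = ic50 gives exactly half the zero-dose growth
  expect_equal(resp$response[resp$dose_um == 10], 0.5, tolerance = 1e-9)
  expect_error(simulate_growth_curves(g, c(-1, 0)), "doses")
})

test_that("spheroid plates shift their EC50 front with the degradation sign", {
  base <- simulate_spheroid_plate(spheroid_sim_config(noise_sd = 0, seed = 1))
  deg <- simulate_spheroid_plate(spheroid_sim_config(
    degradation_coefficient = 1.5, noise_sd = 0, seed = 1))
  slow <- simulate_spheroid_plate(spheroid_sim_config(
    degradation_coefficient = -1.0, noise_sd = 0, seed = 1))
  # analytic per-row EC50 of the generator moves with the coefficient
  expect_true(all(attr(deg, "truth")$ec50_dose >=
                    attr(base, "truth")$ec50_dose))
  expect_gt(attr(deg, "truth")$ec50_dose[1],
            attr(base, "truth")$ec50_dose[1])
  expect_lt(attr(slow, "truth")$ec50_dose[1],
            attr(base, "truth")$ec50_dose[1])
  # zero-coefficient plate: all bacteria rows share one dose response
  expect_lt(max(apply(base$area_end / base$area_t0, 2,
                      function(col) diff(range(col)))), 1e-9)
  # zero-drug column is unaffected by bacteria level
  nz <- normalize_spheroids(deg)
  zero_col <- nz$normalized[, ncol(nz$normalized)]
  expect_lt(diff(range(zero_col)), 1e-9)
})

test_that("fluctuation generator matches the closed-form zero probability", {
  # P(0 colonies) = e^-m at full plating
  cfg <- fluctuation_sim_config(mu = 1 / (1e8 - 730), N0 = 730, Nt = 1e8,
                                epsilon = 1, n_cultures = 2e5, seed = 17)
  counts <- simulate_fluctuation(cfg)
  expect_equal(attr(counts, "m"), 1)
  expect_equal(mean(counts == 0), exp(-1), tolerance = 0.01)
  # mu = 0 -> all zero
  cfg0 <- fluctuation_sim_config(mu = 0, n_cultures = 50, seed = 1)
  expect_true(all(simulate_fluctuation(cfg0) == 0))
})

test_that("conservation generator respects its edge cases", {
  sim <- simulate_conservation(30, 2, 30, seed = 1)
  expect_equal(sim$positions, 1:30)   # n_mut = length mutates everything
  expect_true(all(sim$scores %in% 1:9))
  expect_error(simulate_conservation(10, 2, 11), "n_mut")
  # strong bias concentrates mutations on conserved residues
  sim2 <- simulate_conservation(500, 64, 40, seed = 2)
  expect_gt(mean(sim2$scores[sim2$positions]), mean(sim2$scores))
})

test_that("mutate_sequence applies descriptors exactly", {
  ref <- random_cds(60, seed = 5)
  # same-base substitution is the identity
  b <- substr(ref, 30, 30)
  expect_identical(mutate_sequence(ref, list(type = "substitution",
                                             pos = 30, base = b)), ref)
  del <- mutate_sequence(ref, list(type = "deletion", pos = 10, len = 2))
  expect_equal(nchar(del), nchar(ref) - 2)
  ins <- mutate_sequence(ref, list(type = "insertion", pos = 10,
                                   seq = "ACGT"))
  expect_equal(nchar(ins), nchar(ref) + 4)
  expect_error(mutate_sequence(ref, list(type = "substitution",
                                         pos = nchar(ref) + 1, base = "A")),
               "out of range")
})

test_that("conservation_bias_test is calibrated on unbiased profiles", {
  # with bias 1 the mutated positions are a uniform subset, so one-sided
  # p-values against the exclusive background are uniform
  pvals <- vapply(1:200, function(i) {
    sim <- simulate_conservation(120, 1, 15, seed = 1000 + i)
    conservation_bias_test(sim$scores, sim$positions,
                           background = "exclusive")$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
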