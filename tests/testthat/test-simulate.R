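test_that("serial dilution series match the printed designs", {
  expect_equal(dose_series(20, 5, 5), c(20, 4, 0.8, 0.16, 0.032))
  expect_equal(dose_series(7, 2, 1), 7)
  expect_equal(round(dose_series(20, 3, 9)[9], 3), 0.003)
  expect_error(dose_series(20, 1, 5), class = "validation_error")
  expect_error(dose_series(20, 5, 0), class = "validation_error")
})

test_that("a fixed seed reproduces byte-identical plate CSVs", {
  spec <- surface_spec(noise_sigma = 0.05, seed = 42L)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(simulate_matrix(spec)$records, p1)
  write_plate_table(simulate_matrix(spec)$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noiseless simulate -> normalize -> score recovers truth exactly", {
  for (delta in c(0, 0.15)) {
    sim <- suppressWarnings(simulate_matrix(
      surface_spec(bliss_offset = delta, noise_sigma = 0, seed = 13L)))
    mat <- normalize_matrix(sim$records, plate_qc(sim$records))
    s <- score_matrix(mat)
    expect_equal(s$excess_hsa_sum, sim$truth_score$excess_hsa_sum,
                 tolerance = 1e-9)
    expect_equal(s$excess_bliss_sum, sim$truth_score$excess_bliss_sum,
                 tolerance = 1e-9)
  }
  # Bliss-null surface scores 0 on the Bliss scale
  sim0 <- simulate_matrix(surface_spec(noise_sigma = 0, seed = 14L))
  mat0 <- normalize_matrix(sim0$records)
  expect_equal(excess_bliss(mat0)$sum, 0, tolerance = 1e-9)
  # delta = +0.15 classifies synergistic on a 6x6 design
  sim15 <- suppressWarnings(simulate_matrix(
    surface_spec(bliss_offset = 0.15, noise_sigma = 0, seed = 15L)))
  mat15 <- normalize_matrix(sim15$records)
  expect_lt(score_matrix(mat15)$excess_hsa_sum, -20)
})

test_that("increasing the Bliss offset strictly lowers the recovered sum", {
  deltas <- c(-0.05, 0, 0.05, 0.1, 0.15)
  sums <- vapply(deltas, function(d) {
    sim <- suppressWarnings(simulate_matrix(
      surface_spec(bliss_offset = d, noise_sigma = 0, seed = 16L)))
    excess_bliss(normalize_matrix(sim$records))$sum
  }, numeric(1))
  expect_true(all(diff(sums) < 0))
})

test_that("excess clipping beyond 5% of combo wells raises a warning", {
  expect_warning(simulate_matrix(surface_spec(bliss_offset = 0.5,
                                              noise_sigma = 0)),
                 class = "clipping_warning")
})

test_that("median-effect parameters are recovered from simulated margins", {
  spec <- surface_spec(dm_a = 2.5, m_a = 1.7, noise_sigma = 0,
                       top_a = 40, fold_a = 3, n_a = 9, seed = 17L)
  sim <- simulate_matrix(spec)
  mat <- normalize_matrix(sim$records)
  fit <- median_effect_fit(mat$doses_a[-1], 1 - mat$viability[-1, 1] / 100)
  expect_equal(fit$Dm, 2.5, tolerance = 1e-6)
  expect_equal(fit$m, 1.7, tolerance = 1e-6)
})

test_that("simulated library has the designed shape and truth labels", {
  classes <- data.frame(
    moa_class = c("syn", "null"), n = c(3L, 2L), delta = c(0.2, 0),
    partner_dm = c(1, 2000), partner_m = c(1, 1))
  lib <- simulate_library(classes, cell_lines = c("CL1", "CL2"),
                          noise_sigma = 0, seed = 5L)
  expect_equal(nrow(lib$manifest), 10L)  # 5 compounds x 2 lines
  expect_equal(sum(lib$records$role == "sample" &
                     lib$records$dose_a > 0 & lib$records$dose_b > 0),
               10L * 25L)
  expect_equal(sum(lib$truth_compound$label == "synergistic"), 3L)
  expect_equal(lib$truth_compound$label[lib$truth_compound$moa_class == "null"],
               rep("additive", 2))

  # zero offsets with inert partners: no synergy anywhere
  null_cls <- data.frame(moa_class = "null", n = 4L, delta = 0,
                         partner_dm = 2000, partner_m = 1)
  lib0 <- simulate_library(null_cls, cell_lines = "CL1", noise_sigma = 0,
                           seed = 6L)
  expect_equal(mean(lib0$truth_compound$label == "synergistic"), 0)
})

test_that("growth simulation hits the closed-form TGI identities", {
  sp <- growth_spec(effects = c(vehicle = 0, cytostatic = 1, inert = 0.0001),
                    sigma = 0, seed = 8L)
  g <- simulate_growth(sp)
  expect_equal(g$truth$true_tgi[g$truth$arm == "cytostatic"], 100)
  expect_equal(g$truth$true_tgi[g$truth$arm == "inert"], 0, tolerance = 0.1)
  tab <- tgi_table(g$curves)
  expect_equal(tab$tgi[tab$arm == "cytostatic"], 100, tolerance = 1e-9)
})

test_that("estimated TGI tracks truth within 3 SE and rises with effect", {
  sp <- function(e, seed) growth_spec(effects = c(vehicle = 0, trt = e),
                                      sigma = 0.1, n_animals = 7,
                                      seed = seed)
  true_tgi <- simulate_growth(sp(1.2, 1))$truth$true_tgi
  est <- vapply(1:200, function(s) {
    g <- simulate_growth(sp(1.2, s))
    tgi(g$curves, "trt")$tgi
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_tgi), 3 * se)

  mean_tgi <- vapply(c(0.2, 0.6, 1.0, 1.4), function(e) {
    mean(vapply(1:30, function(s) tgi(simulate_growth(sp(e, s))$curves,
                                      "trt")$tgi, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_tgi) > 0))
})
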