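test_that("ExcessHSA is zero on an HSA-identity matrix and matches arithmetic", {
  h <- excess_hsa(hsa_identity_matrix())
  expect_equal(h$grid, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(h$sum, 0)
  expect_equal(classify_interaction(h$sum), "additive")

  # single combo well: combo 40 vs single agents 70 and 60 -> excess -20
  m <- make_matrix(c(0, 1), c(0, 1), rbind(c(100, 60), c(70, 40)))
  expect_equal(excess_hsa(m)$grid[1, 1], 40 - min(70, 60))
  expect_equal(excess_hsa(m)$sum, -20)
})

test_that("a 6x6 matrix of -1 excesses sums to -25 and classifies synergistic", {
  doses <- c(0, dose_series(20, 5, 5)[5:1])
  v <- matrix(100, 6, 6)
  v[2:6, 2:6] <- 99  # single agents inert; each combo well 1 point below HSA
  m <- make_matrix(doses, doses, v)
  s <- score_matrix(m)
  expect_equal(s$excess_hsa_sum, -25)
  expect_equal(s$interaction_class, "synergistic")
})

test_that("Bliss excess is zero when survival fractions multiply", {
  # inert partner: expected viability equals the active agent's
  m <- bliss_null_matrix(va = c(100, 80, 50), vb = c(100, 100, 100))
  expect_equal(excess_bliss(m)$sum, 0)
  # 50 x 50 -> 25 observed = expected
  m2 <- make_matrix(c(0, 1), c(0, 1), rbind(c(100, 50), c(50, 25)))
  expect_equal(excess_bliss(m2)$grid[1, 1], 0)
  expect_equal(excess_bliss(bliss_null_matrix())$sum, 0)
})

test_that("mean per-well Bliss excess on noisy null plates is within 3 SE", {
  sigma <- 0.03
  n_rep <- 40
  per_well <- unlist(lapply(seq_len(n_rep), function(s) {
    sim <- simulate_matrix(surface_spec(noise_sigma = sigma,
                                        seed = 1000L + s))
    mat <- normalize_matrix(sim$records)
    excess_bliss(mat)$grid
  }))
  se <- sd(per_well) / sqrt(length(per_well))
  expect_lt(abs(mean(per_well)), 3 * se)
})

test_that("interaction classification uses the closed additive interval", {
  expect_equal(classify_interaction(-20), "additive")
  expect_equal(classify_interaction(20), "additive")
  expect_equal(classify_interaction(-20.001), "synergistic")
  expect_equal(classify_interaction(20.001), "antagonistic")
  expect_equal(classify_interaction(96.12), "antagonistic")
  expect_error(classify_interaction(0, thresholds = c(5, -5)),
               class = "validation_error")
  expect_error(classify_interaction(NaN), class = "validation_error")
})

test_that("both scores are anti-monotone in combination viability", {
  sim <- simulate_matrix(surface_spec(noise_sigma = 0, seed = 21L))
  m <- sim$truth_matrix
  h0 <- excess_hsa(m)$sum; b0 <- excess_bliss(m)$sum
  set.seed(33)
  for (k in 1:15) {
    m2 <- m
    i <- sample(2:6, 1); j <- sample(2:6, 1)
    m2$viability[i, j] <- m2$viability[i, j] - runif(1, 0, 20)
    expect_lt(excess_hsa(m2)$sum, h0 + 1e-12)
    expect_lt(excess_bliss(m2)$sum, b0 + 1e-12)
  }
})

test_that("scores are invariant under consistent dose-grid relabeling", {
  sim <- suppressWarnings(simulate_matrix(
    surface_spec(bliss_offset = 0.1, noise_sigma = 0, seed = 22L)))
  m <- sim$truth_matrix
  # transpose the checkerboard (swap drugs a and b)
  mt <- dose_matrix(m$compound_b, m$compound_a, m$doses_b, m$doses_a,
                    t(m$viability))
  expect_equal(excess_hsa(mt)$sum, excess_hsa(m)$sum, tolerance = 1e-12)
  expect_equal(excess_bliss(mt)$sum, excess_bliss(m)$sum, tolerance = 1e-12)
})

test_that("compound ranking matches a brute-force oracle", {
  scores <- data.frame(
    compound = rep(c("axitinib-like", "buparlisib-like", "cisplatin-like"),
                   each = 2),
    cell_line = rep(c("CL1", "CL2"), 3),
    excess_hsa_sum = c(-40, -60, -200, -100, 25, 35))
  ann <- data.frame(compound = c("axitinib-like", "buparlisib-like",
                                 "cisplatin-like"),
                    moa_class = c("VEGFR", "PI3K", "platinum"))
  rk <- rank_compounds(scores, ann)
  # brute force: means are -50, -150, 30 -> order buparlisib, axitinib, cisplatin
  expect_equal(rk$compound,
               c("buparlisib-like", "axitinib-like", "cisplatin-like"))
  expect_equal(rk$average_excess_hsa, c(-150, -50, 30))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$interaction_class,
               c("synergistic", "synergistic", "antagonistic"))
  expect_equal(rk$moa_class, c("PI3K", "VEGFR", "platinum"))

  # single cell line: ranking equals per-cell-line score order
  one <- scores[scores$cell_line == "CL1", ]
  rk1 <- rank_compounds(one, ann)
  expect_equal(rk1$average_excess_hsa, sort(one$excess_hsa_sum))

  # ties break lexicographically by compound name
  tie <- data.frame(compound = c("zeta", "alpha"), cell_line = "CL1",
                    excess_hsa_sum = c(-30, -30))
  expect_equal(rank_compounds(tie)$compound, c("alpha", "zeta"))
})

test_that("failed-QC cell lines are dropped from averages, not zero-filled", {
  scores <- data.frame(
    compound = rep("drugX", 3), cell_line = c("CL1", "CL2", "CL3"),
    excess_hsa_sum = c(-100, -50, 999), qc_passed = c(TRUE, TRUE, FALSE))
  rk <- rank_compounds(scores)
  expect_equal(rk$average_excess_hsa, -75)
  expect_equal(rk$n_cell_lines, 2L)
})

test_that("unannotated compounds are labelled and warned about", {
  scores <- data.frame(compound = c("known", "mystery"), cell_line = "CL1",
                       excess_hsa_sum = c(-30, -10))
  ann <- data.frame(compound = "known", moa_class = "PI3K")
  expect_warning(rk <- rank_compounds(scores, ann),
                 class = "missing_annotation_warning")
  expect_equal(rk$moa_class[rk$compound == "mystery"], "unannotated")
})

test_that("class averages match hand-computed means", {
  rk <- data.frame(
    compound = c("a", "b", "c", "d"),
    moa_class = c("PI3K", "PI3K", "MEK", "taxane"),
    average_excess_hsa = c(-200, -100, -50, 80))
  ca <- class_average(rk)
  expect_equal(ca$mean_excess_hsa[ca$moa_class == "PI3K"], -150)
  expect_equal(ca$mean_excess_hsa[ca$moa_class == "MEK"], -50)
  expect_equal(ca$mean_excess_hsa[ca$moa_class == "taxane"], 80)
  expect_equal(ca$moa_class[1], "PI3K")  # most synergistic first
  # one compound per class -> mean equals that compound's score
  expect_equal(ca$mean_excess_hsa[ca$moa_class == "taxane"],
               rk$average_excess_hsa[rk$compound == "d"])
})
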