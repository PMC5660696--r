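small_geo <- list(raster = 96, field_size_um = 9.375, n_planes = 4)

test_that("zero yields give an all-zero stack; same seed gives identical output", {
  sc0 <- do.call(mat_scenario, c(
    list(n_cells = 3, yield_C = 0, yield_CN = 0, yield_S = 0,
      background_fraction = 0, seed = 4
    ),
    small_geo
  ))
  expect_true(all(simulate_stack(sc0)$stack$counts == 0L))

  sc <- do.call(mat_scenario, c(list(n_cells = 4, r_C = 0.2, seed = 12), small_geo))
  s1 <- simulate_stack(sc)
  s2 <- simulate_stack(sc)
  expect_identical(s1$stack$counts, s2$stack$counts)
  expect_equal(s1$truth, s2$truth)
})

test_that("per-cell empirical atom fractions match the truth within binomial error", {
  # scaled-down law-of-large-numbers check: 2 fields x 60 cells, high yields
  for (seed in c(51, 52)) {
    sim <- simulate_stack(mat_scenario(
      n_cells = 60, raster = 256, field_size_um = 25, n_planes = 10,
      yield_C = 200, r_C = r_active_inactive(0.5, 0.3), seed = seed,
      globule_rate = 0
    ))
    truth <- sim$truth
    acc <- accumulate_planes(sim$stack)
    # read counts off the true pixel sets (generator geometry, no segmentation)
    rows <- matrix(rep(1:256, 256), 256, 256)
    cols <- matrix(rep(1:256, each = 256), 256, 256)
    for (k in seq_len(nrow(truth))) {
      inside <- (rows - truth$row[k])^2 + (cols - truth$col[k])^2 <=
        truth$radius_px[k]^2
      n13 <- sum(acc[["13C"]][inside])
      n12 <- sum(acc[["12C"]][inside])
      a_hat <- n13 / (n13 + n12)
      a <- truth$atom_fraction_C[k]
      tol <- 4 * sqrt(a * (1 - a) / (n13 + n12))
      expect_lt(abs(a_hat - a), tol)
    }
  }
})

test_that("expected carbon counts are conserved across the isotopologue split", {
  sc <- do.call(mat_scenario, c(
    list(n_cells = 5, r_C = 0.4, yield_C = 100, seed = 8, globule_rate = 0),
    small_geo
  ))
  sim <- simulate_stack(sc)
  acc <- accumulate_planes(sim$stack)
  # pixels inside cells: total C = yield_C per pixel-plane in expectation
  rows <- matrix(rep(1:96, 96), 96, 96)
  cols <- matrix(rep(1:96, each = 96), 96, 96)
  inside <- Reduce(`|`, lapply(seq_len(nrow(sim$truth)), function(k) {
    (rows - sim$truth$row[k])^2 + (cols - sim$truth$col[k])^2 <=
      sim$truth$radius_px[k]^2
  }))
  tot <- sum(acc[["12C"]][inside] + acc[["13C"]][inside])
  expected <- sum(inside) * sc$n_planes * sc$yield_C
  expect_lt(abs(tot - expected) / expected, 4 / sqrt(expected)) # Poisson CLT
})

test_that("infeasible packings error instead of looping forever", {
  sc <- do.call(mat_scenario, c(list(n_cells = 500), small_geo))
  expect_error(simulate_stack(sc), "infeasible packing")
})

test_that("sulfur globules appear as count holes inside cells", {
  sc <- do.call(mat_scenario, c(
    list(n_cells = 4, globule_rate = 3, globule_radius_um = 0.25, seed = 19),
    small_geo
  ))
  sim <- simulate_stack(sc)
  acc <- accumulate_planes(sim$stack)
  rows <- matrix(rep(1:96, 96), 96, 96)
  cols <- matrix(rep(1:96, each = 96), 96, 96)
  inside <- Reduce(`|`, lapply(seq_len(nrow(sim$truth)), function(k) {
    (rows - sim$truth$row[k])^2 + (cols - sim$truth$col[k])^2 <=
      sim$truth$radius_px[k]^2
  }))
  # with rate 3 per cell some in-cell pixels must be dead (zero CN counts)
  expect_gt(sum(acc[["12C14N"]][inside] == 0), 0)
})

test_that("FAME generator recovers exactly in the noise-free case and is seeded", {
  sc0 <- fame_scenario(
    panel = c("C16:0", "C18:1n-7"), noise_sd = 0, n_replicates = 2, seed = 1
  )
  tab <- simulate_fame_table(sc0)
  rec <- correct_fame(tab)
  expect_equal(rec$delta_fa, tab$truth_delta_fa, tolerance = 1e-10)
  expect_equal(rec$delta_fa, rep(-28, nrow(rec)), tolerance = 1e-10)

  sc <- fame_scenario(seed = 77)
  expect_equal(simulate_fame_table(sc), simulate_fame_table(sc))
})

test_that("mean recovered effect converges to the scenario truth", {
  shift <- 300
  effs <- numeric(60)
  for (i in seq_along(effs)) {
    sc <- fame_scenario(
      panel = "C16:0",
      effects = tibble::tibble(name = "C16:0", treatment = "AceL", shift = shift),
      treatments = c("control", "AceL"),
      noise_sd = 20, n_replicates = 3, seed = 1000 + i
    )
    rec <- correct_fame(simulate_fame_table(sc))
    means <- tapply(rec$delta_fa, rec$treatment, mean)
    effs[i] <- means[["AceL"]] - means[["control"]]
  }
  se <- 20 * sqrt(2 / 3) / sqrt(length(effs))
  expect_lt(abs(mean(effs) - shift), 2 * se)
})

test_that("the experiment preset encodes the seven-treatment design", {
  pre <- sip_experiment_preset(n_cells = 5, n_replicates = 3, seed = 2)
  expect_length(pre$scenarios, 21)
  expect_equal(
    sort(unique(vapply(pre$scenarios, function(s) s$treatment, character(1)))),
    sort(c("control", "AceL", "AceD", "PyrL", "PyrD", "CO3L", "CO3D"))
  )
  # control cells are strictly unlabelled
  ctrl <- Filter(function(s) s$treatment == "control", pre$scenarios)
  expect_length(ctrl, 3)
  for (s in ctrl) {
    expect_true(all(draw_r0 <- simulate_stack(s)$truth$r_C == 0))
    expect_true(all(simulate_stack(s)$truth$r_N == 0))
  }

  # preset anchors agree with the two-pool mass balance within 0.6 atom%
  natC <- natural_atom_percent("C")
  mixed <- c(
    acetate = mix_pools(pool_spec(500, 99), pool_spec(1000, natC)),
    pyruvate = mix_pools(pool_spec(500, 99), pool_spec(70, natC)),
    bicarbonate = mix_pools(pool_spec(500, 99), pool_spec(1300, natC))
  )
  des <- pre$design
  for (sub in names(mixed)) {
    stored <- unique(des$R_final_C[which(des$substrate == sub)])
    expect_lt(abs(stored - mixed[[sub]]), 0.6)
  }
  mixed_n <- mix_pools(pool_spec(100, 98), pool_spec(30.8, natural_atom_percent("N")))
  expect_lt(abs(74.5 - mixed_n), 0.6)

  # incubation configs carry the final concentrations and durations
  expect_equal(pre$incubations$AceL$concentration_M, 1.5e-3)
  expect_equal(pre$incubations$CO3D$duration_h, 5)
  expect_false(pre$incubations$CO3D$light)
  expect_equal(pre$ammonium$element, "N")
})

test_that("enrichment spec validation rejects bad shapes", {
  sc <- do.call(mat_scenario, c(list(n_cells = 3, r_C = c(0.1, 0.2)), small_geo))
  expect_error(simulate_stack(sc), "scalar, length n_cells, or a function")
  sc2 <- do.call(mat_scenario, c(list(n_cells = 3, r_C = 1.5), small_geo))
  expect_error(simulate_stack(sc2), "\\[0, 1\\]")
})
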