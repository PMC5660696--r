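# single synthetic cell on a small raster, known atom fraction
one_cell_stack <- function(atom_fraction_C = 0.05, yield = 80, planes = 10,
                           raster = 48, seed = 1) {
  set.seed(seed)
  lam13 <- yield * atom_fraction_C
  lam12 <- yield * (1 - atom_fraction_C)
  inside <- disc_field(raster, raster / 2, raster / 2, 9, value = 1L) > 0
  mk <- function(lam) {
    a <- array(0L, dim = c(raster, raster, planes))
    for (p in seq_len(planes)) {
      m <- matrix(0L, raster, raster)
      m[inside] <- rpois(sum(inside), lam)
      a[, , p] <- m
    }
    a
  }
  chans <- list(
    "12C" = mk(lam12), "13C" = mk(lam13),
    "12C14N" = mk(yield), "12C15N" = mk(yield * 0.004),
    "32S" = mk(0.5)
  )
  list(
    stack = ion_count_stack(chans, field_size_um = 48 * 25 / 256),
    mask = import_roi_mask(disc_field(raster, raster / 2, raster / 2, 9,
      value = 1L
    ))
  )
}

test_that("measured atom percent recovers the generator truth within counting error", {
  oc <- one_cell_stack(atom_fraction_C = 0.05, seed = 42)
  m <- measure_rois(oc$stack, oc$mask)
  expect_equal(nrow(m), 1)
  sd_ap <- 100 * m$err_R_C / (1 + m$R_C)^2 # delta-method on 100 R/(1+R)
  expect_lt(abs(m$atom_pc_C - 5), 3 * sd_ap)
})

test_that("ratios are ratio-of-sums, not mean-of-ratios", {
  # two-pixel ROI with very different totals: ratio-of-sums weights by counts
  chans <- lapply(ion_channels, function(ch) array(0L, dim = c(2, 2, 1)))
  names(chans) <- ion_channels
  chans[["12C"]][1, 1, 1] <- 1000L; chans[["13C"]][1, 1, 1] <- 10L
  chans[["12C"]][1, 2, 1] <- 10L; chans[["13C"]][1, 2, 1] <- 10L
  chans[["12C14N"]][1, 1:2, 1] <- 100L
  lab <- matrix(0L, 2, 2); lab[1, 1:2] <- 1L
  m <- measure_rois(ion_count_stack(chans), import_roi_mask(lab))
  expect_equal(m$R_C, 20 / 1010) # pooled; mean-of-ratios would give ~0.505
})

test_that("zero-count ROIs are flagged invalid with a warning", {
  chans <- lapply(ion_channels, function(ch) array(0L, dim = c(8, 8, 1)))
  names(chans) <- ion_channels
  chans[["12C"]][1:2, 1:2, 1] <- 50L
  chans[["12C14N"]][1:2, 1:2, 1] <- 50L
  lab <- matrix(0L, 8, 8)
  lab[1:2, 1:2] <- 1L # counts present
  lab[5:6, 5:6] <- 2L # all-zero pixels
  expect_warning(
    m <- measure_rois(ion_count_stack(chans), import_roi_mask(lab)),
    "invalid"
  )
  expect_equal(m$valid, c(TRUE, FALSE))
})

test_that("doubling all counts preserves ratios and shrinks error by sqrt(2)", {
  oc <- one_cell_stack(seed = 5)
  m1 <- measure_rois(oc$stack, oc$mask)
  doubled <- ion_count_stack(oc$stack$counts * 2L,
    field_size_um = oc$stack$field_size_um
  )
  m2 <- measure_rois(doubled, oc$mask)
  expect_equal(m2$R_C, m1$R_C)
  expect_equal(m2$R_N, m1$R_N)
  expect_equal(m2$err_R_C / m2$R_C, (m1$err_R_C / m1$R_C) / sqrt(2))
})

test_that("measurement is invariant to plane order and ROI label order", {
  sim <- simulate_stack(mat_scenario(
    n_cells = 4, raster = 96, field_size_um = 9.375, n_planes = 4,
    r_C = 0.2, r_N = 0.1, seed = 31
  ))
  mask <- segment_sim(sim)
  m <- measure_rois(sim$stack, mask)

  perm <- c(3, 1, 4, 2)
  shuffled <- ion_count_stack(sim$stack$counts[, , perm, , drop = FALSE],
    field_size_um = sim$stack$field_size_um
  )
  m_shuf <- measure_rois(shuffled, mask)
  expect_equal(m_shuf, m)

  k <- mask$n_rois
  relab <- mask$label_image
  relab[relab > 0] <- (k:1)[relab[relab > 0]] # reverse label order
  m_rev <- measure_rois(sim$stack, import_roi_mask(relab))
  expect_equal(
    dplyr::arrange(dplyr::select(m_rev, -roi_id), count_12C),
    dplyr::arrange(dplyr::select(m, -roi_id), count_12C)
  )
})

test_that("control-referenced deltas are zero at the control composition", {
  oc <- one_cell_stack(seed = 9)
  m <- measure_rois(oc$stack, oc$mask)
  expect_true(all(is.na(m$delta_C_control)))
  m2 <- measure_rois(oc$stack, oc$mask,
    control_ratios = list(C = m$R_C[1], N = m$R_N[1])
  )
  expect_equal(m2$delta_C_control, 0)
  expect_equal(m2$delta_N_control, 0)
})

test_that("mismatched mask and stack dimensions error", {
  oc <- one_cell_stack()
  small <- import_roi_mask(matrix(0L, 8, 8))
  expect_error(measure_rois(oc$stack, small), "dimensions differ")
})

test_that("ratio-of-sums is unbiased on homogeneous cells (Monte Carlo)", {
  # 500 replicate single-cell simulations at >= 1e4 accumulated rare counts
  set.seed(77)
  a <- 0.05
  n_pix <- 250 # pixels x planes pooled
  lam_tot <- 1000 # rare expectation: 250 * 1000 * 0.05 = 1.25e4
  est <- replicate(500, {
    rare <- rpois(n_pix, lam_tot * a)
    abund <- rpois(n_pix, lam_tot * (1 - a))
    sum(rare) / (sum(rare) + sum(abund))
  })
  expect_lt(abs(mean(est) - a) / a, 0.005)
})
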