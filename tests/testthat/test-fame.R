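test_that("fatty-acid name parser handles the field's dialects", {
  fa <- parse_fa_name(c(
    "C18:1n-7", "C16:0", "9-10diMe C16", "C16:0-OH",
    "C15:0 iso", "anteiso C17:0", "cyC17:0", "C20:5n-3"
  ))
  expect_equal(fa$n_carbons, c(18, 16, 16, 16, 15, 17, 17, 20))
  expect_equal(fa$n_double_bonds, c(1, 0, 0, 0, 0, 0, 0, 5))
  expect_equal(fa$omega_position, c(7, NA, NA, NA, NA, NA, NA, 3))
  expect_equal(
    fa$modifier,
    c("none", "none", "cyclopropane", "hydroxy", "iso", "anteiso",
      "cyclopropane", "none")
  )
})

test_that("parser round-trips through the canonical formatter", {
  names <- c(
    "C18:1n-7", "C16:0", "C14:0", "C16:1n-7", "C15:0 iso",
    "C17:0 anteiso", "C16:0-OH", "cyC17:0", "C18:3n-3"
  )
  fa <- parse_fa_name(names)
  again <- parse_fa_name(format_fa_name(fa))
  expect_equal(again[c("n_carbons", "n_double_bonds", "omega_position", "modifier")],
    fa[c("n_carbons", "n_double_bonds", "omega_position", "modifier")]
  )
})

test_that("parser rejects garbage, naming the offending token", {
  expect_error(parse_fa_name("banana"), "banana")
  expect_error(parse_fa_name("C16:0-XYZ"), "unrecognised token")
  expect_error(parse_fa_name(""), "nonempty")
  expect_error(parse_fa_name("C1:0"), ">= 2 carbons")
  expect_error(parse_fa_name("C16:0n-7"), "no double bond")
})

test_that("fa_fraction follows X/(X+1)", {
  expect_equal(fa_fraction(16), 16 / 17)
  expect_equal(fa_fraction(1), 1 / 2)
  expect_equal(fa_fraction(23), 23 / 24) # the C23:0 internal standard
  expect_error(fa_fraction(0), ">= 1")
})

test_that("methyl-group correction matches the hand-computed value", {
  # identity when the ester already matches the methanol
  expect_equal(correct_fame_delta(-37.9, 16 / 17, -37.9), -37.9)
  # hand oracle: (-30 - (1/17) * -37.9) * 17/16
  expect_equal(correct_fame_delta(-30, 16 / 17, -37.9),
    (-30 - (1 / 17) * (-37.9)) * 17 / 16,
    tolerance = 1e-12
  )
  expect_equal(correct_fame_delta(-30, 16 / 17, -37.9), -29.506,
    tolerance = 5e-5
  )
  # f -> 1 limit approaches the uncorrected value
  expect_equal(correct_fame_delta(-30, 1 - 1e-9, -37.9), -30, tolerance = 1e-6)
  expect_error(correct_fame_delta(-30, 1, -37.9), "strictly in")
})

test_that("correction and forward esterification are exact inverses", {
  set.seed(7)
  delta_fa <- runif(50, -60, 4000) # SIP-enriched values included
  f <- fa_fraction(sample(12:24, 50, replace = TRUE))
  for (m in c("delta", "atom_fraction")) {
    fame <- esterify_delta(delta_fa, f, -37.9, method = m)
    back <- correct_fame_delta(fame, f, -37.9, method = m)
    expect_equal(back, delta_fa, tolerance = 1e-9)
  }
})

test_that("correction magnitude shrinks as the chain lengthens", {
  x <- 8:24
  corr <- abs(correct_fame_delta(-30, fa_fraction(x), -37.9) - (-30))
  expect_true(all(diff(corr) < 0))
})

test_that("delta-scale and atom-fraction corrections agree at natural levels
          and diverge for strong enrichment", {
  near <- correct_fame_delta(-28, 16 / 17, -37.9, method = "atom_fraction")
  expect_equal(near, correct_fame_delta(-28, 16 / 17, -37.9), tolerance = 1e-4)
  hot_lin <- correct_fame_delta(3000, 16 / 17, -37.9)
  hot_exact <- correct_fame_delta(3000, 16 / 17, -37.9, method = "atom_fraction")
  expect_gt(abs(hot_lin - hot_exact), 0.1)
})

test_that("correct_fame augments a measured table and honours per-row methanol", {
  tab <- tibble::tibble(
    name = c("C16:0", "C18:1n-7"),
    treatment = "control", replicate = 1:2,
    delta_fame = c(-30, -28),
    delta_meoh = c(NA, -40)
  )
  out <- correct_fame(tab, delta_meoh = -37.9)
  expect_equal(out$f, fa_fraction(c(16, 18)))
  expect_equal(out$delta_fa[1], correct_fame_delta(-30, 16 / 17, -37.9))
  expect_equal(out$delta_fa[2], correct_fame_delta(-28, 18 / 19, -40))
  expect_error(correct_fame(tab[, 1:2]), "lacks column")
})

test_that("enrichment table flags the planted treatment effect and only it", {
  sc <- fame_scenario(
    panel = c("C18:1n-7", "C16:0", "C14:0"),
    effects = tibble::tibble(
      name = "C18:1n-7", treatment = "AceL", shift = 500
    ),
    treatments = c("control", "AceL", "PyrL"),
    noise_sd = 5, n_replicates = 6, seed = 11
  )
  tab <- enrichment_table(correct_fame(simulate_fame_table(sc)))
  hit <- dplyr::filter(tab, name == "C18:1n-7", treatment == "AceL")
  expect_true(hit$enriched)
  expect_gt(hit$diff_from_control, 400)
  others <- dplyr::filter(tab, !(name == "C18:1n-7" & treatment == "AceL"),
    treatment != "control"
  )
  expect_true(all(!others$enriched))
  expect_true(all(abs(others$diff_from_control) < 50))
})

test_that("enrichment table handles degenerate inputs as specified", {
  base <- tidyr::expand_grid(
    name = c("C16:0", "C18:1n-7"),
    treatment = c("control", "AceL"), replicate = 1:3
  ) |>
    dplyr::mutate(delta_fa = -28)
  # all treatments identical to control: zero differences, nothing enriched
  tab <- enrichment_table(base)
  expect_true(all(tab$diff_from_control == 0))
  expect_true(all(!tab$enriched))
  expect_true(all(nchar(tab$letters) >= 1))

  # missing control errors
  expect_error(
    enrichment_table(dplyr::filter(base, treatment != "control")),
    "control"
  )
  # a single-replicate cell is summarised but flagged untested
  single <- base[-(1:2), ]
  tab2 <- enrichment_table(single)
  expect_true(any(!tab2$tested))
  expect_true(all(is.na(tab2$p_value[!tab2$tested])))
})

test_that("treatment ranking by enrichment matches the generator's effects", {
  sc <- fame_scenario(
    panel = "C18:1n-7",
    effects = tibble::tibble(
      name = "C18:1n-7",
      treatment = c("AceL", "PyrL", "CO3L"),
      shift = c(900, 100, 400)
    ),
    treatments = c("control", "AceL", "PyrL", "CO3L"),
    noise_sd = 10, n_replicates = 3, seed = 5
  )
  tab <- enrichment_table(correct_fame(simulate_fame_table(sc))) |>
    dplyr::filter(treatment != "control") |>
    dplyr::arrange(dplyr::desc(diff_from_control))
  expect_equal(tab$treatment, c("AceL", "CO3L", "PyrL"))
})
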