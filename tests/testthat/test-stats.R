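test_that("identical groups give a null Van der Waerden result", {
  gs <- grouped_samples(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  out <- van_der_waerden(gs)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_gt(out$p_value, 0.99)

  # all values tied: degenerate, p = 1
  tied <- van_der_waerden(grouped_samples(rep(5, 6), rep(c("a", "b"), 3)))
  expect_true(tied$degenerate)
  expect_equal(tied$p_value, 1)
  expect_equal(tied$statistic, 0)
})

test_that("statistic matches the longhand normal-scores oracle", {
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(15)
    g <- sample(rep(c("a", "b", "c"), 5))
    out <- van_der_waerden(grouped_samples(v, g))
    expect_equal(out$statistic, oracle_vdw_statistic(v, g), tolerance = 1e-12)
    expect_equal(out$df, 2)
  }
})

test_that("chi-squared p agrees with the exhaustive permutation oracle at small n", {
  # two groups of 4: all choose(8,4)=70 assignments enumerated
  sets <- list(
    list(v = c(1.2, 0.3, 2.1, 0.8, 3.5, 4.1, 2.9, 5.0)),
    list(v = c(-1, 0, 1, 2, 8, 9, 10, 11)), # strong separation
    list(v = c(0.5, 0.6, 0.4, 0.7, 0.55, 0.65, 0.45, 0.35)) # none
  )
  g <- rep(c("a", "b"), each = 4)
  for (s in sets) {
    p_perm <- oracle_vdw_perm_p(s$v, g)
    p_chi <- van_der_waerden(grouped_samples(s$v, g))$p_value
    # chi-squared approximation slack at n=8, fixed a priori
    expect_lt(abs(p_chi - p_perm), 0.15)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(9)
  v <- rexp(24) + 0.1
  g <- sample(rep(c("a", "b", "c"), 8))
  base <- van_der_waerden(grouped_samples(v, g))
  for (f in list(log, sqrt, function(x) x^3, function(x) -1 / x)) {
    tr <- van_der_waerden(grouped_samples(f(v), g))
    expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
  }
})

test_that("letter display separates separated groups and only them", {
  set.seed(21)
  v <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 10))
  g <- rep(c("g1", "g2", "g3"), each = 20)
  ld <- pairwise_letters(grouped_samples(v, g))
  l <- setNames(ld$letters$letters, ld$letters$group)
  shared_12 <- length(intersect(
    strsplit(l[["g1"]], "")[[1]], strsplit(l[["g2"]], "")[[1]]
  )) > 0
  shared_13 <- length(intersect(
    strsplit(l[["g1"]], "")[[1]], strsplit(l[["g3"]], "")[[1]]
  )) > 0
  expect_true(shared_12)
  expect_false(shared_13)

  # identically drawn groups share a single letter
  set.seed(22)
  v0 <- rnorm(60)
  ld0 <- pairwise_letters(grouped_samples(v0, g))
  expect_true(all(ld0$letters$letters == ld0$letters$letters[1]))
})

test_that("letters are consistent with the adjusted p matrix by construction", {
  # exhaustive check on up to 5 groups of randomly separated data
  set.seed(30)
  for (rep_i in 1:6) {
    k <- sample(3:5, 1)
    mu <- sample(0:6, k, replace = TRUE)
    v <- unlist(lapply(mu, function(m) rnorm(12, m)))
    g <- rep(paste0("g", seq_len(k)), each = 12)
    ld <- pairwise_letters(grouped_samples(v, g), alpha = 0.05)
    lm_ <- setNames(strsplit(ld$letters$letters, ""), ld$letters$group)
    for (i in seq_len(nrow(ld$pairwise))) {
      pw <- ld$pairwise[i, ]
      share <- length(intersect(lm_[[pw$group1]], lm_[[pw$group2]])) > 0
      expect_equal(share, pw$p_adj >= 0.05)
    }
    # Holm never adjusts downwards
    expect_true(all(ld$pairwise$p_adj >= ld$pairwise$p_raw))
  }
})

test_that("letter assignment is stable under group input order", {
  set.seed(33)
  v <- c(rnorm(15, 0), rnorm(15, 4), rnorm(15, 8))
  g <- rep(c("x", "y", "z"), each = 15)
  ld1 <- pairwise_letters(grouped_samples(v, g))
  perm <- sample(length(v))
  ld2 <- pairwise_letters(grouped_samples(v[perm], g[perm]))
  # same partition structure up to letter renaming
  sig <- function(ld) {
    l <- setNames(ld$letters$letters, ld$letters$group)
    outer(names(l), names(l), Vectorize(function(a, b) {
      length(intersect(strsplit(l[[a]], "")[[1]], strsplit(l[[b]], "")[[1]])) > 0
    }))
  }
  expect_equal(sig(ld1), sig(ld2))
})

test_that("ANCOVA interaction F matches the normal-equations oracle", {
  # 6 points, two duplicated-structure groups
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 2.2, 3.9, 0.0, 2.1, 4.1)
  g <- rep(c("a", "b"), each = 3)
  got <- ancova_slopes(x = x, y = y, group = g)
  orc <- oracle_interaction_F(x, y, g)
  expect_equal(got$statistic, orc$F, tolerance = 1e-10)
  expect_equal(unname(got$df), c(orc$df1, orc$df2))
  expect_equal(got$p_value, orc$p, tolerance = 1e-10)
})

test_that("ANCOVA holds its size under equal slopes and detects unequal ones", {
  null_p <- numeric(200)
  power_p <- numeric(200)
  set.seed(101)
  for (i in 1:200) {
    x <- runif(100, 0, 2)
    g <- rep(c("a", "b"), each = 50)
    y_null <- 2.0 * x + rnorm(100, 0, 0.1)
    null_p[i] <- ancova_slopes(x = x, y = y_null, group = g)$p_value
    slope <- ifelse(g == "a", 2.0, 5.0)
    y_alt <- slope * x + rnorm(100, 0, 0.1)
    power_p[i] <- ancova_slopes(x = x, y = y_alt, group = g)$p_value
  }
  expect_gte(mean(null_p > 0.05), 0.90)
  expect_gte(mean(power_p < 0.001), 0.95)
})

test_that("ANCOVA validates the design", {
  expect_error(
    ancova_slopes(x = 1:6, y = rnorm(6), group = rep("a", 6)),
    ">= 2 groups"
  )
  expect_error(
    ancova_slopes(x = c(1, 2, 3, 1, 2), y = rnorm(5), group = c("a", "a", "a", "b", "b")),
    "< 3 points"
  )
  expect_error(
    ancova_slopes(x = c(1, 2, 3, 2, 2, 2), y = rnorm(6), group = rep(c("a", "b"), each = 3)),
    "zero covariate variance.*b"
  )
})

test_that("one-sample t and correlation match closed forms", {
  vals <- c(1, 2, 3, 4, 5)
  out <- one_sample_t(vals, mu = 2)
  # longhand: (mean - mu) / (sd / sqrt(n))
  expect_equal(out$statistic, (3 - 2) / (sd(vals) / sqrt(5)), tolerance = 1e-12)
  expect_equal(out$df, 4)

  same <- one_sample_t(rep(3, 4), mu = 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(cn_correlation(x, x)$estimate, 1)
  expect_true(cn_correlation(x, rep(2, 6))$degenerate)
})

test_that("tidy and glance return one-row broom-style summaries", {
  gs <- grouped_samples(c(rnorm(10), rnorm(10, 3)), rep(c("a", "b"), each = 10))
  td <- tidy(van_der_waerden(gs))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "p_value", "df1", "n") %in% names(td)))
  expect_equal(glance(van_der_waerden(gs)), td)
})
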