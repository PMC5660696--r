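#' Grouped samples container
#'
#' Pairs a numeric response with a categorical group label, the input shape
#' for the k-sample tests. Accepts vectors or a data frame plus column names.
#'
#' @param values Numeric vector, or a data frame.
#' @param group Group label per value, or (when `values` is a data frame) the
#'   names of the value and group columns via `value_col`/`group_col`.
#' @param value_col,group_col Column names used when `values` is a data frame.
#' @return A tibble of class `grouped_samples` with columns `value`, `group`.
#' @export
grouped_samples <- function(values, group = NULL,
                            value_col = "value", group_col = "group") {
  if (is.data.frame(values)) {
    df <- tibble::tibble(
      value = as.numeric(values[[value_col]]),
      group = as.character(values[[group_col]])
    )
  } else {
    stopifnot(length(values) == length(group))
    df <- tibble::tibble(value = as.numeric(values), group = as.character(group))
  }
  df <- df[stats::complete.cases(df), ]
  if (any(table(df$group) == 0) || length(unique(df$group)) < 1) {
    stop("every group must be nonempty", call. = FALSE)
  }
  structure(df, class = c("grouped_samples", class(tibble::tibble())))
}

# Normal scores: ranks (mid-ranks for ties) mapped through the standard
# normal quantile function, A_ij = qnorm(R_ij / (N + 1)).
normal_scores <- function(x) {
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

vdw_statistic <- function(value, group) {
  n_tot <- length(value)
  a <- normal_scores(value)
  s2 <- sum(a^2) / (n_tot - 1)
  if (s2 == 0) return(c(statistic = 0, df = length(unique(group)) - 1))
  means <- tapply(a, group, mean)
  sizes <- tapply(a, group, length)
  c(
    statistic = sum(sizes * means^2) / s2,
    df = length(means) - 1
  )
}

#' Van der Waerden normal-scores k-sample test
#'
#' Rank-based k-sample test for a location difference: the pooled ranks
#' (mid-ranks for ties) are converted to quantiles of the standard normal
#' distribution, \eqn{A_{ij} = \Phi^{-1}(R_{ij}/(N+1))}, and the statistic
#' \deqn{T = \sum_j n_j \bar A_j^2 / s^2, \qquad s^2 = \sum_{ij} A_{ij}^2/(N-1)}
#' is referred to a chi-squared distribution with `k - 1` degrees of freedom.
#' Being rank-based, the test is invariant under strictly monotone transforms
#' of the data and needs no normality or variance-homogeneity assumption.
#'
#' @param samples A [grouped_samples()] object (or data frame with `value`
#'   and `group` columns).
#' @return A list of class `sip_test` with `statistic`, `df`, `p_value`,
#'   `method`, `n`, `group_summary` (per-group n and mean normal score) and
#'   `degenerate` (TRUE when all values are tied).
#' @examples
#' gs <- grouped_samples(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
#' van_der_waerden(gs)$p_value
#' @export
van_der_waerden <- function(samples) {
  samples <- as_grouped(samples)
  k <- length(unique(samples$group))
  n_tot <- nrow(samples)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (n_tot < 3) stop("need N >= 3 observations", call. = FALSE)

  degenerate <- length(unique(samples$value)) == 1
  st <- vdw_statistic(samples$value, samples$group)
  p <- if (degenerate) 1 else stats::pchisq(st[["statistic"]], st[["df"]], lower.tail = FALSE)

  a <- normal_scores(samples$value)
  gsum <- tibble::tibble(
    group = names(tapply(a, samples$group, mean)),
    n = as.integer(tapply(a, samples$group, length)),
    mean_score = as.numeric(tapply(a, samples$group, mean))
  )
  structure(
    list(
      statistic = unname(st[["statistic"]]), df = unname(st[["df"]]),
      p_value = p, method = "Van der Waerden normal-scores test",
      n = n_tot, group_summary = gsum, degenerate = degenerate
    ),
    class = "sip_test"
  )
}

as_grouped <- function(x) {
  if (inherits(x, "grouped_samples")) return(x)
  if (is.data.frame(x) && all(c("value", "group") %in% names(x))) {
    return(grouped_samples(x$value, x$group))
  }
  stop("expected a grouped_samples object or a data frame with value/group",
    call. = FALSE
  )
}

#' Pairwise Van der Waerden tests with a compact letter display
#'
#' Runs [van_der_waerden()] on every pair of groups, adjusts the p values for
#' multiplicity (Holm by default) and assigns letters by the insert-absorb
#' compact-letter-display algorithm: two groups share a letter if and only if
#' their adjusted pairwise p value is `>= alpha` (i.e. they are not
#' significantly different) — the convention used above boxplots in the
#' ecological literature.
#'
#' @inheritParams van_der_waerden
#' @param alpha Significance level.
#' @param correction Method for [stats::p.adjust()]; default `"holm"`.
#' @return A list of class `letter_display` with `letters` (tibble: `group`,
#'   `letters`), `pairwise` (tibble of raw and adjusted p per pair), `alpha`
#'   and `correction`.
#' @export
pairwise_letters <- function(samples, alpha = 0.05, correction = "holm") {
  samples <- as_grouped(samples)
  groups <- sort(unique(samples$group))
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)

  pairs <- utils::combn(groups, 2)
  raw_p <- apply(pairs, 2, function(pr) {
    sub <- samples[samples$group %in% pr, ]
    van_der_waerden(sub)$p_value
  })
  adj_p <- stats::p.adjust(raw_p, method = correction)
  pw <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_raw = raw_p, p_adj = adj_p
  )

  # different[i, j] == TRUE means groups i and j must NOT share a letter
  different <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(ncol(pairs))) {
    if (adj_p[i] < alpha) {
      different[pairs[1, i], pairs[2, i]] <- TRUE
      different[pairs[2, i], pairs[1, i]] <- TRUE
    }
  }
  letters_map <- cld_insert_absorb(different)
  structure(
    list(
      letters = tibble::tibble(group = groups, letters = letters_map),
      pairwise = pw, alpha = alpha, correction = correction
    ),
    class = "letter_display"
  )
}

# Insert-absorb algorithm: start with one column (letter) containing all
# groups; for each significantly-different pair found in a shared column,
# duplicate the column into two, dropping one member from each; absorb
# columns that are subsets of others; letter groups by column membership.
cld_insert_absorb <- function(different) {
  groups <- rownames(different)
  k <- length(groups)
  cols <- list(rep(TRUE, k)) # logical membership vectors

  repeat {
    violation <- NULL
    for (ci in seq_along(cols)) {
      members <- which(cols[[ci]])
      if (length(members) < 2) next
      prs <- utils::combn(members, 2)
      bad <- which(different[cbind(prs[1, ], prs[2, ])])
      if (length(bad) > 0) {
        violation <- list(col = ci, i = prs[1, bad[1]], j = prs[2, bad[1]])
        break
      }
    }
    if (is.null(violation)) break
    old <- cols[[violation$col]]
    c1 <- old; c1[violation$i] <- FALSE
    c2 <- old; c2[violation$j] <- FALSE
    cols[[violation$col]] <- c1
    cols[[length(cols) + 1]] <- c2
    # absorb: drop any column whose membership is a subset of another's
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] | !cols[[b]]) && !identical(cols[[a]], cols[[b]])) {
          keep[b] <- FALSE # b subset of a
        }
      }
    }
    # deduplicate identical columns
    sig <- vapply(cols, paste, character(1), collapse = "")
    keep <- keep & !duplicated(sig)
    cols <- cols[keep]
  }
  lab <- letters[seq_along(cols)]
  vapply(seq_len(k), function(g) {
    paste0(lab[vapply(cols, function(cc) cc[g], logical(1))], collapse = "")
  }, character(1))
}

#' ANCOVA slope-homogeneity test
#'
#' Tests whether regression slopes of a response on a covariate are equal
#' across groups, the standard check before interpreting a common C-N uptake
#' relationship across treatments. Fits the full-interaction linear model
#' `y ~ x * group` (with the covariate centred for conditioning) and returns
#' the F test of the `group:x` interaction — equality of slopes — with its
#' degree-of-freedom pair. With the interaction as the highest-order term
#' this is its Type-II test.
#'
#' @param data Optional data frame; when given, `x`, `y`, `group` are column
#'   names, otherwise vectors.
#' @param x,y Covariate and response (vectors or column names).
#' @param group Group labels (vector or column name).
#' @return A list of class `sip_test` with `statistic` (F), `df` (numerator,
#'   denominator), `p_value`, `method`, `slopes` (per-group fitted slope).
#' @export
ancova_slopes <- function(data = NULL, x = "x", y = "y", group = "group") {
  if (!is.null(data)) {
    xv <- data[[x]]; yv <- data[[y]]; gv <- as.character(data[[group]])
  } else {
    xv <- x; yv <- y; gv <- as.character(group)
  }
  ok <- stats::complete.cases(xv, yv, gv)
  xv <- xv[ok]; yv <- yv[ok]; gv <- gv[ok]
  tab <- table(gv)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 3)) {
    stop("group(s) with < 3 points: ",
      paste(names(tab)[tab < 3], collapse = ", "),
      call. = FALSE
    )
  }
  xvar <- tapply(xv, gv, stats::var)
  if (any(xvar == 0)) {
    stop("zero covariate variance in group(s): ",
      paste(names(xvar)[xvar == 0], collapse = ", "),
      call. = FALSE
    )
  }
  df <- data.frame(x = xv - mean(xv), y = yv, g = factor(gv))
  full <- stats::lm(y ~ x * g, data = df)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(which(is.na(stats::coef(full))))
    stop("rank-deficient design (", paste(bad, collapse = ", "), ")",
      call. = FALSE
    )
  }
  additive <- stats::lm(y ~ x + g, data = df)
  cmp <- stats::anova(additive, full)
  co <- stats::coef(full)
  base_slope <- co[["x"]]
  slope_by_g <- vapply(levels(df$g), function(lv) {
    term <- paste0("x:g", lv)
    base_slope + if (term %in% names(co)) co[[term]] else 0
  }, numeric(1))
  structure(
    list(
      statistic = cmp$F[2],
      df = c(df1 = cmp$Df[2], df2 = cmp$Res.Df[2]),
      p_value = cmp$`Pr(>F)`[2],
      method = "ANCOVA slope-homogeneity (group x covariate interaction) F test",
      n = nrow(df),
      slopes = tibble::tibble(group = levels(df$g), slope = unname(slope_by_g))
    ),
    class = "sip_test"
  )
}

#' One-sample t test and C-N correlation
#'
#' Thin, tibble-returning wrappers over [stats::t.test()] and
#' [stats::cor.test()] used for the control-comparison and C-N coupling
#' checks: `one_sample_t()` tests whether values differ from a reference mean
#' `mu`; `cn_correlation()` reports the Pearson correlation between carbon
#' and nitrogen isotope ratios with its t-based p value. Zero-variance input
#' is flagged degenerate (statistic 0/`NA`, p 1) instead of erroring.
#'
#' @param values Numeric vector (n >= 2).
#' @param mu Reference mean.
#' @return A list of class `sip_test`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(structure(
      list(
        statistic = 0, df = length(values) - 1,
        p_value = 1, method = "one-sample t test",
        n = length(values), estimate = mean(values), degenerate = TRUE
      ),
      class = "sip_test"
    ))
  }
  tt <- stats::t.test(values, mu = mu)
  structure(
    list(
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, method = "one-sample t test",
      n = length(values), estimate = unname(tt$estimate), degenerate = FALSE
    ),
    class = "sip_test"
  )
}

#' @rdname one_sample_t
#' @param x,y Paired numeric vectors (e.g. per-cell carbon and nitrogen
#'   isotope ratios).
#' @export
cn_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(
      list(
        statistic = NA_real_, df = length(x) - 2, p_value = 1,
        estimate = NA_real_, method = "Pearson correlation",
        n = length(x), degenerate = TRUE
      ),
      class = "sip_test"
    ))
  }
  ct <- stats::cor.test(x, y)
  structure(
    list(
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value, estimate = unname(ct$estimate),
      method = "Pearson correlation", n = length(x), degenerate = FALSE
    ),
    class = "sip_test"
  )
}

#' @export
print.sip_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", signif(x$statistic, 5),
    " df =", paste(x$df, collapse = ", "),
    " p =", format.pval(x$p_value, digits = 4), "\n"
  )
  invisible(x)
}

#' @export
print.letter_display <- function(x, ...) {
  cat("Compact letter display (alpha =", x$alpha, ",", x$correction,
    "correction)\n"
  )
  print(x$letters)
  invisible(x)
}

#' Tidy a matsip test result
#'
#' broom-style one-row summaries of `sip_test` objects.
#'
#' @param x A `sip_test` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.sip_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    df1 = x$df[1],
    df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
    p_value = x$p_value,
    estimate = if (!is.null(x$estimate)) x$estimate else NA_real_,
    n = x$n
  )
}

#' @rdname tidy.sip_test
#' @export
glance.sip_test <- function(x, ...) tidy.sip_test(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
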