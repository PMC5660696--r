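# Independent oracles and deterministic fixture builders. Everything here is
# written as straight-line textbook computation, deliberately sharing no code
# with the package internals it checks.

# Normal-scores k-sample statistic, computed longhand.
oracle_vdw_statistic <- function(values, group) {
  n <- length(values)
  rk <- rank(values, ties.method = "average")
  a <- qnorm(rk / (n + 1))
  s2 <- sum(a^2) / (n - 1)
  tot <- 0
  for (g in unique(group)) {
    ai <- a[group == g]
    tot <- tot + length(ai) * mean(ai)^2
  }
  tot / s2
}

# Exact permutation p value of the normal-scores statistic for two groups,
# by enumeration of every assignment of group-1 slots.
oracle_vdw_perm_p <- function(values, group) {
  groups <- unique(group)
  stopifnot(length(groups) == 2)
  n <- length(values)
  n1 <- sum(group == groups[1])
  obs <- oracle_vdw_statistic(values, group)
  combs <- combn(n, n1)
  stats <- apply(combs, 2, function(sel) {
    g <- rep(groups[2], n)
    g[sel] <- groups[1]
    oracle_vdw_statistic(values, g)
  })
  mean(stats >= obs - 1e-12)
}

# Least-squares F test of the slope-difference (interaction) term from the
# normal equations, no lm().
oracle_interaction_F <- function(x, y, group) {
  g <- as.integer(factor(group)) - 1L # 0/1 dummy, two groups only
  stopifnot(all(g %in% c(0L, 1L)))
  X_full <- cbind(1, x, g, x * g)
  X_add <- cbind(1, x, g)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss_add <- rss(X_add)
  rss_full <- rss(X_full)
  df2 <- length(y) - ncol(X_full)
  f <- (rss_add - rss_full) / 1 / (rss_full / df2)
  list(F = f, df1 = 1, df2 = df2, p = pf(f, 1, df2, lower.tail = FALSE))
}

# Noise-free disc field: constant counts inside each disc, zero outside.
# Pixel-centre containment, matching the generator's rendering rule.
disc_field <- function(raster, centers_row, centers_col, radius_px,
                       value = 1000L) {
  img <- matrix(0L, raster, raster)
  rows <- matrix(rep(seq_len(raster), raster), raster, raster)
  cols <- matrix(rep(seq_len(raster), each = raster), raster, raster)
  for (k in seq_along(centers_row)) {
    inside <- (rows - centers_row[k])^2 + (cols - centers_col[k])^2 <=
      radius_px[k]^2
    img[inside] <- value
  }
  img
}

# Add an axis-aligned rectangle (rod-shaped distractor) to an image.
add_rod <- function(img, row0, col0, height, width, value = 1000L) {
  img[row0:(row0 + height - 1), col0:(col0 + width - 1)] <- value
  img
}

# Wrap a single accumulated image as a 1-plane 5-channel stack where the
# given channel carries the image and the rest are zero.
image_as_stack <- function(img, channel = "12C14N", field_size_um = 25) {
  chans <- lapply(matsip::ion_channels, function(ch) {
    if (ch == channel) img else matrix(0L, nrow(img), ncol(img))
  })
  names(chans) <- matsip::ion_channels
  ion_count_stack(chans, field_size_um = field_size_um)
}

# Nearest-truth matching of measured ROI centroids to generator ground truth.
match_rois_to_truth <- function(mask, truth) {
  vapply(seq_len(mask$n_rois), function(i) {
    which.min((truth$row - mask$rois$row[i])^2 +
      (truth$col - mask$rois$col[i])^2)
  }, integer(1))
}

# Segment an accumulated simulated stack with package defaults.
segment_sim <- function(sim, ...) {
  segment_cells(
    accumulate_planes(sim$stack)[["12C14N"]],
    pixel_size_um = sim$stack$pixel_size_um, ...
  )
}
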