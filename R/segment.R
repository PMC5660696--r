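#' Otsu threshold of a count image
#'
#' Classic between-class-variance-maximising threshold on the image
#' histogram. Counts are binned (256 bins spanning the observed range) so the
#' method behaves on the high-dynamic-range accumulated CN images.
#'
#' @param img Numeric matrix of non-negative counts.
#' @param n_bins Histogram bins.
#' @return Scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.numeric(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# 4-connected component labelling of a logical matrix by stack-based flood
# fill. Returns an integer matrix with background 0 and components labelled
# 1..k in discovery (row-major) order.
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  idx_fg <- which(fg)
  for (start in idx_fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% nr + 1L
      nbrs <- c(
        if (r > 1L) cur - 1L,
        if (r < nr) cur + 1L,
        if (cur > nr) cur - nr,
        if (cur <= (nc - 1L) * nr) cur + nr
      )
      nbrs <- nbrs[fg[nbrs] & labels[nbrs] == 0L]
      if (length(nbrs) > 0) {
        labels[nbrs] <- lab
        stack <- c(stack, nbrs)
      }
    }
  }
  labels
}

# Per-component area, Manhattan boundary length and centroid. The digital
# (city-block) perimeter of a smooth shape overestimates the true perimeter
# by 4/pi on average, so the corrected perimeter is edge_count * pi/4 —
# exact in expectation for discs, which keeps circularity of round cells
# near 1.
component_props <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  k <- max(labels)
  if (k == 0) {
    return(tibble::tibble(
      label = integer(0), area = integer(0), perimeter = numeric(0),
      circularity = numeric(0), row = numeric(0), col = numeric(0)
    ))
  }
  idx <- which(labels > 0L)
  lab <- factor(labels[idx], levels = seq_len(k)) # absent labels -> area 0
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  area <- tabulate(labels[idx], k)

  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  ri <- r + 1L; ci <- cc + 1L
  edges <- (pad[cbind(ri - 1L, ci)] != labels[idx]) +
    (pad[cbind(ri + 1L, ci)] != labels[idx]) +
    (pad[cbind(ri, ci - 1L)] != labels[idx]) +
    (pad[cbind(ri, ci + 1L)] != labels[idx])
  edge_count <- as.numeric(tapply(edges, lab, sum))
  edge_count[is.na(edge_count)] <- 0
  perim <- edge_count * pi / 4
  circ <- ifelse(perim > 0, pmin(1, 4 * pi * area / perim^2), 0)

  tibble::tibble(
    label = seq_len(k),
    area = area,
    perimeter = perim,
    circularity = circ,
    row = as.numeric(tapply(r, lab, mean)),
    col = as.numeric(tapply(cc, lab, mean))
  )
}

# Binary closing (dilation then erosion) with an L1 ball of radius r,
# implemented via the distance transform; repairs boundary bites left by
# sulfur-globule holes at the cell edge.
binary_close <- function(fg, r) {
  if (r <= 0) return(fg)
  d_out <- distance_transform(!fg)
  dil <- fg | (d_out <= r & d_out > 0)
  d_in <- distance_transform(dil)
  dil & d_in > r
}

# Fill interior holes: background components not connected to the image
# border become foreground (sulfur globules emit no ions but belong to the
# cell's ROI).
fill_holes <- function(fg) {
  bg_lab <- label_components(!fg)
  border <- unique(c(
    bg_lab[1, ], bg_lab[nrow(bg_lab), ], bg_lab[, 1], bg_lab[, ncol(bg_lab)]
  ))
  border <- border[border > 0]
  fg | (bg_lab > 0 & !(bg_lab %in% border))
}

# Repair each labelled component independently (closing + hole fill inside a
# padded bounding box). Per-component repair cannot bridge distinct cells,
# unlike a whole-image closing. Overlap-free by first-come assignment.
repair_labels <- function(labels, closing_radius, fill_interior) {
  k <- max(labels)
  if (k == 0 || (closing_radius <= 0 && !fill_interior)) return(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(0L, nr, nc)
  pad <- closing_radius + 1L
  for (kk in seq_len(k)) {
    idx <- which(labels == kk)
    r <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    r0 <- max(1L, min(r) - pad); r1 <- min(nr, max(r) + pad)
    c0 <- max(1L, min(cc) - pad); c1 <- min(nc, max(cc) + pad)
    sub <- labels[r0:r1, c0:c1] == kk
    if (closing_radius > 0) sub <- binary_close(sub, closing_radius)
    if (fill_interior) sub <- fill_holes(sub)
    tgt <- out[r0:r1, c0:c1]
    tgt[sub & tgt == 0L] <- kk
    out[r0:r1, c0:c1] <- tgt
  }
  out
}

# Two-pass city-block (L1) distance transform to the background.
distance_transform <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  inf <- nr + nc + 2
  d <- matrix(0, nr, nc)
  d[fg] <- inf
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (d[i, j] > 0) {
        up <- if (i > 1) d[i - 1, j] else 0
        left <- if (j > 1) d[i, j - 1] else 0
        d[i, j] <- min(d[i, j], up + 1, left + 1)
      }
    }
  }
  for (j in rev(seq_len(nc))) {
    for (i in rev(seq_len(nr))) {
      if (d[i, j] > 0) {
        down <- if (i < nr) d[i + 1, j] else 0
        right <- if (j < nc) d[i, j + 1] else 0
        d[i, j] <- min(d[i, j], down + 1, right + 1)
      }
    }
  }
  d
}

# Marker-controlled flooding split of touching cells: seeds are local maxima
# of the distance transform (non-max suppression within ~one cell radius);
# remaining foreground pixels are flooded in order of decreasing distance,
# inheriting the label of an already-labelled 4-neighbour.
watershed_split <- function(fg, expected_radius_px) {
  d <- distance_transform(fg)
  nr <- nrow(fg); nc <- ncol(fg)
  win <- max(2L, as.integer(round(expected_radius_px * 0.7)))
  min_d <- max(2, expected_radius_px * 0.4)

  cand <- which(fg & d >= min_d)
  cand <- cand[order(-d[cand])]
  seeds <- integer(0)
  for (p in cand) {
    r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
    if (length(seeds) > 0) {
      sr <- (seeds - 1L) %% nr + 1L; sc <- (seeds - 1L) %/% nr + 1L
      if (any(abs(sr - r) <= win & abs(sc - cc) <= win)) next
    }
    seeds <- c(seeds, p)
  }
  if (length(seeds) == 0) return(label_components(fg))

  labels <- matrix(0L, nr, nc)
  labels[seeds] <- seq_along(seeds)
  todo <- which(fg & labels == 0L)
  todo <- todo[order(-d[todo])]
  pending <- todo
  repeat {
    progressed <- FALSE
    still <- integer(0)
    for (p in pending) {
      r <- (p - 1L) %% nr + 1L
      nbrs <- c(
        if (r > 1L) p - 1L,
        if (r < nr) p + 1L,
        if (p > nr) p - nr,
        if (p <= (nc - 1L) * nr) p + nr
      )
      nl <- labels[nbrs]
      nl <- nl[nl > 0L]
      if (length(nl) > 0) {
        labels[p] <- nl[1]
        progressed <- TRUE
      } else {
        still <- c(still, p)
      }
    }
    pending <- still
    if (length(pending) == 0 || !progressed) break
  }
  # isolated leftovers (disconnected from any seed) get fresh labels
  if (length(pending) > 0) {
    extra <- label_components(matrix(
      seq_len(nr * nc) %in% pending, nr, nc
    ))
    labels[pending] <- max(labels) + extra[pending]
  }
  labels
}

#' Segment coccoid cells from an accumulated CN image
#'
#' Detects cells on the plane-accumulated 12C14N- image — the channel with
#' the strongest, biomass-proportional signal — by (1) thresholding (Otsu by
#' default), (2) 4-connected component labelling, (3) filtering components by
#' area (bounds derived from the expected cell diameter +/- a tolerance) and
#' circularity (`4*pi*area/perimeter^2`), which rejects elongated, rod-shaped
#' or ragged objects, and (4) optionally splitting touching cells by
#' marker-controlled flooding of the distance transform. Surviving components
#' are relabelled contiguously in discovery order.
#'
#' @param cn_image Accumulated 12C14N- count matrix (from
#'   [accumulate_planes()]).
#' @param pixel_size_um Pixel edge length, micrometres.
#' @param expected_diameter_um Expected (mean) cell diameter; default 1.67.
#' @param diameter_tol Relative tolerance on the diameter used to derive the
#'   area bounds; default 0.5 (i.e. diameters within +/- 50%).
#' @param min_circularity Minimum circularity to keep a component;
#'   default 0.6.
#' @param threshold `"otsu"` or a fixed numeric count threshold.
#' @param closing_radius Radius (px) of the binary closing applied after
#'   thresholding; repairs outline bites left by sulfur-globule holes at the
#'   cell edge. 0 disables.
#' @param fill_interior Fill enclosed background holes (interior sulfur
#'   globules) so the ROI covers the whole cell.
#' @param split_touching Split merged components by a watershed-style
#'   flooding of the distance transform before filtering.
#' @return An object of class `roi_mask`: list with `label_image` (integer
#'   matrix, 0 = background), `rois` (tibble of per-ROI area, circularity,
#'   centroid), `params`, `provenance = "automatic"`. A blank image yields a
#'   valid mask with 0 ROIs.
#' @export
segment_cells <- function(cn_image,
                          pixel_size_um,
                          expected_diameter_um = 1.67,
                          diameter_tol = 0.5,
                          min_circularity = 0.6,
                          threshold = "otsu",
                          closing_radius = 2,
                          fill_interior = TRUE,
                          split_touching = FALSE) {
  stopifnot(is.matrix(cn_image), pixel_size_um > 0)
  if (any(cn_image < 0)) stop("cn_image must be non-negative", call. = FALSE)
  d_lo <- expected_diameter_um * (1 - diameter_tol)
  d_hi <- expected_diameter_um * (1 + diameter_tol)
  area_bounds_px <- pi / 4 * c(d_lo, d_hi)^2 / pixel_size_um^2
  if (area_bounds_px[1] > area_bounds_px[2]) {
    stop("degenerate area bounds (min > max); check diameter_tol", call. = FALSE)
  }

  thr <- if (identical(threshold, "otsu")) otsu_threshold(cn_image) else as.numeric(threshold)
  fg <- cn_image > thr
  if (!any(fg)) {
    return(new_roi_mask(matrix(0L, nrow(cn_image), ncol(cn_image)),
      params = list(
        threshold = thr, area_bounds_px = area_bounds_px,
        min_circularity = min_circularity, pixel_size_um = pixel_size_um
      )
    ))
  }

  labels <- if (split_touching) {
    watershed_split(fg, expected_radius_px = expected_diameter_um / 2 / pixel_size_um)
  } else {
    label_components(fg)
  }
  labels <- repair_labels(labels, closing_radius, fill_interior)
  props <- component_props(labels)
  keep <- props$label[
    props$area >= area_bounds_px[1] &
      props$area <= area_bounds_px[2] &
      props$circularity >= min_circularity
  ]
  relab <- integer(max(labels) + 1L) # +1 guard for max=0
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  sel <- labels > 0L
  out[sel] <- relab[labels[sel]]

  new_roi_mask(out, params = list(
    threshold = thr, area_bounds_px = area_bounds_px,
    min_circularity = min_circularity, pixel_size_um = pixel_size_um,
    split_touching = split_touching
  ))
}

new_roi_mask <- function(label_image, params = list(),
                         provenance = "automatic") {
  storage.mode(label_image) <- "integer"
  structure(
    list(
      label_image = label_image,
      rois = component_props(label_image),
      n_rois = max(label_image),
      params = params,
      provenance = provenance
    ),
    class = "roi_mask"
  )
}

#' Import a label image as an ROI mask
#'
#' Accepts manually drawn ROI label images (e.g. exported from vendor
#' software as an integer matrix, text format): 0 is background, each
#' positive integer one cell. Labels are compacted to 1..k.
#'
#' @param label_image Integer matrix, or path to a whitespace-separated text
#'   matrix.
#' @return A `roi_mask` with `provenance = "imported"`.
#' @export
import_roi_mask <- function(label_image) {
  if (is.character(label_image)) {
    label_image <- as.matrix(data.table::fread(label_image, header = FALSE))
    dimnames(label_image) <- NULL
  }
  if (any(label_image < 0) || any(label_image != round(label_image))) {
    stop("label image must contain non-negative integers", call. = FALSE)
  }
  old <- sort(unique(label_image[label_image > 0]))
  relab <- integer(max(c(0, old)) + 1L)
  relab[old] <- seq_along(old)
  out <- matrix(0L, nrow(label_image), ncol(label_image))
  sel <- label_image > 0
  out[sel] <- relab[label_image[sel]]
  new_roi_mask(out, provenance = "imported")
}

#' Write an ROI mask as a text label matrix
#'
#' @param mask A `roi_mask`.
#' @param path Output file.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  data.table::fwrite(data.table::as.data.table(mask$label_image), path,
    sep = " ", col.names = FALSE
  )
  invisible(path)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(
    "roi_mask (", x$provenance, "): ", x$n_rois, " ROI(s) on ",
    paste(dim(x$label_image), collapse = " x "), " px\n",
    sep = ""
  )
  invisible(x)
}
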