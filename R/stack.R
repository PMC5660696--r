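#' Ion channels recorded per analysis
#'
#' The five secondary-ion species recorded simultaneously: 12C-, 13C-,
#' 12C14N-, 12C15N- and 32S-. Carbon isotope ratios come from 13C-/12C-,
#' nitrogen ratios from 12C15N-/12C14N-; the 32S- channel is carried through
#' I/O but excluded from quantification (elemental sulfur is lost during
#' sample preparation and sulfur globules appear only as count "holes").
#'
#' @export
ion_channels <- c("12C", "13C", "12C14N", "12C15N", "32S")

#' Multi-channel ion-count stack
#'
#' Container for a NanoSIMS-style acquisition: integer secondary-ion counts
#' per (row, col, plane, channel), with the acquisition geometry as metadata.
#' Planes are successive rescans of the same field and are summed by
#' [accumulate_planes()] before segmentation and measurement.
#'
#' @param counts Integer array `[row, col, plane, channel]`, or a named list
#'   of per-channel `[row, col, plane]` arrays. Channel names must match
#'   [ion_channels].
#' @param field_size_um Physical field width (square field), micrometres.
#' @param dwell_ms Per-pixel counting time, milliseconds.
#' @return An object of class `ion_count_stack`: list with `counts` (4-d
#'   integer array, channel dimnames), `raster` (pixels per side),
#'   `n_planes`, `field_size_um`, `pixel_size_um`, `dwell_ms`.
#' @export
ion_count_stack <- function(counts, field_size_um = 25, dwell_ms = 1) {
  if (is.list(counts) && !is.array(counts)) {
    missing <- setdiff(ion_channels, names(counts))
    if (length(missing) > 0) {
      stop("missing channel(s): ", paste(missing, collapse = ", "),
        "; found: ", paste(names(counts), collapse = ", "),
        call. = FALSE
      )
    }
    dims <- dim(counts[[ion_channels[1]]])
    if (length(dims) == 2) dims <- c(dims, 1L)
    arr <- array(0L, dim = c(dims, length(ion_channels)),
      dimnames = list(NULL, NULL, NULL, ion_channels)
    )
    for (ch in ion_channels) {
      x <- counts[[ch]]
      if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
      if (!identical(dim(x), as.integer(dims))) {
        stop("channel ", ch, " has mismatched dimensions", call. = FALSE)
      }
      arr[, , , ch] <- x
    }
    counts <- arr
  }
  if (length(dim(counts)) != 4) {
    stop("counts must be a [row, col, plane, channel] array", call. = FALSE)
  }
  if (is.null(dimnames(counts)[[4]])) {
    if (dim(counts)[4] != length(ion_channels)) {
      stop("expected ", length(ion_channels), " channels", call. = FALSE)
    }
    dimnames(counts) <- c(vector("list", 3), list(ion_channels))
  }
  missing <- setdiff(ion_channels, dimnames(counts)[[4]])
  if (length(missing) > 0) {
    stop("missing channel(s): ", paste(missing, collapse = ", "),
      "; found: ", paste(dimnames(counts)[[4]], collapse = ", "),
      call. = FALSE
    )
  }
  counts <- counts[, , , ion_channels, drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("ion counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(
    list(
      counts = counts,
      raster = dim(counts)[1],
      n_planes = dim(counts)[3],
      field_size_um = field_size_um,
      pixel_size_um = field_size_um / dim(counts)[1],
      dwell_ms = dwell_ms
    ),
    class = "ion_count_stack"
  )
}

#' @export
print.ion_count_stack <- function(x, ...) {
  cat(
    "ion_count_stack:", paste(dim(x$counts)[1:2], collapse = " x "),
    "px,", x$n_planes, "plane(s),", dim(x$counts)[4], "channels,",
    x$field_size_um, "um field (", signif(x$pixel_size_um, 4), "um/px)\n"
  )
  tot <- apply(x$counts, 4, sum)
  cat("  total counts:", paste(names(tot), format(tot), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Write / read an ion-count stack as plain-text matrices
#'
#' Portable text format: one whitespace-separated integer matrix file per
#' channel (`channel_<name>.txt`, planes stacked vertically in plane order)
#' plus a `meta.json` sidecar with the acquisition geometry. The round trip
#' preserves every count exactly.
#'
#' @param stack An [ion_count_stack()].
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` returns an
#'   [ion_count_stack()].
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "ion_count_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in ion_channels) {
    mats <- lapply(seq_len(stack$n_planes), function(p) stack$counts[, , p, ch])
    stacked <- do.call(rbind, mats)
    data.table::fwrite(data.table::as.data.table(stacked),
      file.path(dir, channel_file(ch)),
      sep = " ", col.names = FALSE
    )
  }
  meta <- list(
    raster = stack$raster, n_planes = stack$n_planes,
    field_size_um = stack$field_size_um, dwell_ms = stack$dwell_ms,
    channels = ion_channels
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

channel_file <- function(ch) paste0("channel_", ch, ".txt")

#' @rdname write_stack
#' @param meta Optional named list overriding/substituting `meta.json`
#'   (fields `n_planes`, `field_size_um`, `dwell_ms`), for stacks delivered
#'   without a sidecar.
#' @export
read_stack <- function(dir, meta = NULL) {
  if (!dir.exists(dir)) stop("stack directory not found: ", dir, call. = FALSE)
  meta_path <- file.path(dir, "meta.json")
  file_meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  meta <- utils::modifyList(file_meta, as.list(meta))

  found <- list.files(dir, pattern = "^channel_.*\\.txt$")
  missing <- setdiff(vapply(ion_channels, channel_file, character(1)), found)
  if (length(missing) > 0) {
    stop("stack at ", dir, " is missing channel file(s): ",
      paste(missing, collapse = ", "), "; found: ",
      paste(found, collapse = ", "),
      call. = FALSE
    )
  }
  per_ch <- lapply(ion_channels, function(ch) {
    m <- as.matrix(data.table::fread(file.path(dir, channel_file(ch)),
      header = FALSE
    ))
    dimnames(m) <- NULL
    if (any(!is.finite(m)) || any(m != round(m)) || any(m < 0)) {
      stop("non-integer or negative data in ", channel_file(ch), call. = FALSE)
    }
    m
  })
  names(per_ch) <- ion_channels
  np <- meta$n_planes
  if (is.null(np)) np <- 1L
  rows_tot <- nrow(per_ch[[1]])
  if (rows_tot %% np != 0) {
    stop("channel file rows (", rows_tot, ") not divisible by n_planes (",
      np, ")",
      call. = FALSE
    )
  }
  nr <- rows_tot / np
  arrs <- lapply(per_ch, function(m) {
    a <- array(0L, dim = c(nr, ncol(m), np))
    for (p in seq_len(np)) a[, , p] <- m[((p - 1) * nr + 1):(p * nr), ]
    a
  })
  ion_count_stack(arrs,
    field_size_um = meta$field_size_um %||% 25,
    dwell_ms = meta$dwell_ms %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accumulate rescanned planes into per-channel images
#'
#' Pixel-wise integer sum of all planes per channel — the accumulated images
#' on which segmentation and ROI measurement operate.
#'
#' @param stack An [ion_count_stack()].
#' @return Named list of integer matrices, one per channel.
#' @export
accumulate_planes <- function(stack) {
  stopifnot(inherits(stack, "ion_count_stack"))
  out <- lapply(ion_channels, function(ch) {
    m <- rowSums(stack$counts[, , , ch, drop = FALSE], dims = 2)
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  })
  names(out) <- ion_channels
  out
}
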