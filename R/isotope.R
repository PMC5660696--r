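#' Isotope systems and reference standards
#'
#' Two isotope systems are predefined: carbon (\eqn{^{13}C/^{12}C} against
#' VPDB, reference ratio 0.0112372) and nitrogen (\eqn{^{15}N/^{14}N} against
#' atmospheric N2, reference ratio 0.0036765). All delta values in the package
#' are expressed against these standards unless a control-derived reference is
#' supplied explicitly.
#'
#' @param element `"C"` or `"N"` (case-insensitive; `"13C"`/`"15N"` also
#'   accepted).
#' @return A list of class `isotope_system` with fields `element`,
#'   `element_label` and `reference_ratio`.
#' @examples
#' isotope_system("C")$reference_ratio # 0.0112372 (VPDB)
#' natural_atom_percent("N")           # ~0.3663 atom%
#' @export
isotope_system <- function(element = c("C", "N")) {
  key <- toupper(gsub("[0-9]", "", as.character(element)[1]))
  sys <- switch(key,
    C = list(
      element = "C",
      element_label = "carbon-13/carbon-12",
      reference_ratio = 0.0112372 # VPDB
    ),
    N = list(
      element = "N",
      element_label = "nitrogen-15/nitrogen-14",
      reference_ratio = 0.0036765 # atmospheric N2
    ),
    stop("unknown isotope system: ", element, " (use \"C\" or \"N\")",
      call. = FALSE
    )
  )
  structure(sys, class = "isotope_system")
}

#' @rdname isotope_system
#' @export
natural_atom_percent <- function(element = c("C", "N")) {
  ratio_to_atom_percent(isotope_system(element)$reference_ratio)
}

#' Convert between isotope ratio, atom percent and delta notation
#'
#' Standard conversions of isotope geochemistry. A ratio `R` is the
#' rare/abundant isotope ratio (e.g. \eqn{^{13}C/^{12}C}); atom percent is
#' \eqn{100 R/(1+R)}; delta is the per-mil deviation from the reference ratio,
#' \eqn{\delta = (R/R_{std} - 1) \times 1000}. All functions are vectorised
#' and are exact inverses of their counterparts.
#'
#' @param R Rare/abundant isotope ratio(s), `>= 0`.
#' @param ap Atom percent value(s) in `[0, 100)`.
#' @param delta Delta value(s) in per mil, `> -1000`.
#' @param system An [isotope_system()], or `"C"`/`"N"`.
#' @return Numeric vector.
#' @examples
#' ratio_to_atom_percent(0.0112372) # 1.11123 atom% (natural carbon)
#' delta_to_ratio(-37.9, "C")       # ratio of the methanol reagent
#' @export
ratio_to_atom_percent <- function(R) {
  stopifnot(is.numeric(R))
  if (any(R < 0, na.rm = TRUE)) {
    stop("isotope ratio must be >= 0", call. = FALSE)
  }
  100 * R / (1 + R)
}

#' @rdname ratio_to_atom_percent
#' @export
atom_percent_to_ratio <- function(ap) {
  stopifnot(is.numeric(ap))
  if (any(ap < 0 | ap >= 100, na.rm = TRUE)) {
    stop("atom percent must lie in [0, 100)", call. = FALSE)
  }
  ap / (100 - ap)
}

#' @rdname ratio_to_atom_percent
#' @export
ratio_to_delta <- function(R, system = "C") {
  if (!inherits(system, "isotope_system")) system <- isotope_system(system)
  if (any(R < 0, na.rm = TRUE)) {
    stop("isotope ratio must be >= 0", call. = FALSE)
  }
  (R / system$reference_ratio - 1) * 1000
}

#' @rdname ratio_to_atom_percent
#' @export
delta_to_ratio <- function(delta, system = "C") {
  if (!inherits(system, "isotope_system")) system <- isotope_system(system)
  if (any(delta <= -1000, na.rm = TRUE)) {
    stop("delta must be > -1000 per mil (ratio would be <= 0)", call. = FALSE)
  }
  system$reference_ratio * (1 + delta / 1000)
}

#' Substrate pool specification
#'
#' A pool is an amount of substrate at a given isotopic composition: a
#' concentration (micromolar) and the atom percent of the heavy isotope.
#' Used by [mix_pools()] for the label/natural mass balance.
#'
#' @param concentration Concentration in uM, `>= 0`.
#' @param atom_percent Heavy-isotope atom percent of the pool, in `[0, 100]`.
#' @return A list of class `pool_spec`.
#' @export
pool_spec <- function(concentration, atom_percent) {
  stopifnot(is.numeric(concentration), is.numeric(atom_percent))
  if (concentration < 0) stop("pool concentration must be >= 0", call. = FALSE)
  if (atom_percent < 0 || atom_percent > 100) {
    stop("pool atom percent must lie in [0, 100]", call. = FALSE)
  }
  structure(
    list(concentration = concentration, atom_percent = atom_percent),
    class = "pool_spec"
  )
}

#' Two-pool label mixing mass balance
#'
#' Computes the final heavy-isotope atom percent of a substrate pool after a
#' labelled spike is added to the natural background pool, by
#' concentration-weighted averaging of the two atom fractions:
#' \deqn{ap = (c_L ap_L + c_N ap_N) / (c_L + c_N).}
#'
#' Mixing is at the substrate-molecule level: a singly labelled substrate
#' (e.g. 1-13C acetate at 99 atom%) is treated as a 99 atom% pool, which is
#' the convention that reproduces typical published final ratios for SIP
#' incubations. An alternative position-aware mode distributes the label over
#' all `n_positions` carbon (or nitrogen) positions of the molecule, so the
#' same spike contributes `ap/n` excess per atom; this diverges from the
#' molecule-level bookkeeping and is off by default.
#'
#' @param label,natural [pool_spec()] objects (or 2-element lists with
#'   `concentration` and `atom_percent`), for the added label and the ambient
#'   natural pool. A natural pool at natural abundance can be built with
#'   `pool_spec(conc, natural_atom_percent("C"))`.
#' @param n_positions Number of label-bearing atom positions per molecule;
#'   `1` (default) is the molecule-level convention.
#' @return Final atom percent of the combined pool (scalar).
#' @examples
#' # 500 uM 1-13C acetate (99 atom%) into a 1000 uM natural pool:
#' mix_pools(pool_spec(500, 99), pool_spec(1000, natural_atom_percent("C")))
#' @export
mix_pools <- function(label, natural, n_positions = 1) {
  label <- as_pool(label)
  natural <- as_pool(natural)
  cl <- label$concentration
  cn <- natural$concentration
  if (cl + cn <= 0) {
    stop("undefined mixture: both pool concentrations are zero", call. = FALSE)
  }
  if (n_positions == 1) {
    (cl * label$atom_percent + cn * natural$atom_percent) / (cl + cn)
  } else {
    # position-aware: label excess over natural abundance is diluted over all
    # atom positions of the molecule
    ap_nat <- natural$atom_percent
    excess <- (label$atom_percent - ap_nat) / n_positions
    (cl * (ap_nat + excess) + cn * ap_nat) / (cl + cn)
  }
}

as_pool <- function(x) {
  if (inherits(x, "pool_spec")) return(x)
  if (is.list(x) && all(c("concentration", "atom_percent") %in% names(x))) {
    return(pool_spec(x$concentration, x$atom_percent))
  }
  if (is.numeric(x) && length(x) == 2) return(pool_spec(x[1], x[2]))
  stop("cannot interpret pool specification", call. = FALSE)
}

#' Exportable table of isotope constants
#'
#' Returns (and optionally writes as JSON, for provenance alongside pipeline
#' outputs) the reference ratios and natural-abundance atom percents used
#' throughout the package.
#'
#' @param path Optional file path; when given the table is also written as
#'   JSON.
#' @return A tibble with one row per isotope system.
#' @export
isotope_constants <- function(path = NULL) {
  tab <- dplyr::bind_rows(lapply(c("C", "N"), function(el) {
    sys <- isotope_system(el)
    tibble::tibble(
      element = sys$element,
      element_label = sys$element_label,
      reference_ratio = sys$reference_ratio,
      natural_atom_percent = natural_atom_percent(el)
    )
  }))
  if (!is.null(path)) {
    jsonlite::write_json(tab, path, digits = NA, pretty = TRUE)
  }
  tab
}
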