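#' Parse fatty-acid shorthand names
#'
#' Parses the `CX:Y` family of fatty-acid designations used in membrane-lipid
#' work, where `X` is the number of carbons, `Y` the number of double bonds
#' and `Z` (in `CX:Yn-Z`) the position of the ultimate double bond counted
#' from the terminal methyl. Recognised dialects:
#'
#' * `"C16:0"`, `"C18:1n-7"` (also `"C18:1 n-7"`)
#' * `"C16:0-OH"` — hydroxy fatty acid
#' * `"C15:0 iso"`, `"iso C15:0"`, `"C17:0 anteiso"` — branched
#' * `"9-10diMe C16"`, `"cyC17:0"` — cyclopropane (methylene-bridged)
#'
#' Whitespace and case are treated permissively; unknown suffixes are
#' rejected rather than guessed.
#'
#' @param name Character vector of fatty-acid names.
#' @return A tibble with one row per name: `raw_name`, `n_carbons`,
#'   `n_double_bonds`, `omega_position` (NA when unspecified), `modifier`
#'   (one of `"none"`, `"iso"`, `"anteiso"`, `"cyclopropane"`, `"hydroxy"`).
#' @examples
#' parse_fa_name(c("C18:1n-7", "C16:0", "9-10diMe C16"))
#' @export
parse_fa_name <- function(name) {
  stopifnot(is.character(name), length(name) >= 1)
  purrr::map_dfr(name, parse_fa_name_one)
}

parse_fa_name_one <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) {
    stop("fatty-acid name must be nonempty", call. = FALSE)
  }
  s <- trimws(raw)
  modifier <- "none"
  omega <- NA_integer_

  # cyclopropane dialects: "9-10diMe C16" / "cyC17:0"
  if (grepl("^[0-9]+-[0-9]+\\s*diMe\\s+C[0-9]+", s, ignore.case = TRUE)) {
    modifier <- "cyclopropane"
    s <- sub("^[0-9]+-[0-9]+\\s*diMe\\s+", "", s, ignore.case = TRUE)
    if (!grepl(":", s)) s <- paste0(s, ":0")
  } else if (grepl("^cy\\s*C[0-9]+", s, ignore.case = TRUE)) {
    modifier <- "cyclopropane"
    s <- sub("^cy\\s*", "", s, ignore.case = TRUE)
  }

  # branched prefix or suffix
  if (grepl("^(iso|anteiso)\\s+", s, ignore.case = TRUE)) {
    modifier <- tolower(sub("\\s.*$", "", s))
    s <- sub("^(iso|anteiso)\\s+", "", s, ignore.case = TRUE)
  } else if (grepl("\\s+(iso|anteiso)$", s, ignore.case = TRUE)) {
    modifier <- tolower(sub("^.*\\s+", "", s))
    s <- sub("\\s+(iso|anteiso)$", "", s, ignore.case = TRUE)
  }

  # hydroxy suffix
  if (grepl("-OH$", s, ignore.case = TRUE)) {
    if (modifier != "none") {
      stop("cannot parse \"", raw, "\": conflicting modifiers", call. = FALSE)
    }
    modifier <- "hydroxy"
    s <- sub("-OH$", "", s, ignore.case = TRUE)
  }

  m <- regmatches(s, regexec(
    "^C([0-9]+):([0-9]+)\\s*(?:n-?\\s*([0-9]+))?$", s,
    ignore.case = TRUE
  ))[[1]]
  if (length(m) == 0) {
    stop("cannot parse fatty-acid name \"", raw,
      "\": unrecognised token \"", s, "\"",
      call. = FALSE
    )
  }
  x <- as.integer(m[2])
  y <- as.integer(m[3])
  if (nzchar(m[4])) omega <- as.integer(m[4])
  if (x < 2) stop("fatty acid must have >= 2 carbons: \"", raw, "\"", call. = FALSE)
  if (!is.na(omega) && y < 1) {
    stop("omega position given but no double bond: \"", raw, "\"", call. = FALSE)
  }
  tibble::tibble(
    raw_name = raw, n_carbons = x, n_double_bonds = y,
    omega_position = omega, modifier = modifier
  )
}

#' Canonical fatty-acid name from a parsed descriptor
#'
#' Inverse of [parse_fa_name()] up to whitespace/case normalisation; parsing
#' the formatted name recovers the same descriptor fields.
#'
#' @param fa A one-or-more-row tibble as returned by [parse_fa_name()].
#' @return Character vector of canonical names.
#' @export
format_fa_name <- function(fa) {
  base <- paste0("C", fa$n_carbons, ":", fa$n_double_bonds)
  out <- ifelse(!is.na(fa$omega_position),
    paste0(base, "n-", fa$omega_position), base
  )
  out <- ifelse(fa$modifier %in% c("iso", "anteiso"),
    paste(out, fa$modifier), out
  )
  out <- ifelse(fa$modifier == "hydroxy", paste0(out, "-OH"), out)
  ifelse(fa$modifier == "cyclopropane", paste0("cy", out), out)
}

#' Fractional carbon contribution of the free fatty acid to its methyl ester
#'
#' Methylation adds one carbon to an X-carbon fatty acid, so the free acid
#' contributes `X/(X+1)` of the ester's carbon (16/17 for a C16 acid). This is
#' the weight `f` in [correct_fame_delta()].
#'
#' @param n_carbons Carbon number(s) of the free fatty acid, `>= 1`.
#' @return `n_carbons / (n_carbons + 1)`, vectorised.
#' @export
fa_fraction <- function(n_carbons) {
  stopifnot(is.numeric(n_carbons))
  if (any(n_carbons < 1, na.rm = TRUE)) {
    stop("fatty-acid carbon number must be >= 1", call. = FALSE)
  }
  n_carbons / (n_carbons + 1)
}

#' Correct measured FAME delta-13C for the derivatization methyl group
#'
#' The delta-13C measured on a fatty acid methyl ester (FAME) includes one
#' carbon from the methanol used for methylation. The free-fatty-acid value
#' is recovered by the linear (delta-scale) mass balance
#' \deqn{\delta^{13}C_{FA} = (\delta^{13}C_{FAME} - (1-f)\,\delta^{13}C_{CH_3OH})/f}
#' with `f` from [fa_fraction()]. The delta-scale form is the standard
#' correction; it is a linearisation of the exact atom-fraction mixing and is
#' slightly biased for strongly 13C-enriched SIP samples (deltas of thousands
#' of per mil), for which `method = "atom_fraction"` performs the same mass
#' balance on the atom-fraction scale exactly.
#'
#' @param delta_fame Measured ester delta-13C (per mil), vectorised.
#' @param f Fractional carbon contribution of the free acid, in `(0, 1)`.
#' @param delta_meoh Delta-13C of the derivatization methanol (per mil);
#'   default -37.9.
#' @param method `"delta"` (default, linear on the delta scale) or
#'   `"atom_fraction"` (exact).
#' @return Free-fatty-acid delta-13C (per mil).
#' @seealso [esterify_delta()], the forward mixing, its exact inverse.
#' @export
correct_fame_delta <- function(delta_fame, f, delta_meoh = -37.9,
                               method = c("delta", "atom_fraction")) {
  method <- match.arg(method)
  if (any(f <= 0 | f >= 1, na.rm = TRUE)) {
    stop("f must lie strictly in (0, 1)", call. = FALSE)
  }
  if (method == "delta") {
    (delta_fame - (1 - f) * delta_meoh) / f
  } else {
    x_fame <- delta_to_atom_fraction(delta_fame, "C")
    x_meoh <- delta_to_atom_fraction(delta_meoh, "C")
    x_fa <- (x_fame - (1 - f) * x_meoh) / f
    atom_fraction_to_delta(x_fa, "C")
  }
}

#' Forward esterification mixing of delta values
#'
#' The ester's delta as the f-weighted mixture of the free acid and the
#' methanol carbon: `f * delta_fa + (1 - f) * delta_meoh` (delta scale), or
#' the equivalent exact mixture of atom fractions. Inverse of
#' [correct_fame_delta()] under the matching `method`.
#'
#' @inheritParams correct_fame_delta
#' @param delta_fa Free-fatty-acid delta-13C (per mil).
#' @return Ester delta-13C (per mil).
#' @export
esterify_delta <- function(delta_fa, f, delta_meoh = -37.9,
                           method = c("delta", "atom_fraction")) {
  method <- match.arg(method)
  if (any(f <= 0 | f >= 1, na.rm = TRUE)) {
    stop("f must lie strictly in (0, 1)", call. = FALSE)
  }
  if (method == "delta") {
    f * delta_fa + (1 - f) * delta_meoh
  } else {
    x <- f * delta_to_atom_fraction(delta_fa, "C") +
      (1 - f) * delta_to_atom_fraction(delta_meoh, "C")
    atom_fraction_to_delta(x, "C")
  }
}

delta_to_atom_fraction <- function(delta, system) {
  R <- delta_to_ratio(delta, system)
  R / (1 + R)
}

atom_fraction_to_delta <- function(x, system) {
  ratio_to_delta(x / (1 - x), system)
}

#' Apply the methyl-group correction to a CSIA-FAME table
#'
#' Data-frame-first wrapper: parses the fatty-acid names, computes `f` and
#' adds the corrected free-fatty-acid `delta_fa` column. The input is the CSV
#' layout produced by GC-IRMS export: one row per (fatty acid, treatment,
#' replicate) with the measured ester `delta_fame`. A per-row `delta_meoh`
#' column overrides the global default when present.
#'
#' @param records Data frame with columns `name`, `treatment`, `replicate`,
#'   `delta_fame` and optionally `delta_meoh`.
#' @param delta_meoh Default methanol delta-13C (per mil) for rows without
#'   their own value.
#' @param method Passed to [correct_fame_delta()].
#' @return The input as a tibble with added columns `n_carbons`,
#'   `n_double_bonds`, `omega_position`, `modifier`, `f`, `delta_fa`.
#' @export
correct_fame <- function(records, delta_meoh = -37.9,
                         method = c("delta", "atom_fraction")) {
  method <- match.arg(method)
  records <- tibble::as_tibble(records)
  need <- c("name", "treatment", "replicate", "delta_fame")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("FAME table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  fa <- parse_fa_name(records$name)
  meoh <- if ("delta_meoh" %in% names(records)) {
    dplyr::coalesce(records$delta_meoh, delta_meoh)
  } else {
    rep(delta_meoh, nrow(records))
  }
  records |>
    dplyr::mutate(
      n_carbons = fa$n_carbons,
      n_double_bonds = fa$n_double_bonds,
      omega_position = fa$omega_position,
      modifier = fa$modifier,
      f = fa_fraction(fa$n_carbons),
      delta_meoh = meoh,
      delta_fa = correct_fame_delta(.data$delta_fame, .data$f, meoh,
        method = method
      )
    )
}

#' Per-fatty-acid treatment enrichment summary
#'
#' Summarises corrected free-fatty-acid delta-13C per fatty acid and
#' treatment (mean, sd, n), computes each treatment's difference from the
#' control mean, and runs a Van der Waerden normal-scores test across
#' treatments per fatty acid with a Holm-adjusted compact letter display
#' ([pairwise_letters()]). Treatments that do not share a letter with the
#' control are flagged `enriched`.
#'
#' Fatty acids with fewer than two replicates in any treatment are summarised
#' without a test (`tested = FALSE`).
#'
#' @param records A corrected FAME table from [correct_fame()] (needs columns
#'   `name`, `treatment`, `replicate`, `delta_fa`).
#' @param control_label Treatment label of the unamended control.
#' @param alpha Significance level for the letter display.
#' @param correction Multiplicity correction for pairwise p values
#'   (see [stats::p.adjust()]); Holm by default.
#' @return A tibble with one row per fatty acid x treatment: `name`,
#'   `treatment`, `n`, `mean_delta_fa`, `sd_delta_fa`, `diff_from_control`,
#'   `p_value` (global test, repeated within fatty acid), `letters`,
#'   `enriched`, `tested`.
#' @export
enrichment_table <- function(records, control_label = "control",
                             alpha = 0.05, correction = "holm") {
  records <- tibble::as_tibble(records)
  if (!"delta_fa" %in% names(records)) {
    stop("records lack a delta_fa column; run correct_fame() first",
      call. = FALSE
    )
  }
  if (!control_label %in% records$treatment) {
    stop("control treatment \"", control_label, "\" not present", call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$name) |>
    dplyr::group_modify(~ enrich_one_fa(.x, control_label, alpha, correction)) |>
    dplyr::ungroup()
}

enrich_one_fa <- function(df, control_label, alpha, correction) {
  summ <- df |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delta_fa = mean(.data$delta_fa),
      sd_delta_fa = stats::sd(.data$delta_fa),
      .groups = "drop"
    )
  ctrl_mean <- summ$mean_delta_fa[summ$treatment == control_label]
  summ$diff_from_control <- summ$mean_delta_fa - ctrl_mean

  testable <- all(summ$n >= 2) && nrow(summ) >= 2
  if (testable) {
    gs <- grouped_samples(df$delta_fa, df$treatment)
    gt <- van_der_waerden(gs)
    ld <- pairwise_letters(gs, alpha = alpha, correction = correction)
    summ$p_value <- gt$p_value
    summ$letters <- ld$letters$letters[match(summ$treatment, ld$letters$group)]
    ctrl_letters <- strsplit(summ$letters[summ$treatment == control_label], "")[[1]]
    summ$enriched <- !purrr::map_lgl(
      strsplit(summ$letters, ""),
      ~ any(.x %in% ctrl_letters)
    )
    summ$tested <- TRUE
  } else {
    summ$p_value <- NA_real_
    summ$letters <- NA_character_
    summ$enriched <- NA
    summ$tested <- FALSE
  }
  summ
}
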