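#' Synthetic mat scenario
#'
#' Declarative description of one simulated NanoSIMS acquisition of a coccoid
#' purple-sulfur-bacteria mat: field geometry, cell population, per-cell true
#' enrichment, ion yields and counting noise. [simulate_stack()] turns it
#' into an [ion_count_stack()] plus a ground-truth table.
#'
#' Enrichment specifications (`r_C`, `r_N`) may be a scalar, a vector of
#' length `n_cells`, or a `function(n)` returning `n` draws — the latter is
#' how bimodal active/inactive populations are expressed (see
#' [r_active_inactive()]).
#'
#' @param n_cells Number of cells to place.
#' @param field_size_um Field width (square), micrometres; default 25.
#' @param raster Pixels per side; default 256.
#' @param n_planes Number of rescans; default 28 (acquisitions rescan the
#'   field 25-30 times at 1 ms/pixel).
#' @param diameter_mean_um,diameter_sd_um Cell diameter distribution
#'   (truncated normal, floored at 4 pixels); defaults 1.67 and 0.1.
#' @param r_C,r_N True enrichment fractions per element (scalar, vector or
#'   function).
#' @param A_ini_C,A_final_C,A_ini_N,A_final_N Atom-percent anchors mapping r
#'   to the cell's isotopic composition (baseline and fully-labelled pool);
#'   defaults: natural abundance baselines, acetate-like 33.5 atom% 13C and
#'   ammonium-like 74.5 atom% 15N pools.
#' @param yield_C,yield_CN,yield_S Expected counts per pixel per plane inside
#'   a cell for total carbon (12C- + 13C-), total CN- and 32S-.
#' @param background_fraction Cell-free pixels receive this fraction of the
#'   cell yields, at natural abundance.
#' @param globule_rate Mean number of sulfur-globule "holes" per cell
#'   (Poisson); globules are zero-yield discs.
#' @param globule_radius_um Globule radius.
#' @param allow_touching Permit overlapping cell placements.
#' @param treatment,replicate Labels carried into the truth table.
#' @param seed Integer seed; makes the simulated stack bit-reproducible.
#' @return List of class `mat_scenario`.
#' @export
mat_scenario <- function(n_cells = 40,
                         field_size_um = 25, raster = 256, n_planes = 28,
                         diameter_mean_um = 1.67, diameter_sd_um = 0.1,
                         r_C = 0, r_N = 0,
                         A_ini_C = natural_atom_percent("C"),
                         A_final_C = 33.5,
                         A_ini_N = natural_atom_percent("N"),
                         A_final_N = 74.5,
                         yield_C = 40, yield_CN = 150, yield_S = 2,
                         background_fraction = 0.03,
                         globule_rate = 1, globule_radius_um = 0.15,
                         allow_touching = FALSE,
                         treatment = "sim", replicate = 1L,
                         seed = NULL) {
  stopifnot(
    n_cells >= 0, field_size_um > 0, raster >= 8, n_planes >= 1,
    yield_C >= 0, yield_CN >= 0, yield_S >= 0,
    background_fraction >= 0, globule_rate >= 0
  )
  structure(
    as.list(environment()),
    class = "mat_scenario"
  )
}

#' Bimodal active/inactive enrichment distribution
#'
#' Returns a `function(n)` drawing per-cell enrichment fractions from a
#' zero-inflated scaled Beta: a cell is active with probability
#' `active_fraction` and then has `r ~ r_max * Beta(shape1, shape2)`;
#' inactive cells have `r = 0`. This is the between-cell heterogeneity
#' pattern seen in natural mats, where physically adjacent cells of the same
#' population differ strongly in uptake.
#'
#' @param active_fraction Probability a cell is active.
#' @param r_max Upper scale of the active-cell enrichment.
#' @param shape1,shape2 Beta shape parameters of the active mode.
#' @return A `function(n)`.
#' @export
r_active_inactive <- function(active_fraction = 0.6, r_max = 0.2,
                              shape1 = 2, shape2 = 8) {
  force(active_fraction); force(r_max); force(shape1); force(shape2)
  function(n) {
    active <- stats::runif(n) < active_fraction
    r <- numeric(n)
    r[active] <- r_max * stats::rbeta(sum(active), shape1, shape2)
    r
  }
}

draw_r <- function(spec, n) {
  r <- if (is.function(spec)) {
    spec(n)
  } else if (length(spec) == 1) {
    rep(as.numeric(spec), n)
  } else if (length(spec) == n) {
    as.numeric(spec)
  } else {
    stop("enrichment spec must be scalar, length n_cells, or a function",
      call. = FALSE
    )
  }
  if (any(r < 0 | r > 1)) stop("true r must lie in [0, 1]", call. = FALSE)
  r
}

#' Simulate a NanoSIMS ion-count stack from a mat scenario
#'
#' Forward model: cells are rendered as discs (a pixel belongs to a cell when
#' its centre lies within the radius, giving an exact-area ground truth);
#' each cell's atom fractions follow from its true enrichment via the inverse
#' of the enrichment-fraction relation,
#' \eqn{A = A_{ini} + r (A_{final} - A_{ini})}; per pixel and plane the total
#' element yield is partitioned between isotopologue channels by the atom
#' fraction and counts are drawn independently Poisson per channel —
#' ion-counting physics. Background pixels emit at `background_fraction` of
#' the cell yields at natural abundance; sulfur-globule discs emit nothing in
#' any channel. The CN- channels carry the nitrogen isotope signal; carbon
#' isotope effects on the CN- yield are ignored (13C14N- is not a recorded
#' species).
#'
#' @param scenario A [mat_scenario()].
#' @return List with `stack` (an [ion_count_stack()]), `truth` (tibble: one
#'   row per cell with centre, diameter, pixel area, true r and atom
#'   fractions) and `scenario`.
#' @export
simulate_stack <- function(scenario) {
  stopifnot(inherits(scenario, "mat_scenario"))
  sc <- scenario
  if (!is.null(sc$seed)) set.seed(sc$seed)
  px <- sc$field_size_um / sc$raster
  n <- sc$raster

  diam <- pmax(stats::rnorm(sc$n_cells, sc$diameter_mean_um, sc$diameter_sd_um),
    4 * px
  )
  radius_px <- diam / 2 / px
  centers <- place_cells(sc$n_cells, n, radius_px, sc$allow_touching)

  r_C <- draw_r(sc$r_C, sc$n_cells)
  r_N <- draw_r(sc$r_N, sc$n_cells)
  a_C <- (sc$A_ini_C + r_C * (sc$A_final_C - sc$A_ini_C)) / 100
  a_N <- (sc$A_ini_N + r_N * (sc$A_final_N - sc$A_ini_N)) / 100
  a_C_nat <- natural_atom_percent("C") / 100
  a_N_nat <- natural_atom_percent("N") / 100

  # per-pixel maps: cell id (0 = background) and dead (globule) mask
  cell_map <- matrix(0L, n, n)
  dead <- matrix(FALSE, n, n)
  rows <- matrix(rep(seq_len(n), n), n, n)
  cols <- matrix(rep(seq_len(n), each = n), n, n)
  n_pixels <- integer(sc$n_cells)
  for (k in seq_len(sc$n_cells)) {
    inside <- (rows - centers$row[k])^2 + (cols - centers$col[k])^2 <=
      radius_px[k]^2
    n_pixels[k] <- sum(inside)
    cell_map[inside] <- k
    n_glob <- stats::rpois(1, sc$globule_rate)
    if (n_glob > 0) {
      g_r_px <- sc$globule_radius_um / px
      for (g in seq_len(n_glob)) {
        theta <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.6 * radius_px[k])
        gr <- centers$row[k] + rad * cos(theta)
        gc <- centers$col[k] + rad * sin(theta)
        dead <- dead | ((rows - gr)^2 + (cols - gc)^2 <= g_r_px^2 & inside)
      }
    }
  }

  in_cell <- cell_map > 0L
  idx <- ifelse(in_cell, cell_map, NA_integer_)
  pix_aC <- matrix(a_C_nat, n, n)
  pix_aN <- matrix(a_N_nat, n, n)
  pix_aC[in_cell] <- a_C[idx[in_cell]]
  pix_aN[in_cell] <- a_N[idx[in_cell]]

  lam_C <- ifelse(in_cell, sc$yield_C, sc$yield_C * sc$background_fraction)
  lam_CN <- ifelse(in_cell, sc$yield_CN, sc$yield_CN * sc$background_fraction)
  lam_S <- ifelse(in_cell, sc$yield_S, sc$yield_S * sc$background_fraction)
  lam_C[dead] <- 0; lam_CN[dead] <- 0; lam_S[dead] <- 0

  lam <- list(
    "12C" = lam_C * (1 - pix_aC),
    "13C" = lam_C * pix_aC,
    "12C14N" = lam_CN * (1 - pix_aN),
    "12C15N" = lam_CN * pix_aN,
    "32S" = lam_S
  )
  counts <- array(0L,
    dim = c(n, n, sc$n_planes, length(ion_channels)),
    dimnames = list(NULL, NULL, NULL, ion_channels)
  )
  for (ch in ion_channels) {
    lv <- as.numeric(lam[[ch]])
    for (p in seq_len(sc$n_planes)) {
      counts[, , p, ch] <- stats::rpois(n * n, lv)
    }
  }

  truth <- tibble::tibble(
    cell_id = seq_len(sc$n_cells),
    row = centers$row, col = centers$col,
    diameter_um = diam, radius_px = radius_px,
    n_pixels = n_pixels,
    r_C = r_C, r_N = r_N,
    atom_fraction_C = a_C, atom_fraction_N = a_N,
    treatment = sc$treatment, replicate = sc$replicate
  )
  list(
    stack = ion_count_stack(counts,
      field_size_um = sc$field_size_um, dwell_ms = 1
    ),
    truth = truth,
    scenario = sc
  )
}

place_cells <- function(n_cells, raster, radius_px, allow_touching,
                        max_tries = 300) {
  rows <- numeric(0); cols <- numeric(0)
  for (k in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, radius_px[k] + 1, raster - radius_px[k] - 1)
      cc <- stats::runif(1, radius_px[k] + 1, raster - radius_px[k] - 1)
      if (allow_touching || length(rows) == 0 ||
        all(sqrt((rows - r)^2 + (cols - cc)^2) >
          radius_px[seq_along(rows)] + radius_px[k] + 2)) {
        rows <- c(rows, r); cols <- c(cols, cc)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible packing: could not place ", n_cells,
        " non-overlapping cells of this size in the field",
        call. = FALSE
      )
    }
  }
  list(row = rows, col = cols)
}

#' Synthetic CSIA-FAME scenario and table
#'
#' `fame_scenario()` declares a fatty-acid panel with per-FA baseline
#' delta-13C, per-(FA, treatment) enrichment effects (per-mil shifts),
#' replicate noise and a replicate count. `simulate_fame_table()` draws the
#' true free-fatty-acid values (`baseline + effect + N(0, noise_sd)`) and
#' emits them as *measured ester* values by forward esterification mixing
#' with the scenario's methanol delta — so an analysis pipeline must invert
#' the methyl-group correction to recover the truth.
#'
#' @param panel Character vector of fatty-acid names (parseable by
#'   [parse_fa_name()]).
#' @param baseline Named numeric: baseline delta-13C per FA (per mil);
#'   unnamed scalar recycles.
#' @param effects Tibble with columns `name`, `treatment`, `shift` (per mil),
#'   or NULL for no effects. Treatments absent for a FA shift by 0; the
#'   control treatment must not appear here.
#' @param treatments Treatment labels (first is taken as control when
#'   summarising).
#' @param noise_sd Replicate noise sd, per mil.
#' @param n_replicates Replicates per (FA, treatment).
#' @param delta_meoh Methanol delta-13C used in the forward esterification.
#' @param seed Integer seed.
#' @return `fame_scenario()`: list of class `fame_scenario`;
#'   `simulate_fame_table()`: tibble with `name`, `treatment`, `replicate`,
#'   `delta_fame`, `delta_meoh` and the ground-truth `truth_delta_fa`.
#' @export
fame_scenario <- function(panel = c(
                            "C18:1n-7", "C16:1n-7", "C16:0", "C14:0",
                            "C15:0 iso", "C17:0 anteiso", "9-10diMe C16"
                          ),
                          baseline = -28,
                          effects = NULL,
                          treatments = c("control", "AceL", "PyrL", "CO3L"),
                          noise_sd = 10,
                          n_replicates = 3,
                          delta_meoh = -37.9,
                          seed = NULL) {
  parse_fa_name(panel) # validates
  if (is.null(names(baseline))) {
    baseline <- stats::setNames(rep(baseline[1], length(panel)), panel)
  }
  if (!all(panel %in% names(baseline))) {
    stop("baseline must cover every panel fatty acid", call. = FALSE)
  }
  if (!is.null(effects)) {
    stopifnot(all(c("name", "treatment", "shift") %in% names(effects)))
    if (any(effects$treatment == treatments[1])) {
      stop("effects must not target the control treatment", call. = FALSE)
    }
  }
  structure(
    list(
      panel = panel, baseline = baseline, effects = effects,
      treatments = treatments, noise_sd = noise_sd,
      n_replicates = n_replicates, delta_meoh = delta_meoh, seed = seed
    ),
    class = "fame_scenario"
  )
}

#' @rdname fame_scenario
#' @param scenario A `fame_scenario`.
#' @export
simulate_fame_table <- function(scenario) {
  stopifnot(inherits(scenario, "fame_scenario"))
  sc <- scenario
  if (!is.null(sc$seed)) set.seed(sc$seed)
  grid <- tidyr::expand_grid(
    name = sc$panel, treatment = sc$treatments,
    replicate = seq_len(sc$n_replicates)
  )
  shift <- rep(0, nrow(grid))
  if (!is.null(sc$effects)) {
    key <- paste(grid$name, grid$treatment)
    ekey <- paste(sc$effects$name, sc$effects$treatment)
    hit <- match(key, ekey)
    shift[!is.na(hit)] <- sc$effects$shift[hit[!is.na(hit)]]
  }
  truth <- sc$baseline[grid$name] + shift +
    stats::rnorm(nrow(grid), 0, sc$noise_sd)
  f <- fa_fraction(parse_fa_name(grid$name)$n_carbons)
  grid |>
    dplyr::mutate(
      delta_fame = unname(esterify_delta(truth, f, sc$delta_meoh)),
      delta_meoh = sc$delta_meoh,
      truth_delta_fa = unname(truth)
    )
}

#' The seven-treatment SIP incubation preset
#'
#' Returns the full design of the mat labelling experiment: seven triplicate
#' treatments — an unamended control plus acetate, pyruvate and bicarbonate
#' under light ("L") and dark ("D"), all carbon treatments carrying the
#' 15N-ammonium co-label — with the final pool atom percents
#' (bicarbonate 28.1, acetate 33.5, pyruvate 86.9 atom% 13C; ammonium
#' 74.5 atom% 15N), final substrate concentrations (label + ambient:
#' acetate 1.5 mM, pyruvate 570 uM, bicarbonate 1.8 mM, ammonium 130.8 uM),
#' a 5 h duration and 1.67 um mean cell diameter. Per-cell enrichment uses
#' the bimodal active/inactive mixture ([r_active_inactive()]): in the light
#' active cells reach up to ~0.2 of full equilibration; in the dark uptake is
#' strongly reduced except for acetate, whose assimilation is not
#' light-dependent. The control has `r = 0` for every cell.
#'
#' @param n_cells Cells per simulated field.
#' @param n_replicates Replicate fields per treatment (3, as incubated).
#' @param seed Base seed; each scenario gets a distinct derived seed.
#' @param ... Further arguments passed to every [mat_scenario()] (e.g.
#'   `yield_C` to raise counting statistics).
#' @return List with `scenarios` (list of `mat_scenario`, one per treatment x
#'   replicate), `incubations` (named list of [incubation_config()] per
#'   non-control treatment, carbon substrate), `ammonium` (the 15N
#'   incubation config) and `design` (tibble of the treatment table).
#' @export
sip_experiment_preset <- function(n_cells = 40, n_replicates = 3,
                                  seed = 1, ...) {
  design <- tibble::tibble(
    treatment = c("control", "AceL", "AceD", "PyrL", "PyrD", "CO3L", "CO3D"),
    substrate = c(NA, "acetate", "acetate", "pyruvate", "pyruvate",
      "bicarbonate", "bicarbonate"
    ),
    light = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    concentration_M = c(NA, 1.5e-3, 1.5e-3, 570e-6, 570e-6, 1.8e-3, 1.8e-3),
    R_final_C = c(NA, 33.5, 33.5, 86.9, 86.9, 28.1, 28.1),
    R_final_N = c(NA, rep(74.5, 6)),
    duration_h = 5
  )

  r_spec <- function(treatment, light, substrate, element) {
    if (treatment == "control") return(0)
    dark_scale <- if (substrate == "acetate") 0.75 else 0.1
    scale <- if (light) 1 else dark_scale
    r_max <- if (element == "C") 0.2 else 0.1
    r_active_inactive(active_fraction = 0.6, r_max = r_max * scale)
  }

  scenarios <- list()
  i <- 0
  for (t_i in seq_len(nrow(design))) {
    row <- design[t_i, ]
    for (rep_i in seq_len(n_replicates)) {
      i <- i + 1
      scenarios[[i]] <- mat_scenario(
        n_cells = n_cells,
        r_C = r_spec(row$treatment, row$light, row$substrate %||% "", "C"),
        r_N = r_spec(row$treatment, row$light, row$substrate %||% "", "N"),
        A_final_C = if (is.na(row$R_final_C)) 33.5 else row$R_final_C,
        A_final_N = if (is.na(row$R_final_N)) 74.5 else row$R_final_N,
        treatment = row$treatment, replicate = rep_i,
        seed = if (is.null(seed)) NULL else seed + 1000L * t_i + rep_i,
        ...
      )
    }
  }

  incubations <- list()
  for (t_i in which(!is.na(design$substrate))) {
    row <- design[t_i, ]
    incubations[[row$treatment]] <- incubation_config(
      substrate = row$substrate, element = "C",
      concentration_M = row$concentration_M,
      duration_h = row$duration_h, light = row$light,
      R_final = row$R_final_C
    )
  }
  ammonium <- incubation_config(
    substrate = "ammonium", element = "N",
    concentration_M = 130.8e-6, duration_h = 5, light = TRUE,
    R_final = 74.5
  )
  list(
    scenarios = scenarios, incubations = incubations,
    ammonium = ammonium, design = design
  )
}
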