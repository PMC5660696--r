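#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML or JSON (by extension). Recognised sections:
#' `out` (output directory, required), `seed`, `simulate` (arguments of
#' [sip_experiment_preset()]: `n_cells`, `n_replicates`, plus any
#' [mat_scenario()] override such as `yield_C`), `segmentation` (arguments of
#' [segment_cells()]), `fame` (`table` path to a measured CSV, or a
#' [fame_scenario()] description: `panel`, `baseline`, `effects`, `noise_sd`,
#' `n_replicates`; plus `delta_meoh`, `control`), `stats` (`alpha`,
#' `correction`) and `community` (`cell_density` or `bchl_per_g_sediment` /
#' `bchl_per_C` / `C_per_cell_fg`; optional `chamber_flux_mgC_m2_h`,
#' `depth_cm`, `sediment_density`).
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return The validated configuration list, classed `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  if (is.null(config$out)) stop("config requires an 'out' directory", call. = FALSE)
  seg <- config$segmentation
  if (!is.null(seg$min_circularity) &&
    (seg$min_circularity < 0 || seg$min_circularity > 1)) {
    stop("segmentation$min_circularity must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seg$diameter_tol) && seg$diameter_tol >= 1) {
    stop("segmentation$diameter_tol must be < 1", call. = FALSE)
  }
  structure(config, class = c("run_config", "list"))
}

pipeline_stages <- c(
  "simulate", "segment", "quantify", "flux", "fame", "stats", "community"
)

#' Run the analysis pipeline
#'
#' Drives the stage graph over a run configuration. Stages (run in dependency
#' order regardless of the order requested):
#' \describe{
#'   \item{simulate}{generate the preset experiment's ion-count stacks and
#'     ground truth under `out/stacks/`}
#'   \item{segment}{segment every stack's accumulated CN image to
#'     `out/masks/`}
#'   \item{quantify}{per-ROI isotope measurement, control-referenced, to
#'     `out/measurements.csv`}
#'   \item{flux}{enrichment fractions and per-cell C and N fluxes to
#'     `out/fluxes.csv` + `out/flux_summary.csv`}
#'   \item{fame}{CSIA-FAME correction and enrichment summary to
#'     `out/fame_*.csv`}
#'   \item{stats}{treatment comparison (Van der Waerden + letters) and C-N
#'     ANCOVA on the measurements to `out/stats_*.csv`}
#'   \item{community}{community-scale extrapolation to `out/community.csv`}
#' }
#' An empty `stages` validates the configuration only. Each invocation writes
#' the resolved configuration to `out/resolved_config.json`. Stages read
#' their inputs from `out`, so a later stage can resume from intermediates
#' produced by an earlier run; a missing intermediate raises an error naming
#' the producing stage. Result tables are written with numbers fixed to six
#' significant digits, so the same configuration and seed give byte-identical
#' outputs.
#'
#' @param config Path to a YAML/JSON config, or a list (see
#'   [read_run_config()]).
#' @param stages Character vector of stage names; `"all"` for every stage.
#' @param seed Overrides the config seed.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(config, stages = "all", seed = NULL) {
  cfg <- read_run_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L

  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(out, "resolved_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  artifacts <- list(resolved_config = file.path(out, "resolved_config.json"))
  if (length(stages) == 0) {
    return(invisible(artifacts))
  }

  preset <- do.call(sip_experiment_preset, c(
    list(seed = cfg$seed),
    cfg$simulate %||% list()
  ))

  for (st in stages) {
    artifacts <- c(artifacts, switch(st,
      simulate = stage_simulate(cfg, preset, out),
      segment = stage_segment(cfg, out),
      quantify = stage_quantify(cfg, out),
      flux = stage_flux(cfg, preset, out),
      fame = stage_fame(cfg, out),
      stats = stage_stats(cfg, out),
      community = stage_community(cfg, out)
    ))
  }
  invisible(artifacts)
}

write_result_csv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double), ~ signif(.x, 6)
  ))
  data.table::fwrite(df, path, sep = ",")
  path
}

require_artifact <- function(path, producer) {
  if (!file.exists(path) && !dir.exists(path)) {
    stop("missing intermediate ", path, "; run the '", producer,
      "' stage first",
      call. = FALSE
    )
  }
  path
}

field_id <- function(treatment, replicate) paste0(treatment, "_", replicate)

stage_simulate <- function(cfg, preset, out) {
  stack_root <- file.path(out, "stacks")
  dir.create(stack_root, recursive = TRUE, showWarnings = FALSE)
  truth_all <- list()
  for (sc in preset$scenarios) {
    sim <- simulate_stack(sc)
    id <- field_id(sc$treatment, sc$replicate)
    write_stack(sim$stack, file.path(stack_root, id))
    truth_all[[id]] <- sim$truth
  }
  truth <- dplyr::bind_rows(truth_all)
  list(
    stacks = stack_root,
    truth = write_result_csv(truth, file.path(out, "truth.csv"))
  )
}

list_stack_dirs <- function(out) {
  root <- require_artifact(file.path(out, "stacks"), "simulate")
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) == 0) {
    stop("no stack directories under ", root, "; run the 'simulate' stage first",
      call. = FALSE
    )
  }
  dirs
}

stage_segment <- function(cfg, out) {
  mask_root <- file.path(out, "masks")
  dir.create(mask_root, recursive = TRUE, showWarnings = FALSE)
  seg <- cfg$segmentation %||% list()
  for (d in list_stack_dirs(out)) {
    stack <- read_stack(d)
    acc <- accumulate_planes(stack)
    mask <- do.call(segment_cells, c(
      list(cn_image = acc[["12C14N"]], pixel_size_um = stack$pixel_size_um),
      seg
    ))
    write_roi_mask(mask, file.path(mask_root, paste0(basename(d), ".txt")))
  }
  list(masks = mask_root)
}

stage_quantify <- function(cfg, out) {
  mask_root <- require_artifact(file.path(out, "masks"), "segment")
  dirs <- list_stack_dirs(out)
  per_field <- lapply(dirs, function(d) {
    id <- basename(d)
    mask_path <- require_artifact(
      file.path(mask_root, paste0(id, ".txt")), "segment"
    )
    stack <- read_stack(d)
    mask <- import_roi_mask(mask_path)
    m <- measure_rois(stack, mask)
    m$treatment <- sub("_[0-9]+$", "", id)
    m$replicate <- as.integer(sub("^.*_", "", id))
    m$field <- id
    m
  })
  all_m <- dplyr::bind_rows(per_field)
  ctrl <- dplyr::filter(all_m, .data$treatment == "control", .data$valid)
  if (nrow(ctrl) > 0) {
    cr <- control_ratios(ctrl)
    all_m$delta_C_control <- (all_m$R_C / cr$C - 1) * 1000
    all_m$delta_N_control <- (all_m$R_N / cr$N - 1) * 1000
  }
  list(measurements = write_result_csv(
    all_m, file.path(out, "measurements.csv")
  ))
}

read_measurements <- function(out) {
  path <- require_artifact(file.path(out, "measurements.csv"), "quantify")
  tibble::as_tibble(data.table::fread(path))
}

stage_flux <- function(cfg, preset, out) {
  m <- dplyr::filter(read_measurements(out), .data$valid)
  ctrl <- dplyr::filter(m, .data$treatment == "control")
  if (nrow(ctrl) == 0) {
    stop("no control ROIs in measurements; cannot anchor R_ini", call. = FALSE)
  }
  R_ini_C <- ratio_to_atom_percent(sum(ctrl$count_13C) / sum(ctrl$count_12C))
  R_ini_N <- ratio_to_atom_percent(
    sum(ctrl$count_12C15N) / sum(ctrl$count_12C14N)
  )
  v_bac <- sphere_volume(
    cfg$simulate$diameter_mean_um %||% 1.67
  )$volume_L

  fluxes <- list()
  for (tr in names(preset$incubations)) {
    inc <- preset$incubations[[tr]]
    inc$R_ini <- R_ini_C
    sub <- dplyr::filter(m, .data$treatment == tr)
    if (nrow(sub) == 0) next
    ef_c <- enrichment_fraction(sub$atom_pc_C, inc)
    fc <- cell_flux(ef_c, inc, V_bac_L = v_bac, roi_id = sub$roi_id)
    amm <- preset$ammonium
    amm$R_ini <- R_ini_N
    amm$light <- inc$light
    ef_n <- enrichment_fraction(sub$atom_pc_N, amm)
    fn <- cell_flux(ef_n, amm, V_bac_L = v_bac, roi_id = sub$roi_id)
    fluxes[[tr]] <- dplyr::bind_rows(
      dplyr::mutate(fc, treatment = tr, field = sub$field),
      dplyr::mutate(fn, treatment = tr, field = sub$field)
    )
  }
  fx <- dplyr::bind_rows(fluxes)
  summ <- fx |>
    dplyr::group_by(.data$treatment, .data$element) |>
    dplyr::summarise(
      n = sum(!is.na(.data$r)),
      mean_mass_flux = mean(.data$mass_flux_fg_per_cell_h, na.rm = TRUE),
      sd_mass_flux = stats::sd(.data$mass_flux_fg_per_cell_h, na.rm = TRUE),
      light = .data$light[1],
      .groups = "drop"
    )
  list(
    fluxes = write_result_csv(fx, file.path(out, "fluxes.csv")),
    flux_summary = write_result_csv(summ, file.path(out, "flux_summary.csv"))
  )
}

stage_fame <- function(cfg, out) {
  fc <- cfg$fame %||% list()
  tab <- if (!is.null(fc$table)) {
    tibble::as_tibble(data.table::fread(require_artifact(fc$table, "input")))
  } else {
    sc_args <- fc[names(fc) %in% c(
      "panel", "baseline", "effects", "treatments",
      "noise_sd", "n_replicates", "delta_meoh"
    )]
    if (!is.null(sc_args$effects)) {
      sc_args$effects <- tibble::as_tibble(sc_args$effects)
    }
    sc <- do.call(fame_scenario, c(sc_args, list(seed = cfg$seed)))
    simulate_fame_table(sc)
  }
  corrected <- correct_fame(tab, delta_meoh = fc$delta_meoh %||% -37.9)
  enr <- enrichment_table(corrected,
    control_label = fc$control %||% "control",
    alpha = cfg$stats$alpha %||% 0.05,
    correction = cfg$stats$correction %||% "holm"
  )
  list(
    fame_corrected = write_result_csv(
      corrected, file.path(out, "fame_corrected.csv")
    ),
    fame_enrichment = write_result_csv(
      enr, file.path(out, "fame_enrichment.csv")
    )
  )
}

stage_stats <- function(cfg, out) {
  m <- dplyr::filter(read_measurements(out), .data$valid)
  alpha <- cfg$stats$alpha %||% 0.05
  correction <- cfg$stats$correction %||% "holm"
  gs <- grouped_samples(m$delta_C, m$treatment)
  gt <- van_der_waerden(gs)
  ld <- pairwise_letters(gs, alpha = alpha, correction = correction)
  vdw_tab <- dplyr::mutate(ld$letters,
    statistic = gt$statistic, df = gt$df, p_value = gt$p_value
  )
  noctrl <- dplyr::filter(m, .data$treatment != "control")
  anc <- ancova_slopes(noctrl, x = "delta_C", y = "delta_N", group = "treatment")
  anc_tab <- dplyr::mutate(tidy(anc), alpha = alpha)
  list(
    stats_vdw = write_result_csv(vdw_tab, file.path(out, "stats_vdw.csv")),
    stats_ancova = write_result_csv(anc_tab, file.path(out, "stats_ancova.csv"))
  )
}

stage_community <- function(cfg, out) {
  path <- require_artifact(file.path(out, "flux_summary.csv"), "flux")
  summ <- tibble::as_tibble(data.table::fread(path))
  cc <- cfg$community %||% list()
  density <- cc$cell_density %||% cell_density_from_bchla(
    cc$bchl_per_g_sediment %||% 0.2987,
    cc$bchl_per_C %||% 0.01991,
    cc$C_per_cell_fg %||% 20
  )
  pick <- function(tr) {
    x <- summ$mean_mass_flux[summ$treatment == tr & summ$element == "C"]
    if (length(x) == 0) NA_real_ else x
  }
  light_f <- pick("CO3L"); dark_f <- pick("CO3D")
  if (is.na(light_f) || is.na(dark_f)) {
    stop("flux summary lacks CO3L/CO3D carbon fluxes; run the 'flux' stage first",
      call. = FALSE
    )
  }
  rate <- community_rate(light_f, dark_f, density)
  res <- tibble::tibble(
    cell_density = density,
    mean_CO3L_flux_fg = light_f,
    mean_CO3D_flux_fg = dark_f,
    rate_g_per_g_h = rate$rate_g_per_g_h,
    floored = rate$floored,
    chamber_rate_g_per_g_h = if (!is.null(cc$chamber_flux_mgC_m2_h)) {
      chamber_to_per_gram(
        cc$chamber_flux_mgC_m2_h,
        cc$depth_cm %||% 0.1, cc$sediment_density %||% 1
      )
    } else {
      NA_real_
    }
  )
  list(community = write_result_csv(res, file.path(out, "community.csv")))
}
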