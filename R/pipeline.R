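#' Pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: physical and
#' chemical constants, stage toggles and the simulation settings of the
#' all-synthetic demonstration run. Any element can be overridden; the
#' defaults reproduce the standard two-arm exposure study end to end.
#'
#' @param half_life_days Radionuclide half-life (days).
#' @param s_medium Medium -> cell S-value, Gy mL/(Bq s); `NULL` means the
#'   calibrated default.
#' @param s_cytoplasm Cytoplasm -> nucleus S-value, Gy/(Bq s).
#' @param cytoplasm_volume_um3 Assumed cytoplasm volume.
#' @param total_ag,total_cl Speciation totals (mol/L).
#' @param doses_Gy Dose ladder for planning and simulation.
#' @param exposure_days Exposure arms (days).
#' @param arm_params Per-arm LQ truth for the simulated colonies, named by
#'   exposure time.
#' @param rbe_reference `list(alpha =, beta =)` of the reference-radiation
#'   LQ curve used for RBE (default: a cobalt-60 photon curve).
#' @param sf_endpoints Surviving-fraction endpoints for RBE.
#' @param imaging `list(n_nuclei, foci_per_nucleus, focus_amplitude,
#'   mn_frequency, axis_range)` for the synthetic micrograph stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("plan", "speciate", "clonogenic", "imaging")`.
#' @param seed Integer seed controlling all synthetic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(half_life_days = 7.45,
                            s_medium = NULL,
                            s_cytoplasm = 0.075e-3,
                            cytoplasm_volume_um3 = 1000,
                            total_ag = 1.23e-7,
                            total_cl = 2.46e-1,
                            doses_Gy = c(0.5, 1, 2, 4),
                            exposure_days = c(4, 6),
                            arm_params = list(
                              "4" = list(alpha = 0.4, beta = 0.03),
                              "6" = list(alpha = 0.5, beta = 0.04)
                            ),
                            rbe_reference = list(alpha = 0.12, beta = 0.06),
                            sf_endpoints = 0.1,
                            imaging = list(
                              n_nuclei = 40, axis_range = c(12, 15),
                              foci_per_nucleus = 4, focus_amplitude = 10,
                              mn_frequency = 0.1
                            ),
                            stages = c("plan", "speciate", "clonogenic",
                                       "imaging"),
                            seed = 1) {
  stages <- match.arg(stages, c("plan", "speciate", "clonogenic", "imaging"),
                      several.ok = TRUE)
  structure(
    list(
      half_life_days = half_life_days, s_medium = s_medium,
      s_cytoplasm = s_cytoplasm,
      cytoplasm_volume_um3 = cytoplasm_volume_um3,
      total_ag = total_ag, total_cl = total_cl,
      doses_Gy = doses_Gy, exposure_days = exposure_days,
      arm_params = arm_params, rbe_reference = rbe_reference,
      sf_endpoints = sf_endpoints, imaging = imaging,
      stages = stages, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys follow the arguments of [pipeline_config()]; missing keys fall
#' back to the defaults. An empty `stages:` list disables every stage.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("Config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("Unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # "stages: []" must disable everything, not fall back to the default
  if (!is.null(raw$stages) && length(raw$stages) == 0) {
    raw$stages <- character()
    cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "stages")])
    cfg$stages <- character()
    return(cfg)
  }
  do.call(pipeline_config, raw)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic inputs (or
#' a supplied colony table) and assembles a machine-readable report:
#'
#' 1. `plan` — exposure plans (activity concentration per dose and arm);
#' 2. `speciate` — Ag-Cl speciation of the administered solution;
#' 3. `clonogenic` — simulate or ingest colony counts, reduce to surviving
#'    fractions, fit the LQ model per arm, compute RBE at the requested
#'    endpoints against the reference curve;
#' 4. `imaging` — synthetic micrograph pair, nucleus segmentation, foci
#'    counts and grouping, micronucleus frequency.
#'
#' The run is deterministic for a fixed config and seed; the timestamp is
#' isolated in `report$provenance$timestamp` so reports can be compared
#' after dropping that one field. If a stage fails, previously completed
#' stage outputs are still written and the error names the failing stage.
#'
#' @param config A `pipeline_config`, or a path to a YAML/JSON config.
#' @param output_dir Directory for stage outputs (CSV) and the report
#'   (`report.json`, `report.md`); `NULL` skips writing.
#' @param colony_table Optional colony-count table (tibble or CSV path)
#'   used instead of the simulated one; must carry `dose_Gy`,
#'   `exposure_days`, `replicate`, `cells_seeded`, `colonies`.
#' @return The report, a list of class `analysis_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         colony_table = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  physics <- ag111_physics(config$half_life_days)
  s_medium <- if (is.null(config$s_medium)) {
    s_medium_calibrated(physics)
  } else {
    config$s_medium
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }

  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("radcell")),
    seed = config$seed,
    stages = config$stages,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  ))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if ("plan" %in% config$stages) {
    report$plan <- run_stage("plan", {
      plan <- plan_exposure(config$doses_Gy, config$exposure_days,
                            s_medium = s_medium, physics = physics)
      s_set <- s_value_set(medium = s_medium, cytoplasm = config$s_cytoplasm)
      list(
        exposure_plan = plan,
        s_medium = s_medium,
        internalization_excess = internalization_excess(
          config$cytoplasm_volume_um3, s_set, physics = physics
        ),
        cytoplasm_volume_um3 = config$cytoplasm_volume_um3,
        cytoplasm_volume_is_assumed = TRUE
      )
    })
    if (!is.null(output_dir)) {
      write_exposure_plan(report$plan$exposure_plan,
                          file.path(output_dir, "exposure_plan.csv"))
    }
  }

  if ("speciate" %in% config$stages) {
    report$speciation <- run_stage("speciate", {
      speciate_agcl(config$total_ag, config$total_cl)
    })
    if (!is.null(output_dir)) {
      utils::write.csv(report$speciation,
                       file.path(output_dir, "speciation.csv"),
                       row.names = FALSE)
    }
  }

  if ("clonogenic" %in% config$stages) {
    report$clonogenic <- run_stage("clonogenic", {
      colonies <- resolve_colony_table(config, colony_table, s_medium,
                                       physics)
      sf <- surviving_fraction(colonies, .data$exposure_days)
      # dish-level fit: calibrated uncertainties (see fit_lq_colonies)
      fits <- lapply(split(colonies, colonies$exposure_days), fit_lq_colonies)
      ref <- lq_params(config$rbe_reference$alpha, config$rbe_reference$beta)
      rbe_tbl <- tidyr::expand_grid(
        exposure_days = as.numeric(names(fits)),
        sf_endpoint = config$sf_endpoints
      )
      rbe_tbl$rbe <- purrr::map2_dbl(
        rbe_tbl$exposure_days, rbe_tbl$sf_endpoint,
        function(d, s) rbe(fits[[as.character(d)]], ref, s)
      )
      list(colonies = colonies, survival = sf,
           fits = lapply(fits, function(f) {
             c(as.list(tidyr::pivot_wider(
               tidy(f), names_from = "term",
               values_from = c("estimate", "std.error")
             )), bound_active = f$bound_active)
           }),
           fit_objects = fits, rbe = rbe_tbl)
    })
    if (!is.null(output_dir)) {
      utils::write.csv(report$clonogenic$survival,
                       file.path(output_dir, "survival.csv"),
                       row.names = FALSE)
      curves <- purrr::imap_dfr(report$clonogenic$fit_objects, function(f, d) {
        dplyr::mutate(survival_curve(f), exposure_days = as.numeric(d))
      })
      utils::write.csv(curves, file.path(output_dir, "survival_curves.csv"),
                       row.names = FALSE)
    }
  }

  if ("imaging" %in% config$stages) {
    report$imaging <- run_stage("imaging", {
      im_cfg <- config$imaging
      pair <- generate_image_pair(
        n_nuclei = im_cfg$n_nuclei,
        axis_range = im_cfg$axis_range %||% c(12, 15),
        foci_per_nucleus = im_cfg$foci_per_nucleus,
        focus_amplitude = im_cfg$focus_amplitude,
        mn_frequency = im_cfg$mn_frequency,
        seed = config$seed
      )
      masks <- segment_nuclei(pair$dapi)
      foci <- detect_foci(pair$focus, masks)
      mn <- detect_micronuclei(pair$dapi, masks)
      list(
        n_nuclei_planted = nrow(pair$truth$nuclei),
        n_nuclei_segmented = nrow(masks$nuclei),
        foci = foci,
        foci_groups = foci_group_distribution(foci),
        mn_frequency = mn_frequency(mn)
      )
    })
    if (!is.null(output_dir)) {
      utils::write.csv(report$imaging$foci,
                       file.path(output_dir, "foci.csv"), row.names = FALSE)
    }
  }

  report <- structure(report, class = "analysis_report")
  if (!is.null(output_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report_to_markdown(report),
               file.path(output_dir, "report.md"))
  }
  report
}

resolve_colony_table <- function(config, colony_table, s_medium, physics) {
  if (is.null(colony_table)) {
    ds <- generate_exposure_dataset(
      doses_Gy = config$doses_Gy, exposure_days = config$exposure_days,
      arm_params = config$arm_params, s_medium = s_medium,
      physics = physics, seed = config$seed
    )
    return(ds$colonies)
  }
  tbl <- if (is.character(colony_table)) {
    tibble::as_tibble(utils::read.csv(colony_table))
  } else {
    tibble::as_tibble(colony_table)
  }
  required <- c("dose_Gy", "exposure_days", "replicate", "cells_seeded",
                "colonies")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("Colony table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_colony_table(tbl)
  tbl
}

config_hash <- function(config) {
  # deterministic digest of the config without external dependencies
  ser <- serialize(config[setdiff(names(config), "seed")], NULL, version = 2)
  sum(as.integer(ser) * (seq_along(ser) %% 997)) %% .Machine$integer.max
}

report_to_json <- function(report) {
  strip <- unclass(report)
  if (!is.null(strip$clonogenic)) strip$clonogenic$fit_objects <- NULL
  strip
}

report_to_markdown <- function(report) {
  lines <- c("# Analysis report", "",
             sprintf("- package: radcell %s",
                     report$provenance$package_version),
             sprintf("- seed: %d", report$provenance$seed),
             sprintf("- stages: %s",
                     paste(report$provenance$stages, collapse = ", ")),
             sprintf("- timestamp: %s", report$provenance$timestamp), "")
  if (!is.null(report$plan)) {
    lines <- c(lines, "## Exposure plan", "",
               utils::capture.output(print.data.frame(
                 as.data.frame(report$plan$exposure_plan))),
               "",
               sprintf(paste0("Cytoplasm-internalization excess: %.4f%% ",
                              "(assumed cytoplasm volume %g um^3)"),
                       100 * report$plan$internalization_excess,
                       report$plan$cytoplasm_volume_um3), "")
  }
  if (!is.null(report$speciation)) {
    s <- report$speciation
    lines <- c(lines, "## Speciation", "",
               sprintf("- AgCl2-: %.1f%%, AgCl: %.1f%%, free Ag+: %.2g%%",
                       100 * s$fraction_agcl2, 100 * s$fraction_agcl,
                       100 * s$fraction_free_ag),
               sprintf("- ion product %.3g M^2; saturated: %s",
                       s$ion_product, s$saturated), "")
  }
  if (!is.null(report$clonogenic)) {
    lines <- c(lines, "## Clonogenic fits", "")
    for (d in names(report$clonogenic$fits)) {
      f <- report$clonogenic$fits[[d]]
      lines <- c(lines, sprintf(
        "- %s d arm: alpha = %.3f +/- %.3f Gy^-1, beta = %.3f +/- %.3f Gy^-2%s",
        d, f$estimate_alpha, f$std.error_alpha, f$estimate_beta,
        f$std.error_beta,
        if (isTRUE(f$bound_active)) " (beta bound active)" else ""
      ))
    }
    lines <- c(lines, "", "RBE vs reference:",
               utils::capture.output(print.data.frame(
                 as.data.frame(report$clonogenic$rbe))), "")
  }
  if (!is.null(report$imaging)) {
    mnf <- report$imaging$mn_frequency
    lines <- c(lines, "## Imaging", "",
               sprintf("- nuclei: %d segmented / %d planted",
                       report$imaging$n_nuclei_segmented,
                       report$imaging$n_nuclei_planted),
               sprintf("- micronucleus frequency: %.3f +/- %.3f (n = %d)",
                       mnf$frequency, mnf$se, mnf$n_cells), "")
  }
  lines
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(report_to_markdown(x), sep = "\n")
  invisible(x)
}
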