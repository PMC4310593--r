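# allowed config keys per section; unknown keys are rejected by name
config_schema <- list(
  top = c("schema_version", "seed", "output_dir", "phantom", "boundary",
          "enface", "cohort", "trace", "morphometry", "grid", "inputs"),
  phantom = c("fov_width", "fov_depth", "px_lateral", "px_axial",
              "keratin_thickness", "intensity_keratin",
              "intensity_epithelium", "intensity_lamina_af",
              "intensity_lamina_shg", "intensity_cytoplasm",
              "intensity_nucleus", "noise_gaussian_sd",
              "noise_poisson_scale", "texture_strength", "texture_scale",
              "render_nuclei", "bit_depth"),
  boundary = c("baseline_depth", "sine_amplitude", "sine_period", "bumps",
               "roughness_sd"),
  enface = c("density", "nucleus_diameter", "fov"),
  cohort = c("modality", "per_grade", "n_reps"),
  trace = c("threshold_method", "manual_level", "sigma", "low", "high",
            "jump", "epsilon", "max_gap", "smooth", "smooth_halfwidth"),
  morphometry = c("surface_threshold", "n_sites", "scale_range"),
  grid = c("n_normal", "n_dysplastic"),
  inputs = c("tiff", "sidecar", "cohort_csv")
)

check_keys <- function(x, section) {
  allowed <- config_schema[[section]]
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("config error: unknown key `", unknown[1], "` in ",
         if (section == "top") "config" else paste0("section `", section, "`"))
  }
  x
}

#' Read and validate a run configuration
#'
#' Loads a YAML or JSON configuration (by file extension) or validates an
#' in-memory list. Unknown keys anywhere in the configuration are rejected
#' by name, and every run must carry an integer `seed` so that stochastic
#' stages are reproducible.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return The validated configuration list, class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config error: file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      stop("config error: unrecognized config extension (use .yaml/.json)")
    }
  }
  if (!is.list(config)) stop("config error: configuration must be a mapping")
  check_keys(config, "top")
  for (section in intersect(names(config), names(config_schema))) {
    if (section %in% c("boundary")) {
      check_keys(config[[section]], section)
    } else if (is.list(config[[section]])) {
      check_keys(config[[section]], section)
    }
  }
  if (is.null(config$seed)) {
    stop("config error: a `seed` is required for every run")
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = c("run_config", "list"))
}

config_boundary <- function(cfg) {
  b <- cfg$boundary
  if (is.null(b)) stop("config error: `boundary` section required")
  bumps <- if (!is.null(b$bumps)) {
    do.call(rbind, lapply(b$bumps, as.data.frame))
  }
  boundary_model(
    baseline_depth = b$baseline_depth,
    sine_amplitude = b$sine_amplitude %||% 0,
    sine_period = b$sine_period %||% NA_real_,
    bumps = bumps,
    roughness_sd = b$roughness_sd %||% 0
  )
}

config_params <- function(cfg, seed = cfg$seed) {
  args <- cfg$phantom %||% list()
  args$rng_seed <- seed
  do.call(phantom_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_run <- function(dir, subcommand, cfg, outputs) {
  outputs <- basename(outputs)   # logs must not depend on the target path
  lines <- c(
    paste0("ectishape ", as.character(utils::packageVersion("ectishape"))),
    paste0("subcommand: ", subcommand),
    paste0("seed: ", cfg$seed),
    paste0("outputs: ", paste(outputs, collapse = ", "))
  )
  writeLines(lines, file.path(dir, "run-log.txt"))
  jsonlite::write_json(
    list(package = "ectishape",
         version = as.character(utils::packageVersion("ectishape")),
         subcommand = subcommand, seed = cfg$seed,
         config = unclass(cfg), outputs = outputs),
    file.path(dir, "run-log.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

# deterministic phantom grid emulating a small imaging session:
# near-flat interfaces for normal sites, rete-ridged ones for dysplasia
grid_models <- function(n_normal, n_dysplastic, baseline, fov_width = 320) {
  norm <- lapply(seq_len(n_normal), function(i) {
    boundary_model(baseline, sine_amplitude = 1 + 0.4 * i,
                   sine_period = 90 + 10 * i)
  })
  dys <- lapply(seq_len(n_dysplastic), function(i) {
    boundary_model(
      baseline,
      sine_amplitude = 8 + 3 * i, sine_period = 60 + 5 * i,
      bumps = data.frame(center = c(0.3, 0.7) * fov_width,
                         amplitude = c(10 + 2 * i, 8 + 3 * i),
                         width = c(9, 12)))
  })
  list(normal = norm, dysplasia = dys)
}

#' Run a pipeline subcommand
#'
#' Drives the pipeline end to end from a single configuration:
#' \describe{
#'   \item{`simulate-phantom`}{render one phantom and write TIFF + ground
#'     truth sidecar (`phantom.tif`/`.json`).}
#'   \item{`simulate-cohort`}{draw a per-site cohort and write
#'     `cohort.csv`.}
#'   \item{`trace`}{read a phantom TIFF pair, run the extraction chain, and
#'     write `trace.csv` + `metrics.json`.}
#'   \item{`morphometry`}{as `trace`, plus surface detection and epithelial
#'     thickness appended to the metrics record.}
#'   \item{`stats`}{read a cohort CSV and write `group_summary.csv`,
#'     `tukey.csv`, `roc_points.csv` and `stats-metrics.json`.}
#'   \item{`all`}{phantom grid -> traces -> measured cohort CSV -> stats,
#'     all under one seed.}
#' }
#' Every run writes `run-log.txt` and `run-log.json` (parameters, seed,
#' package version) into the output directory; outputs are byte-identical
#' across runs with the same configuration.
#'
#' @param config Path to a YAML/JSON config or a named list
#'   (see [read_run_config()]).
#' @param subcommand One of the subcommands above.
#' @param output_dir Overrides `output_dir` from the config (default
#'   `"ectishape-out"`).
#' @return Invisibly, a named character vector of the files written.
#' @export
run_pipeline <- function(config,
                         subcommand = c("all", "simulate-phantom",
                                        "simulate-cohort", "trace",
                                        "morphometry", "stats"),
                         output_dir = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- read_run_config(config)
  dir <- output_dir %||% cfg$output_dir %||% "ectishape-out"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr_cfg <- cfg$trace %||% list()
  mo_cfg <- cfg$morphometry %||% list()

  run_trace_on <- function(section) {
    measure_ecti(
      section,
      threshold_method = tr_cfg$threshold_method %||% "otsu",
      manual_level = tr_cfg$manual_level,
      sigma = tr_cfg$sigma %||% 1.5, low = tr_cfg$low %||% 0.2,
      high = tr_cfg$high %||% 0.5, jump = tr_cfg$jump %||% 15,
      epsilon = tr_cfg$epsilon %||% 0.01,
      max_gap = tr_cfg$max_gap %||% 20,
      smooth = tr_cfg$smooth %||% TRUE,
      smooth_halfwidth = tr_cfg$smooth_halfwidth %||% 1)
  }

  outputs <- switch(subcommand,
    "simulate-phantom" = {
      ph <- render_phantom(config_params(cfg), config_boundary(cfg))
      write_phantom(ph, file.path(dir, "phantom"))
      c(tif = file.path(dir, "phantom.tif"),
        json = file.path(dir, "phantom.json"))
    },
    "simulate-cohort" = {
      co_cfg <- cfg$cohort %||% list()
      specs <- default_cohort_specs(co_cfg$modality %||% "imaging",
                                    per_grade = isTRUE(co_cfg$per_grade))
      coh <- sample_cohort(specs, seed = cfg$seed,
                           modality = co_cfg$modality %||% "imaging")
      write_cohort_csv(coh, file.path(dir, "cohort.csv"))
      c(cohort = file.path(dir, "cohort.csv"))
    },
    "trace" = ,
    "morphometry" = {
      inp <- cfg$inputs
      if (is.null(inp$tiff)) {
        stop("config error: `inputs.tiff` required for this subcommand")
      }
      section <- read_cross_section(inp$tiff, sidecar = inp$sidecar)
      tr <- run_trace_on(section)
      extra <- NULL
      if (subcommand == "morphometry") {
        surf <- detect_surface(section,
                               mo_cfg$surface_threshold %||% 0.2)
        th <- epithelial_thickness(surf, tr, mo_cfg$n_sites %||% 4L)
        extra <- list(thickness_um = th$mean_um)
      }
      write_trace(tr, file.path(dir, "trace.csv"),
                  file.path(dir, "metrics.json"), seed = cfg$seed,
                  extra = extra)
      c(trace = file.path(dir, "trace.csv"),
        metrics = file.path(dir, "metrics.json"))
    },
    "stats" = {
      path <- cfg$inputs$cohort_csv %||% file.path(dir, "cohort.csv")
      coh <- read_cohort_csv(path)
      write_stats_outputs(coh, dir)
    },
    "all" = {
      g_cfg <- cfg$grid %||% list()
      models <- grid_models(g_cfg$n_normal %||% 3L,
                            g_cfg$n_dysplastic %||% 3L,
                            (cfg$boundary %||% list())$baseline_depth %||% 60,
                            (cfg$phantom %||% list())$fov_width %||% 320)
      rows <- list(); k <- 0L
      for (grp in names(models)) {
        for (i in seq_along(models[[grp]])) {
          k <- k + 1L
          params <- config_params(cfg, seed = cfg$seed + k)
          ph <- render_phantom(params, models[[grp]][[i]])
          prefix <- file.path(dir, sprintf("phantom-%s-%02d", grp, i))
          write_phantom(ph, prefix)
          tr <- run_trace_on(ph$section)
          surf <- detect_surface(ph$section,
                                 mo_cfg$surface_threshold %||% 0.2)
          th <- epithelial_thickness(surf, tr, mo_cfg$n_sites %||% 4L)
          write_trace(tr, paste0(prefix, "-trace.csv"),
                      paste0(prefix, "-metrics.json"),
                      seed = cfg$seed + k,
                      extra = list(thickness_um = th$mean_um))
          rows[[k]] <- data.frame(
            site_id = sprintf("%s-%02d", grp, i), group = grp,
            modality = "imaging", delta_linearity = tr$delta_L_norm,
            thickness_um = th$mean_um)
        }
      }
      coh <- do.call(rbind, rows)
      write_cohort_csv(coh, file.path(dir, "cohort.csv"))
      c(cohort = file.path(dir, "cohort.csv"),
        write_stats_outputs(coh, dir))
    }
  )
  log_run(dir, subcommand, cfg, outputs)
  invisible(outputs)
}

# group summaries, pairwise tests, ROC table and metrics for a cohort
write_stats_outputs <- function(coh, dir) {
  gs <- group_summary(coh$delta_linearity, coh$group)
  write.csv(gs, file.path(dir, "group_summary.csv"), row.names = FALSE)
  gl <- split(coh$delta_linearity, coh$group)
  outputs <- c(summary = file.path(dir, "group_summary.csv"))
  if (length(gl) >= 2L && all(lengths(gl) >= 2L)) {
    tk <- tukey_hsd(gl)
    write.csv(tk, file.path(dir, "tukey.csv"), row.names = FALSE)
    av <- one_way_anova(gl)
    pos <- coh$group != "normal"
    roc <- empirical_roc(coh$delta_linearity, pos)
    write.csv(roc$points, file.path(dir, "roc_points.csv"),
              row.names = FALSE)
    op <- operating_point(roc, "youden")
    jsonlite::write_json(
      list(schema = "ectishape-stats/1",
           anova_F = av$F, anova_p = av$p,
           auc = roc$auc, cutoff = op$cutoff,
           sensitivity_pct = op$sensitivity_pct,
           specificity_pct = op$specificity_pct,
           rates = as.list(op$rates)),
      file.path(dir, "stats-metrics.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    outputs <- c(outputs,
                 tukey = file.path(dir, "tukey.csv"),
                 roc = file.path(dir, "roc_points.csv"),
                 metrics = file.path(dir, "stats-metrics.json"))
  }
  outputs
}
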