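# Batch orchestration: configuration handling, the simulate -> static ->
# kinematics -> ploidy -> compare pipeline, output tables and the run
# manifest.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out = NULL,
    cohorts = list(
      list(name = "WT",
           n_roots = 6L,
           spec = list(meristem_length = 500, initial_cell_length = 10,
                       meristem_strain_rate = 0.04,
                       elongation_zone_length = 400,
                       elongation_strain_integral = 280,
                       bump_shape = "raised_cosine"))
    ),
    particles = list(n_per_root = 40L, dt = 1, position_noise_sd = 5),
    cell_files = list(length_cv = 0.05, qc_offset = 0),
    ploidy_sim = NULL,
    static_profile = list(tol = 0.05, median_filter = FALSE),
    kinematics = list(bandwidth = 50, grid_step = 1, plateau_frac = 0.95),
    ploidy = list(anchor = NULL, min_intensity = NULL, max_intensity = NULL),
    compare = list(metrics = c("P_cells_per_h", "mature_len_um"))
  )
}

#' Read and validate a pipeline configuration
#'
#' Configurations are flat YAML with per-stage sections; unknown top-level
#' keys are rejected by name. Missing sections fall back to package defaults.
#' A run manifest (which embeds the config it ran with) is also accepted, so
#' a run can be reproduced from its manifest alone.
#'
#' @param config Path to a YAML/JSON file, or a config list.
#' @return The merged, validated config list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    stop_rootkin("`config` must be a file path or a list", "rootkin_error_config")
  }
  if (!is.null(config$config)) config <- config$config # a manifest
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop_rootkin(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
                 "rootkin_error_config")
  }
  merged <- defaults
  for (nm in names(config)) merged[[nm]] <- config[[nm]]
  merged
}

cohort_spec <- function(cohort) {
  do.call(growth_zone_spec, cohort$spec)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> static-profile -> kinematics -> ploidy -> compare as
#' configured, writes all output tables to `out` and a `manifest.json`
#' recording the config, seed, package version and rule-interpretation flags.
#' Identical seeds reproduce byte-identical outputs.
#'
#' @param config Path to a YAML config, a config list, or a manifest (see
#'   [read_config()]).
#' @param seed Overrides the config seed.
#' @param out Output directory (overrides the config `out`).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the result tibbles and output paths.
#' @export
run_pipeline <- function(config, seed = NULL, out = NULL, verbose = FALSE) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out)) cfg$out <- out
  if (is.null(cfg$out)) {
    stop_rootkin("no output directory: set `out`", "rootkin_error_config")
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (verbose) message("[rootkin] ", sprintf(...))

  # -- simulate ----------------------------------------------------------
  log_stage("simulate: %d cohort(s), seed %s", length(cfg$cohorts), cfg$seed)
  particles <- list()
  cell_files <- list()
  truth <- list()
  for (ci in seq_along(cfg$cohorts)) {
    cohort <- cfg$cohorts[[ci]]
    spec <- cohort_spec(cohort)
    sim <- simulate_cohort(
      spec,
      n_roots = cohort$n_roots,
      particles_per_root = cfg$particles$n_per_root,
      dt = cfg$particles$dt,
      position_noise_sd = cfg$particles$position_noise_sd,
      length_cv = cfg$cell_files$length_cv,
      qc_offset = cfg$cell_files$qc_offset,
      seed = sub_seed(cfg$seed, ci, 10L),
      genotype = cohort$name
    )
    particles[[ci]] <- sim$particles
    cell_files[[ci]] <- sim$cell_files
    truth[[cohort$name]] <- c(unclass(spec), as.list(glance(spec)))
  }
  particles <- dplyr::bind_rows(particles)
  cell_files <- dplyr::bind_rows(cell_files)
  readr::write_csv(dplyr::select(particles, "root_id", "x_start_um",
                                 "x_end_um", "dt_h"),
                   file.path(cfg$out, "particles.csv"))
  readr::write_csv(dplyr::select(cell_files, "root_id", "file_side",
                                 "cell_index", "length_um", "qc_offset_um"),
                   file.path(cfg$out, "cellfile.csv"))
  jsonlite::write_json(truth, file.path(cfg$out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  ploidy_nuclei <- NULL
  if (!is.null(cfg$ploidy_sim)) {
    ps <- cfg$ploidy_sim
    sims <- list()
    for (gi in seq_along(ps$proportions)) {
      geno <- names(ps$proportions)[gi]
      for (si in seq_len(ps$samples_per_group)) {
        sims[[length(sims) + 1L]] <- simulate_ploidy(
          unlist(ps$proportions[[gi]]), n = ps$n_nuclei, anchor = ps$anchor,
          cv = ps$cv, seed = sub_seed(cfg$seed, si, 100L + gi),
          sample_id = sprintf("%s_s%02d", geno, si), genotype = geno
        )
      }
    }
    ploidy_nuclei <- dplyr::bind_rows(sims)
    readr::write_csv(dplyr::select(ploidy_nuclei, "sample_id", "genotype",
                                   "intensity"),
                     file.path(cfg$out, "ploidy.csv"))
  }

  # -- static profile ----------------------------------------------------
  log_stage("static-profile: %d files", dplyr::n_distinct(
    paste(cell_files$root_id, cell_files$file_side)))
  seg <- segment_cell_file(cell_files, tol = cfg$static_profile$tol,
                           qc_offset = cfg$cell_files$qc_offset,
                           median_filter = cfg$static_profile$median_filter)
  static_summary <- summarize_seedling(seg) %>%
    dplyr::rename(meristem_cells = "meristem_cells")
  readr::write_csv(static_summary, file.path(cfg$out, "static_summary.csv"))

  # -- kinematics --------------------------------------------------------
  log_stage("kinematics: %d roots", dplyr::n_distinct(particles$root_id))
  kin <- analyze_kinematics(
    particles, cell_files,
    bandwidth = cfg$kinematics$bandwidth,
    grid_step = cfg$kinematics$grid_step,
    plateau_frac = cfg$kinematics$plateau_frac,
    tol = cfg$static_profile$tol,
    qc_offset = cfg$cell_files$qc_offset
  )
  genotype_of <- dplyr::distinct(particles, .data$root_id, .data$genotype)
  kin_summary <- dplyr::select(kin, -"fit") %>%
    dplyr::left_join(genotype_of, by = "root_id")
  readr::write_csv(kin_summary, file.path(cfg$out, "kinematics_summary.csv"))
  profiles <- kinematic_profiles(kin) %>%
    dplyr::select("root_id", "x_um", "v_um_per_h", "flux_per_h", "regr_per_h")
  readr::write_csv(profiles, file.path(cfg$out, "regr_profile.csv"))

  # -- ploidy ------------------------------------------------------------
  ploidy_props <- NULL
  ploidy_tests <- NULL
  if (!is.null(ploidy_nuclei)) {
    log_stage("ploidy: %d samples", dplyr::n_distinct(ploidy_nuclei$sample_id))
    ploidy_props <- ploidy_proportions(
      dplyr::select(ploidy_nuclei, "sample_id", "genotype", "intensity"),
      anchor = cfg$ploidy$anchor,
      estimate_anchor = is.null(cfg$ploidy$anchor),
      min_intensity = cfg$ploidy$min_intensity,
      max_intensity = cfg$ploidy$max_intensity
    )
    readr::write_csv(ploidy_props, file.path(cfg$out, "ploidy_proportions.csv"))
    if (length(unique(ploidy_props$genotype)) == 2L) {
      ploidy_tests <- compare_ploidy(ploidy_props)
      readr::write_csv(ploidy_tests, file.path(cfg$out, "ploidy_tests.csv"))
    }
  }

  # -- compare -----------------------------------------------------------
  group_tests <- NULL
  if (length(unique(kin_summary$genotype)) == 2L &&
      length(cfg$compare$metrics) > 0) {
    log_stage("compare: %s", paste(cfg$compare$metrics, collapse = ", "))
    group_tests <- dplyr::bind_rows(
      lapply(cfg$compare$metrics, function(m) compare_groups(kin_summary, m))
    )
    readr::write_csv(group_tests, file.path(cfg$out, "group_tests.csv"))
  }

  manifest <- list(
    package = "rootkin",
    version = as.character(utils::packageVersion("rootkin")),
    seed = cfg$seed,
    interpretation = list(
      plateau_candidate_excluded_from_remaining_mean = TRUE,
      t_test_variant = "welch",
      boundary_resolution = "grid (no sub-grid interpolation)"
    ),
    config = cfg
  )
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(
    particles = particles, cell_files = cell_files,
    static_summary = static_summary, kinematics = kin_summary,
    profiles = profiles, ploidy_proportions = ploidy_props,
    ploidy_tests = ploidy_tests, group_tests = group_tests,
    out = cfg$out
  ))
}
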