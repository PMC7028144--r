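# End-to-end kinematic analysis of one root or a batch of roots: velocity
# profile, zone boundaries, cell production, cell-cycle duration, REGR
# profile and elongation-zone transit time.

#' Kinematic analysis of a single root
#'
#' Runs the full kinematic pipeline on one root's particle displacements and
#' its paired cortical cell file(s): velocity-profile estimation, growth-zone
#' and meristem boundaries (95%-of-plateau rules on velocity and flux), cell
#' production `P = V / l_mature`, meristem cell number, cell-cycle duration
#' `Tc = ln(2) N / P`, REGR profile and elongation-zone transit time.
#'
#' The meristem cell number is kinematic, as in the underlying framework:
#' the number of cells of the paired file whose midpoints lie within the
#' flux-determined meristem boundary (falling back to the static
#' doubling-rule count when no boundary is available). The mature cell
#' length comes from the static segmentation of the paired cell file
#' ([segment_cell_file()], averaged over files of the root); when the
#' segmentation rules cannot be applied the mean of the first five cells
#' lying wholly beyond the growth-zone boundary is used instead, and noted.
#'
#' Boundary failures (for example a root whose particles all sit in the
#' plateau) leave the affected quantities `NA` and are reported in `notes`
#' rather than raised, so batch analyses never abort on one root.
#'
#' @param particles Data frame of one root's particle records
#'   (`x_start_um`, `x_end_um`, `dt_h`).
#' @param cell_files Data frame of the root's cortical cell file(s)
#'   (`root_id`, `file_side`, `cell_index`, `length_um`, optionally
#'   `qc_offset_um`).
#' @param bandwidth,grid_step Velocity-fit controls, um
#'   (see [estimate_velocity_profile()]).
#' @param plateau_frac Plateau threshold fraction for both boundary rules.
#' @param tol Maturation-rule tolerance for the static segmentation.
#' @param qc_offset Default QC offset (um) when the cell table has none.
#' @param root_id Label for the root (defaults to the one in `particles`).
#' @return An object of class `kinematic_summary`; `glance()` gives the
#'   one-row scalar summary, `tidy()` the per-position profile table
#'   (velocity, flux, REGR).
#' @export
analyze_root_kinematics <- function(particles, cell_files,
                                    bandwidth = 50, grid_step = 1,
                                    plateau_frac = 0.95, tol = 0.05,
                                    qc_offset = 0, root_id = NULL) {
  if (is.null(root_id)) {
    root_id <- if ("root_id" %in% names(particles)) as.character(particles$root_id[1]) else "root"
  }
  notes <- character(0)
  note <- function(msg) notes <<- c(notes, msg)

  profile <- estimate_velocity_profile(particles, bandwidth, grid_step)
  grid <- profile$data$x_um
  v <- profile$data$v_um_per_h

  gz <- tryCatch(growth_zone_boundary(profile, plateau_frac), error = identity)
  if (inherits(gz, "error")) {
    note(paste0("growth-zone boundary: ", conditionMessage(gz)))
    lg <- NA_real_
    v_final <- max(v) # best available plateau proxy
  } else {
    lg <- gz$growth_zone_length_um
    v_final <- gz$final_velocity_um_per_h
  }

  # cell-length field: average the per-file interpolations where they overlap
  len_mat <- sapply(split(cell_files, cell_files$file_side), function(cf) {
    cell_length_on_grid(cf, grid, qc_offset)
  })
  len_grid <- rowMeans(as.matrix(len_mat), na.rm = TRUE)
  len_grid[!is.finite(len_grid)] <- NA_real_

  lm_hat <- tryCatch(meristem_boundary(profile, len_grid, plateau_frac),
                     error = identity)
  if (inherits(lm_hat, "error")) {
    note(paste0("meristem boundary: ", conditionMessage(lm_hat)))
    lm_hat <- NA_real_
  }

  # static anatomy of the paired cell file(s)
  seg <- segment_cell_file(cell_files, tol = tol, qc_offset = qc_offset)
  seedling <- summarize_seedling(seg)

  mature_len <- if (any(seg$segmented)) {
    seedling$mature_cell_length_um[1]
  } else {
    note("static segmentation failed for all files; mature length from cells beyond the growth-zone boundary")
    mature_length_fallback(cell_files, lg, qc_offset)
  }
  if (is.na(mature_len)) note("mature cell length unavailable")

  n_meristem <- if (!is.na(lm_hat)) {
    # kinematic count: cells of the file lying within the flux-determined
    # meristem boundary, as in the kinematic framework
    meristem_cell_count_kinematic(cell_files, lm_hat, qc_offset)
  } else if (any(seg$segmented)) {
    note("no kinematic meristem boundary; meristem cell number from the static doubling-rule count")
    seedling$meristem_cells[1]
  } else {
    NA_real_
  }

  production <- if (!is.na(mature_len) && mature_len > 0) {
    cell_production_rate(v_final, mature_len)
  } else {
    NA_real_
  }
  tc <- if (!is.na(n_meristem) && !is.na(production) && production > 0 && n_meristem >= 1) {
    cell_cycle_duration(n_meristem, production)
  } else {
    NA_real_
  }

  transit <- if (!is.na(lm_hat) && !is.na(lg) && lm_hat < lg) {
    tryCatch(elongation_transit_time(profile, lm_hat, lg),
             error = function(e) {
               note(paste0("transit time: ", conditionMessage(e)))
               NA_real_
             })
  } else {
    if (is.na(lm_hat) || is.na(lg)) NA_real_ else {
      note("transit time: boundaries out of order")
      NA_real_
    }
  }

  regr <- strain_rate_profile(profile)

  structure(
    list(
      root_id = root_id,
      profile = profile,
      grid_data = tibble::tibble(
        root_id = root_id,
        x_um = grid,
        v_um_per_h = v,
        cell_length_um = len_grid,
        flux_per_h = ifelse(is.na(len_grid), NA_real_, v / len_grid),
        regr_per_h = regr$regr_per_h
      ),
      static = seg,
      summary = tibble::tibble(
        root_id = root_id,
        Lm_um = lm_hat,
        Lg_um = lg,
        V_um_per_h = v_final,
        P_cells_per_h = production,
        N_meristem = n_meristem,
        Tc_h = tc,
        mature_len_um = mature_len,
        transit_h = transit,
        n_particles = nrow(particles),
        n_notes = length(notes)
      ),
      notes = notes
    ),
    class = "kinematic_summary"
  )
}

# mean of the first five cells lying wholly beyond the growth-zone boundary,
# averaged across the root's files
mature_length_fallback <- function(cell_files, lg, qc_offset) {
  if (is.na(lg)) return(NA_real_)
  per_file <- vapply(split(cell_files, cell_files$file_side), function(cf) {
    cf <- dplyr::arrange(cf, .data$cell_index)
    offset <- if ("qc_offset_um" %in% names(cf)) cf$qc_offset_um[1] else qc_offset
    starts <- offset + cumsum(cf$length_um) - cf$length_um
    beyond <- which(starts >= lg)
    if (length(beyond) == 0) return(NA_real_)
    mean(cf$length_um[beyond[seq_len(min(5L, length(beyond)))]])
  }, numeric(1))
  if (all(is.na(per_file))) NA_real_ else mean(per_file, na.rm = TRUE)
}

# cells whose midpoints lie within the kinematic meristem boundary,
# averaged across the root's files
meristem_cell_count_kinematic <- function(cell_files, lm_hat, qc_offset) {
  per_file <- vapply(split(cell_files, cell_files$file_side), function(cf) {
    cf <- dplyr::arrange(cf, .data$cell_index)
    offset <- if ("qc_offset_um" %in% names(cf)) cf$qc_offset_um[1] else qc_offset
    mids <- offset + cumsum(cf$length_um) - cf$length_um / 2
    sum(mids <= lm_hat)
  }, numeric(1))
  mean(per_file)
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf("<kinematic_summary> root %s\n", x$root_id))
  print(x$summary)
  if (length(x$notes) > 0) cat("notes:\n", paste0("  - ", x$notes, "\n"), sep = "")
  invisible(x)
}

#' @rdname analyze_root_kinematics
#' @param x A `kinematic_summary`.
#' @param ... Unused.
#' @export
glance.kinematic_summary <- function(x, ...) x$summary

#' @rdname analyze_root_kinematics
#' @export
tidy.kinematic_summary <- function(x, ...) x$grid_data

#' Batch kinematic analysis
#'
#' Applies [analyze_root_kinematics()] to every root present in the particle
#' table, pairing it with the matching rows of the cell-length table by
#' `root_id`. Per-root failures are captured in the `n_notes` column and the
#' `fit` list-column rather than aborting the batch.
#'
#' @inheritParams analyze_root_kinematics
#' @param particles Particle table for all roots (must contain `root_id`).
#' @param cell_files Cell-length table for all roots.
#' @return A tibble with one row per root (the [glance()] summary) and a
#'   `fit` list-column holding the full `kinematic_summary` objects.
#' @export
analyze_kinematics <- function(particles, cell_files,
                               bandwidth = 50, grid_step = 1,
                               plateau_frac = 0.95, tol = 0.05,
                               qc_offset = 0) {
  if (!"root_id" %in% names(particles)) {
    stop_rootkin("`particles` must contain a `root_id` column", "rootkin_error_schema")
  }
  roots <- unique(particles$root_id)
  fits <- purrr::map(roots, function(id) {
    cf <- dplyr::filter(cell_files, .data$root_id == id)
    if (nrow(cf) == 0) {
      stop_rootkin(paste0("no cell file for root ", id), "rootkin_error_schema")
    }
    analyze_root_kinematics(
      dplyr::filter(particles, .data$root_id == id), cf,
      bandwidth = bandwidth, grid_step = grid_step,
      plateau_frac = plateau_frac, tol = tol, qc_offset = qc_offset,
      root_id = as.character(id)
    )
  })
  out <- dplyr::bind_rows(purrr::map(fits, glance))
  out$fit <- fits
  out
}

#' Per-position profiles of a batch analysis
#'
#' Binds the `tidy()` profile tables (velocity, flux, REGR along the root) of
#' every fitted root in a batch result.
#'
#' @param results Output of [analyze_kinematics()].
#' @return A long tibble with `root_id`, `x_um`, `v_um_per_h`,
#'   `cell_length_um`, `flux_per_h`, `regr_per_h`.
#' @export
kinematic_profiles <- function(results) {
  dplyr::bind_rows(purrr::map(results$fit, tidy))
}
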