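# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_vline
#'   labs facet_wrap position_dodge theme_minimal
NULL

#' Plot a fitted velocity profile
#'
#' Raw midpoint velocities with the smoothed monotone fit.
#'
#' @param object A `velocity_profile` from [estimate_velocity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.velocity_profile <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x_um, y = .data$v_um_per_h)) +
    geom_point(data = object$points,
               aes(x = .data$mid_um, y = .data$v_um_per_h),
               colour = "grey50", size = 1) +
    geom_line(colour = "#1b7837", linewidth = 0.8) +
    labs(x = "Distance from QC (µm)", y = "Velocity (µm/h)") +
    theme_minimal()
}

#' Plot a kinematic analysis of one root
#'
#' Velocity, flux and REGR profiles with the estimated meristem and
#' growth-zone boundaries.
#'
#' @param object A `kinematic_summary` from [analyze_root_kinematics()].
#' @param ... Unused.
#' @return A ggplot with one facet per profile.
#' @export
autoplot.kinematic_summary <- function(object, ...) {
  long <- object$grid_data %>%
    dplyr::select("x_um", "v_um_per_h", "flux_per_h", "regr_per_h") %>%
    tidyr::pivot_longer(-"x_um", names_to = "profile", values_to = "value") %>%
    dplyr::mutate(profile = factor(.data$profile,
                                   levels = c("v_um_per_h", "flux_per_h", "regr_per_h"),
                                   labels = c("velocity (µm/h)",
                                              "flux (1/h)", "REGR (1/h)")))
  bounds <- tibble::tibble(
    boundary = c("meristem", "growth zone"),
    x = c(object$summary$Lm_um, object$summary$Lg_um)
  )
  ggplot(long, aes(x = .data$x_um, y = .data$value)) +
    geom_line(colour = "#1b7837") +
    geom_vline(data = bounds[!is.na(bounds$x), ],
               aes(xintercept = .data$x, linetype = .data$boundary),
               colour = "grey30") +
    facet_wrap(~profile, ncol = 1, scales = "free_y") +
    labs(x = "Distance from QC (µm)", y = NULL, linetype = NULL,
         title = paste("Root", object$root_id)) +
    theme_minimal()
}

#' Plot ploidy-class proportions by sample
#'
#' @param proportions Output of [ploidy_proportions()].
#' @return A ggplot of per-class proportions, grouped by genotype.
#' @export
plot_ploidy_proportions <- function(proportions) {
  long <- proportions %>%
    dplyr::select("sample_id", "genotype", dplyr::starts_with("p_")) %>%
    tidyr::pivot_longer(dplyr::starts_with("p_"),
                        names_to = "class", values_to = "proportion") %>%
    dplyr::mutate(class = factor(sub("^p_", "", .data$class),
                                 levels = ploidy_classes()))
  ggplot(long, aes(x = .data$class, y = .data$proportion,
                   fill = .data$genotype)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7,
             alpha = 0.85) +
    labs(x = "Ploidy class", y = "Proportion of nuclei", fill = NULL) +
    theme_minimal()
}
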