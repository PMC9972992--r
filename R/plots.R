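#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_contour geom_line
#'   geom_hline geom_vline labs scale_fill_viridis_c scale_fill_gradient2
#'   theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Phase/contour map of a parameter sweep
#'
#' For exposure-susceptibility sweeps: filled pathogen-density map with
#' contour lines at the scan's stored increment and a dashed line at the
#' competitive-release threshold `f*` (when defined). For interaction
#' sweeps: diverging map of the beneficial-resistance gradient with dashed
#' zero axes.
#'
#' @param object An `lv_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_scan <- function(object, ...) {
  axes <- attr(object, "axes")
  nm1 <- axes$axis1$name
  base <- attr(object, "base_params")
  if (nm1 == "A") {
    inc <- attr(object, "contour_increment")
    gg <- ggplot(object, aes(x = .data$A, y = .data$f)) +
      geom_raster(aes(fill = .data$P_star)) +
      geom_contour(aes(z = .data$P_star), binwidth = inc,
                   colour = "grey30", linewidth = 0.2) +
      scale_fill_viridis_c(name = "P*") +
      labs(x = "antibiotic exposure A",
           y = "commensal relative susceptibility f") +
      theme_minimal()
    if (base$alpha_pc > 0) {
      thr <- release_threshold_f(base)
      if (thr <= max(object$f)) {
        gg <- gg + geom_hline(yintercept = thr, linetype = "dashed",
                              colour = "white")
      }
    }
    gg
  } else {
    ggplot(object, aes(x = .data$alpha_pc, y = .data$alpha_cp)) +
      geom_raster(aes(fill = .data$dP_df)) +
      scale_fill_gradient2(name = "dP*/df", low = "blue", mid = "white",
                           high = "red") +
      geom_hline(yintercept = 0, linetype = "dashed") +
      geom_vline(xintercept = 0, linetype = "dashed") +
      labs(x = "effect of commensal on pathogen (alpha_pc)",
           y = "effect of pathogen on commensal (alpha_cp)") +
      theme_minimal()
  }
}

#' Time-course plot of a trajectory
#'
#' @param object An `lv_trajectory` object.
#' @param ... Unused.
#' @return A ggplot object with one line per state variable.
#' @export
autoplot.lv_trajectory <- function(object, ...) {
  tidy.lv_trajectory(object) |>
    ggplot(aes(x = .data$time, y = .data$density,
               colour = .data$species)) +
    geom_line() +
    labs(x = "time", y = "density") +
    theme_minimal()
}

#' Exposure-ladder plot (pathogen density vs time, coloured by exposure)
#'
#' @param object An `lv_ladder` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_ladder <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$P, colour = .data$A,
                     group = .data$A)) +
    geom_line() +
    scale_colour_viridis_c_safe() +
    labs(x = "time", y = "pathogen density",
         colour = "exposure A") +
    theme_minimal()
}

scale_colour_viridis_c_safe <- function() ggplot2::scale_colour_viridis_c()

#' Risk-decomposition plot
#'
#' Dashed per-class risk curves (pathogen, commensal, HGT when active) and
#' the solid total-risk curve, as functions of commensal susceptibility.
#'
#' @param object A `risk_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_profile <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("f", "pathogen_risk", "commensal_risk", "hgt_risk",
                  "total_risk") |>
    tidyr::pivot_longer(-"f", names_to = "component", values_to = "risk")
  if (all(object$hgt_risk == 0)) {
    long <- dplyr::filter(long, .data$component != "hgt_risk")
  }
  ggplot(long, aes(x = .data$f, y = .data$risk,
                   colour = .data$component,
                   linetype = .data$component == "total_risk")) +
    geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   guide = "none") +
    labs(x = "commensal relative susceptibility f", y = "infection risk",
         colour = NULL) +
    theme_minimal()
}
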