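#' Plot a chemical-shift-perturbation profile
#'
#' @param csps CSP tibble from [compute_csp()].
#' @param cfg A [csp_config()] supplying the active threshold line.
#' @return A ggplot object.
#' @export
plot_csp_profile <- function(csps, cfg = csp_config()) {
  ggplot2::ggplot(csps, ggplot2::aes(x = .data$residue, y = .data$csp)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$csp - .data$csp_error,
                                        ymax = .data$csp + .data$csp_error),
                           width = 0, colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = cfg$active_csp_threshold,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "residue", y = "CSP (ppm)") +
    ggplot2::theme_minimal()
}

#' Plot a PRE intensity-ratio profile
#'
#' @param profile Ratio tibble (columns `residue`, `ratio`, `ratio_error`).
#' @param threshold Restraint threshold line.
#' @return A ggplot object.
#' @export
plot_pre_profile <- function(profile, threshold = 0.2) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$ratio - .data$ratio_error, 0),
                                        ymax = pmin(.data$ratio + .data$ratio_error, 1)),
                           width = 0) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "I/I0") +
    ggplot2::theme_minimal()
}

#' Plot endpoint titration curves
#'
#' @param datasets List of `list(condition, curve)` entries (as from
#'   [gen_kinetic_data()]), or a single curve tibble.
#' @return A ggplot object.
#' @export
plot_titration <- function(datasets) {
  if (is.data.frame(datasets)) {
    datasets <- list(list(condition = list(construct = "curve"),
                          curve = datasets))
  }
  df <- bind_rows(lapply(datasets, function(d) {
    lab <- d$condition$construct
    if (!is.null(d$condition$pip2_mol_percent) &&
        d$condition$construct != "ZA") {
      lab <- paste0(lab, ifelse(d$condition$pip2_mol_percent > 0,
                                " +PIP2", " -PIP2"))
    }
    mutate(d$curve, assay = lab)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$fraction,
                                   colour = .data$assay)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "enzyme concentration (M)",
                  y = "fraction GTP hydrolyzed") +
    ggplot2::theme_minimal()
}
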