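# broom-style accessors and ggplot2 methods for run and result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the trajectory of a run
#'
#' @param x An `alveosim_run`.
#' @param ... Unused.
#' @returns The per-sweep trajectory tibble (time, mean diameter, mean
#'   coverage, per-species mean protein counts, dissolved fraction,
#'   concentration ratio, control-volume history).
#' @export
tidy.alveosim_run <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a run
#'
#' @param x An `alveosim_run`.
#' @param ... Unused.
#' @returns One-row tibble: scenario, particle spec, seed, elapsed time,
#'   stop reason, sweeps, deposited rows, final mean coverage and
#'   dissolved fraction.
#' @export
glance.alveosim_run <- function(x, ...) {
  tr <- x$trajectory
  n <- nrow(tr)
  tibble::tibble(
    scenario = x$config$scenario,
    enm_spec = x$config$enm_spec,
    seed = x$seed,
    n_particles = x$config$n_particles,
    elapsed_s = tr$time[n],
    sweeps = n - 1,
    stop_reason = x$stop_reason,
    n_deposited = nrow(x$deposited),
    final_mean_theta = tr$mean_theta[n],
    final_dissolved_fraction = tr$dissolved_fraction[n],
    final_conc_ratio = tr$conc_ratio[n]
  )
}

#' Plot a run trajectory
#'
#' @param object An `alveosim_run`.
#' @param what One of `"diameter"`, `"coverage"`, `"depth"`,
#'   `"dissolution"`, `"proteins"`, `"concentration"`.
#' @param ... Unused.
#' @returns A ggplot.
#' @export
autoplot.alveosim_run <- function(object,
                                  what = c("coverage", "diameter", "depth",
                                           "dissolution", "proteins",
                                           "concentration"),
                                  ...) {
  what <- match.arg(what)
  tr <- object$trajectory
  base <- function(y, lab) {
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data[[y]])) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = lab) +
      ggplot2::theme_minimal()
  }
  switch(what,
    coverage = base("mean_theta", "mean lipid coverage θ"),
    diameter = base("mean_d_nm", "mean diameter (nm)"),
    depth = base("mean_depth_frac", "mean fractional depth"),
    dissolution = base("dissolved_fraction", "dissolved core fraction"),
    concentration = base("conc_ratio", "concentration / initial"),
    proteins = {
      long <- tidyr::pivot_longer(
        tr[, c("time", "SP-A", "SP-B", "SP-C", "SP-D")],
        -"time", names_to = "species", values_to = "count"
      )
      ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$count,
                                         colour = .data$species)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (s)", y = "mean adsorbed molecules per particle") +
        ggplot2::theme_minimal()
    }
  )
}

#' Plot normalised sensitivity indices
#'
#' @param object A `sensitivity_result` from [local_sensitivity()].
#' @param ... Unused.
#' @returns A ggplot tile map of normalised indices (parameter x output).
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$output, y = .data$parameter,
                               fill = .data$Si_normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Si (normalised)") +
    ggplot2::theme_minimal()
}
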