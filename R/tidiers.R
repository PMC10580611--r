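#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Monte-Carlo experiment
#'
#' @param x An `abm_experiment`.
#' @param scale_factor Optional scale override.
#' @param ... Unused.
#' @return One row per metric with scaled mean and 90% credible interval.
#' @exportS3Method generics::tidy
tidy.abm_experiment <- function(x, scale_factor = NULL, ...) {
  out <- summarize_runs(x, scale_factor)
  tibble::as_tibble(unclass(out))
}

#' @exportS3Method generics::tidy
tidy.abm_summary <- function(x, ...) tibble::as_tibble(unclass(x))

#' One-line experiment overview
#'
#' @param x An `abm_experiment`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.abm_experiment <- function(x, ...) {
  s <- summarize_runs(x)
  tibble::tibble(
    scenario = x$meta$scenario, sensitivity = x$meta$sensitivity,
    n_runs = x$meta$n_runs, n_agents = x$meta$n_agents, years = x$meta$years,
    overdoses_mean = s$mean[s$metric == "overdoses"],
    fatal_mean = s$mean[s$metric == "fatal_overdoses"],
    diverted_users_mean = s$mean[s$metric == "diverted_users"]
  )
}

#' Plot cumulative fatal-overdose curves
#'
#' @param object An `abm_curves` tibble from [cumulative_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.abm_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$day / 365, y = .data$cumulative_fatal,
    colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Years", y = "Cumulative fatal opioid overdoses",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.abm_curves
#' @param curves An `abm_curves` tibble.
#' @export
plot_cumulative_curves <- function(curves) autoplot(curves)

#' @importFrom rlang .data
NULL

#' Export a population snapshot
#'
#' Writes one row per agent (id, use state, pain, desire, tolerance,
#' prescription and diversion flags) as CSV.
#'
#' @param pop Population tibble (e.g. `run$population` from a run with
#'   `keep_population = TRUE`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_population_csv <- function(pop, path) {
  cols <- c("agent_id", "use_state", "pain", "desire", "tolerance",
            "has_bupe_rx", "ever_bupe", "alive")
  utils::write.csv(pop[, cols], path, row.names = FALSE)
  invisible(path)
}
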