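#' Tidy study results
#'
#' `tidy()` returns the study's main result table; `glance()` a one-row
#' design overview.
#'
#' @param x A study object (`ser_study1` ... `ser_study4`).
#' @param ... Unused.
#' @return A tibble.
#' @name ser-tidiers
NULL

#' @rdname ser-tidiers
#' @exportS3Method generics::tidy
tidy.ser_study1 <- function(x, ...) x$summary

#' @rdname ser-tidiers
#' @exportS3Method generics::tidy
tidy.ser_study2 <- function(x, ...) x$distribution

#' @rdname ser-tidiers
#' @exportS3Method generics::tidy
tidy.ser_study3 <- function(x, ...) x$agent_summaries

#' @rdname ser-tidiers
#' @exportS3Method generics::tidy
tidy.ser_study4 <- function(x, ...) x$group_summary

#' @rdname ser-tidiers
#' @exportS3Method generics::glance
glance.ser_study1 <- function(x, ...) {
  tibble::tibble(study = "study1", n_conditions = nrow(x$conditions),
                 n_runs = x$n_runs, n_timesteps = x$n_timesteps,
                 burn_in = x$burn_in, master_seed = x$master_seed)
}

#' @rdname ser-tidiers
#' @exportS3Method generics::glance
glance.ser_study2 <- function(x, ...) {
  tibble::tibble(study = "study2", environment = x$environment$name,
                 n_runs = x$n_runs, n_timesteps = x$n_timesteps,
                 mean_final_ts_admi = x$distribution$mean_ts_admi,
                 mean_final_ts_riva = x$distribution$mean_ts_riva,
                 master_seed = x$master_seed)
}

#' @rdname ser-tidiers
#' @exportS3Method generics::glance
glance.ser_study3 <- function(x, ...) {
  s <- x$agent_summaries
  tibble::tibble(study = "study3", origin = x$origin, n_runs = x$n_runs,
                 n_timesteps = x$n_timesteps,
                 mean_se_median = mean(s$se_median),
                 mean_se_variance = mean(s$se_variance),
                 total_admiration = sum(s$n_admiration),
                 total_rivalry = sum(s$n_rivalry),
                 master_seed = x$master_seed)
}

#' @rdname ser-tidiers
#' @exportS3Method generics::glance
glance.ser_study4 <- function(x, ...) {
  tibble::tibble(study = "study4", n_groups = nrow(x$thresholds),
                 n_agents = sum(x$thresholds$n_agents),
                 n_timesteps = x$n_timesteps, master_seed = x$master_seed)
}

#' @export
print.ser_study <- function(x, ...) {
  g <- glance(x)
  cat("<", class(x)[1], "> ", sep = "")
  cat(paste0(names(g), " = ", unlist(lapply(g, format))), sep = ", ")
  cat("\n")
  invisible(x)
}
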