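#' Tidy a fitted population model
#'
#' @param x An `mtx_fit` from [fit_population()].
#' @param ... Unused.
#' @return Tibble with one row per population parameter (`term`,
#'   `estimate`, `init`).
#' @export
tidy.mtx_fit <- function(x, ...) {
  tibble::tibble(term = pop_names,
                 estimate = as.numeric(x$par),
                 init = as.numeric(x$init))
}

#' @rdname tidy.mtx_fit
#' @return For `glance()`: a one-row tibble with the objective value,
#'   data sizes, evaluation count and convergence flag.
#' @export
glance.mtx_fit <- function(x, ...) {
  tibble::tibble(objective = x$value, n_obs = x$n_obs,
                 n_patients = x$n_patients,
                 evaluations = unname(x$counts["function"]),
                 converged = x$convergence,
                 config_hash = x$config_hash)
}

#' Tidy a bootstrap summary
#'
#' @param x An `mtx_boot` from [bootstrap_population()].
#' @param ... Unused.
#' @return Tibble with per-parameter resampling `mean` and `sd`.
#' @export
tidy.mtx_boot <- function(x, ...) x$summary

#' @rdname tidy.mtx_boot
#' @export
glance.mtx_boot <- function(x, ...) {
  tibble::tibble(n_resamples = x$n_resamples, n_failed = x$n_failed,
                 seed = x$seed, config_hash = x$config_hash)
}

#' Tidy a simulated course
#'
#' @param x An `mtx_sim` from [simulate_course()].
#' @param ... Unused.
#' @return Long tibble: `time`, `compartment`, `amount_mg`,
#'   `conc_mg_per_ml`.
#' @export
tidy.mtx_sim <- function(x, ...) {
  tr <- x$trace
  comps <- c("cs", "rcs", "hcs", "isf", "icf")
  dplyr::bind_rows(lapply(comps, function(cp) {
    tibble::tibble(time = tr$time, compartment = cp,
                   amount_mg = tr[[paste0("m_", cp)]],
                   conc_mg_per_ml = tr[[paste0("c_", cp)]])
  }))
}

#' @rdname tidy.mtx_sim
#' @export
glance.mtx_sim <- function(x, ...) {
  tibble::as_tibble(x$audit)
}
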