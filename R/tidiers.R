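#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted GCA/SCA model
#'
#' One row per variance component.
#'
#' @param x A `ttc_gblup`.
#' @param ... Unused.
#' @return Tibble `component`, `estimate`.
#' @method tidy ttc_gblup
#' @export
tidy.ttc_gblup <- function(x, ...) {
  tibble::tibble(component = names(x$sigma2), estimate = unname(x$sigma2))
}

#' Glance at a fitted GCA/SCA model
#'
#' @param x A `ttc_gblup`.
#' @param ... Unused.
#' @return One-row tibble: `trait`, `n`, `h2`, `H2`, `logLik`,
#'   `iterations`, `converged`.
#' @method glance ttc_gblup
#' @export
glance.ttc_gblup <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(trait = x$trait, n = x$n), heritability(x),
                   tibble::tibble(logLik = x$logLik, iterations = x$iterations,
                                  converged = x$converged))
}

#' Tidy cross-validation results
#'
#' @param x A `ttc_cv`.
#' @param ... Unused.
#' @return The per run x fold accuracy tibble.
#' @method tidy ttc_cv
#' @export
tidy.ttc_cv <- function(x, ...) tibble::as_tibble(x)

#' Summarise cross-validation results
#'
#' @param x A `ttc_cv`.
#' @param ... Unused.
#' @return One-row tibble: `trait`, `n_runs`, `n_folds`, `accuracy_mean`,
#'   `accuracy_sd` (across all fold-runs).
#' @method glance ttc_cv
#' @export
glance.ttc_cv <- function(x, ...) {
  tibble::tibble(trait = attr(x, "trait"), n_runs = attr(x, "n_runs"),
                 n_folds = attr(x, "n_folds"),
                 accuracy_mean = mean(x$accuracy, na.rm = TRUE),
                 accuracy_sd = sd(x$accuracy, na.rm = TRUE))
}
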