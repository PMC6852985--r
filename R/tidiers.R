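#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x an `apomir_de` object from [de_test()].
#' @param ... unused.
#' @return the per-tag results as a plain tibble.
#' @export
tidy.apomir_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "apomir_de")
  out
}

#' One-row model summary of a differential-expression result
#'
#' @param x an `apomir_de` object from [de_test()].
#' @param ... unused.
#' @return tibble with `n_tags`, `dispersion`, thresholds, and called counts
#'   per direction.
#' @export
glance.apomir_de <- function(x, ...) {
  genos <- attr(x, "genotypes")
  tibble(
    n_tags = nrow(x),
    dispersion = attr(x, "dispersion"),
    p_threshold = attr(x, "p_threshold"),
    fc_threshold = attr(x, "fc_threshold"),
    n_called = sum(x$call != "ns"),
    !!paste0("n_up_", genos[1]) := sum(x$call == paste0("up-in-", genos[1])),
    !!paste0("n_up_", genos[2]) := sum(x$call == paste0("up-in-", genos[2]))
  )
}

#' Tidy a qPCR genotype comparison
#'
#' @param x a `qpcr_test` from [qpcr_compare()].
#' @param ... unused.
#' @return a plain one-row tibble.
#' @export
tidy.qpcr_test <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "qpcr_test")
  out
}

#' One-row summary of a qPCR genotype comparison
#'
#' @param x a `qpcr_test` from [qpcr_compare()].
#' @param ... unused.
#' @return tibble with test settings and outcome.
#' @export
glance.qpcr_test <- function(x, ...) {
  tibble(
    method = if (attr(x, "var_equal")) "Student" else "Welch",
    alpha = attr(x, "alpha"),
    t = x$t, df = x$df, pvalue = x$pvalue, significant = x$significant
  )
}
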