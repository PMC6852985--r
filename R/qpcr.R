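#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per biological sample and assay, each
#' sample's dCt is `Ct(target) - Ct(reference)`, the ddCt subtracts the mean
#' dCt of the calibrator genotype, and relative expression is `2^-ddCt`
#' (amplification efficiency assumed 2.0 per the method's standard form).
#'
#' @param records tidy Ct table with columns `sample`, `genotype`, `assay`,
#'   `ct` (one row per technical replicate).
#' @param target_assay assay to quantify.
#' @param reference_assay housekeeping assay (default `"actin"`).
#' @param calibrator_genotype genotype whose mean dCt anchors ddCt = 0.
#' @return tibble with one row per biological sample: `sample`, `genotype`,
#'   `ct_target`, `ct_reference`, `delta_ct`, `delta_delta_ct`,
#'   `relative_expression`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample = rep(c("s1", "s2"), each = 2),
#'   genotype = rep(c("sexual", "apomictic"), each = 2),
#'   assay = rep(c("miR156", "actin"), 2),
#'   ct = c(25, 20, 24, 20)
#' )
#' qpcr_relative(ct, "miR156", "actin", calibrator_genotype = "apomictic")
qpcr_relative <- function(records, target_assay, reference_assay = "actin",
                          calibrator_genotype) {
  records <- as_tibble(records)
  need <- c("sample", "genotype", "assay", "ct")
  if (!all(need %in% names(records))) {
    abort("`records` must have columns sample, genotype, assay, ct.")
  }
  if (any(records$ct <= 0)) abort("Ct values must be positive.")
  means <- records |>
    dplyr::filter(.data$assay %in% c(target_assay, reference_assay)) |>
    dplyr::group_by(.data$sample, .data$genotype, .data$assay) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "ct")
  if (!all(c(target_assay, reference_assay) %in% names(means)) ||
      anyNA(means[[reference_assay]]) || anyNA(means[[target_assay]])) {
    abort(sprintf("Every sample needs Ct values for both '%s' and '%s'.",
                  target_assay, reference_assay))
  }
  out <- means |>
    dplyr::transmute(
      sample = .data$sample, genotype = .data$genotype,
      ct_target = .data[[target_assay]],
      ct_reference = .data[[reference_assay]],
      delta_ct = .data$ct_target - .data$ct_reference
    )
  calib <- out$delta_ct[out$genotype == calibrator_genotype]
  if (length(calib) == 0) {
    abort(sprintf("No samples of calibrator genotype '%s'.", calibrator_genotype))
  }
  out |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - mean(calib),
      relative_expression = 2^(-.data$delta_delta_ct)
    )
}

#' Compare genotype relative expression with a two-sample t-test
#'
#' Student's (equal-variance) two-sided t-test on the per-sample relative
#' expressions of the two genotypes; Welch's variant is available via
#' `var_equal = FALSE`. Significance is declared at `p < alpha`
#' (default 0.05).
#'
#' @param rel output of [qpcr_relative()] (or any tibble with `genotype` and
#'   `relative_expression` columns); exactly two genotypes, each with at
#'   least two biological samples.
#' @param var_equal pool variances (Student's t, the default) or not (Welch).
#' @param alpha significance level.
#' @return object of class `qpcr_test` (a one-row tibble): per-genotype
#'   means, `t`, `df`, `pvalue`, `significant`.
#' @export
qpcr_compare <- function(rel, var_equal = TRUE, alpha = 0.05) {
  genos <- unique(rel$genotype)
  if (length(genos) != 2) abort("Exactly two genotypes are required.")
  sizes <- table(rel$genotype)
  if (any(sizes < 2)) {
    abort("Each genotype needs at least two biological samples.")
  }
  x <- rel$relative_expression[rel$genotype == genos[1]]
  y <- rel$relative_expression[rel$genotype == genos[2]]
  ht <- t.test(x, y, var.equal = var_equal)
  out <- tibble(
    !!paste0("mean_", genos[1]) := mean(x),
    !!paste0("mean_", genos[2]) := mean(y),
    t = unname(ht$statistic), df = unname(ht$parameter),
    pvalue = ht$p.value, significant = ht$p.value < alpha
  )
  structure(out, class = c("qpcr_test", class(out)),
            genotypes = genos, alpha = alpha, var_equal = var_equal)
}
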