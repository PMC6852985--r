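#' Counts-per-million normalization
#'
#' @param counts numeric matrix (tags x libraries) of raw counts.
#' @param lib_sizes library sizes; defaults to column sums.
#' @return matrix of CPM values (`count / library size * 1e6`).
#' @export
normalize_cpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) abort("Library sizes must be positive.")
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Method-of-moments common dispersion estimate
#'
#' Libraries are scaled to the geometric-mean library size, and for every
#' genotype with replicates the within-genotype sample mean and variance of
#' each tag are pooled into the ratio estimator
#' `phi = sum(s2 - m) / sum(m^2 - s2/k)` (the denominator debiases `m^2`),
#' floored at 0. Under the negative binomial, `Var = mu + phi * mu^2` at a
#' common library size, so the ratio targets the dispersion `phi`.
#'
#' @param counts numeric matrix (tags x libraries).
#' @param groups factor/character of genotype labels, one per column.
#' @param lib_sizes library sizes; defaults to column sums.
#' @return scalar dispersion `phi >= 0`. With no replicated genotype a
#'   warning is raised and 0 is returned (Poisson fallback).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(groups) != ncol(counts)) {
    abort("`groups` must have one label per library column.")
  }
  geo <- exp(mean(log(lib_sizes)))
  scaled <- sweep(counts, 2, geo / lib_sizes, "*")
  num <- 0; den <- 0; any_rep <- FALSE
  for (g in unique(groups)) {
    cols <- which(groups == g)
    k <- length(cols)
    if (k < 2) next
    any_rep <- TRUE
    m <- rowMeans(scaled[, cols, drop = FALSE])
    s2 <- apply(scaled[, cols, drop = FALSE], 1, var)
    use <- m > 0
    num <- num + sum(s2[use] - m[use])
    den <- den + sum(m[use]^2 - s2[use] / k)
  }
  if (!any_rep) {
    warn("No genotype has replicates; returning dispersion 0 (Poisson).")
    return(0)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# exact conditional NB p-value for one (yA, yB) split given the numbers of
# pooled libraries kA, kB (after size equalization) and dispersion phi.
# At phi = 0 this is the exact conditional binomial test with
# prob = kA / (kA + kB). Ties in outcome probability are included in the
# rejection sum (conservative).
.exact_nb_pvalue <- function(y_a, y_b, k_a, k_b, phi) {
  n <- y_a + y_b
  if (n == 0) return(1)
  y <- 0:n
  tol <- 1 + 1e-12
  if (phi <= 0) {
    lw <- dbinom(y, n, k_a / (k_a + k_b), log = TRUE)
  } else {
    r_a <- k_a / phi; r_b <- k_b / phi
    lw <- lgamma(y + r_a) - lgamma(y + 1) - lgamma(r_a) +
      lgamma(n - y + r_b) - lgamma(n - y + 1) - lgamma(r_b)
  }
  w <- exp(lw - max(lw))
  sum(w[w <= w[y_a + 1] * tol]) / sum(w)
}

#' Exact conditional negative-binomial test for one tag
#'
#' Replicate libraries are scaled to the geometric-mean library size and
#' summed within genotype; conditional on the total, the probability of every
#' split as or less likely than the observed one is accumulated under the
#' negative binomial with common dispersion `phi` (at `phi = 0` this reduces
#' to the exact conditional binomial test). Two-sided by construction; ties
#' are included.
#'
#' @param counts_a,counts_b per-replicate raw counts of the tag in the two
#'   genotypes.
#' @param sizes_a,sizes_b corresponding library sizes.
#' @param dispersion common dispersion `phi >= 0`.
#' @return two-sided p-value.
#' @export
#' @examples
#' exact_nb_test(0, 10, 1e6, 1e6) # = 2 * 0.5^10
exact_nb_test <- function(counts_a, counts_b, sizes_a, sizes_b,
                          dispersion = 0) {
  if (any(c(counts_a, counts_b) < 0)) abort("Counts must be non-negative.")
  if (length(counts_a) != length(sizes_a) ||
      length(counts_b) != length(sizes_b)) {
    abort("Counts and library sizes must have matching lengths per genotype.")
  }
  sizes <- c(sizes_a, sizes_b)
  if (any(sizes <= 0)) abort("Library sizes must be positive.")
  geo <- exp(mean(log(sizes)))
  y_a <- round(sum(counts_a * geo / sizes_a))
  y_b <- round(sum(counts_b * geo / sizes_b))
  .exact_nb_pvalue(y_a, y_b, length(counts_a), length(counts_b), dispersion)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone in ranks, capped at 1),
#' delegating to [stats::p.adjust()] behind input validation.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}

#' Differential expression of tags between two genotypes
#'
#' Count-based differential expression with the package's exact conditional
#' negative-binomial test: libraries are scaled to the geometric-mean library
#' size, within-genotype replicates are summed, a common dispersion is
#' estimated by moments (unless supplied), each tag is tested exactly, and
#' p-values are Benjamini-Hochberg adjusted. A tag is called differentially
#' expressed only when `padj < p_threshold` **and** `|log2FC| > fc_threshold`
#' (both strict; the conventional thresholds are 0.01 and 2). The fold change
#' uses a pseudo-count of 0.5 per side so tags detected in a single genotype
#' keep a finite log fold change.
#'
#' @param x tag table (long: `sequence`, `library`, `count`) or a counts
#'   matrix (tags x libraries).
#' @param design tibble with `library` and `genotype` columns (libraries must
#'   match `x`).
#' @param lib_sizes library sizes; default: total counts per library in `x`.
#'   Pass the depured totals when testing a filtered subset.
#' @param dispersion common dispersion; estimated from the data when `NULL`.
#' @param p_threshold,fc_threshold call thresholds (strict inequalities).
#' @return tibble of class `apomir_de`: `sequence`, mean CPM per genotype
#'   (`cpm_<genotype>`), `log2fc` (first genotype over second), `pvalue`,
#'   `padj`, `call` (`"up-in-<genotype>"` or `"ns"`). Attributes record
#'   genotype order, dispersion and thresholds; see [glance.apomir_de()].
#' @export
de_test <- function(x, design, lib_sizes = NULL, dispersion = NULL,
                    p_threshold = 0.01, fc_threshold = 2) {
  if (is.data.frame(x)) {
    wide <- x |>
      dplyr::select("sequence", "library", "count") |>
      tidyr::pivot_wider(names_from = "library", values_from = "count",
                         values_fill = 0L)
    counts <- as.matrix(wide[, -1, drop = FALSE])
    rownames(counts) <- wide$sequence
  } else {
    counts <- as.matrix(x)
    if (is.null(rownames(counts))) {
      rownames(counts) <- paste0("tag", seq_len(nrow(counts)))
    }
  }
  design <- as_tibble(design)
  if (!all(colnames(counts) %in% design$library)) {
    abort("Every count column must appear in `design$library`.")
  }
  design <- design[match(colnames(counts), design$library), ]
  genotypes <- unique(design$genotype)
  if (length(genotypes) != 2) abort("Exactly two genotypes are required.")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) abort("Library sizes must be positive.")

  cols_a <- which(design$genotype == genotypes[1])
  cols_b <- which(design$genotype == genotypes[2])
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, design$genotype, lib_sizes)
  }

  geo <- exp(mean(log(lib_sizes)))
  scaled <- sweep(counts, 2, geo / lib_sizes, "*")
  y_a <- round(rowSums(scaled[, cols_a, drop = FALSE]))
  y_b <- round(rowSums(scaled[, cols_b, drop = FALSE]))

  # exact test per unique split (many tags share small splits)
  key <- paste(y_a, y_b)
  uk <- !duplicated(key)
  pv <- vapply(which(uk), function(i) {
    .exact_nb_pvalue(y_a[i], y_b[i], length(cols_a), length(cols_b), dispersion)
  }, numeric(1))
  pvalue <- pv[match(key, key[uk])]

  cpm <- normalize_cpm(counts, lib_sizes)
  mean_a <- rowMeans(cpm[, cols_a, drop = FALSE])
  mean_b <- rowMeans(cpm[, cols_b, drop = FALSE])
  log2fc <- log2((y_a / length(cols_a) + 0.5) / (y_b / length(cols_b) + 0.5))
  padj <- bh_adjust(pvalue)

  out <- tibble(
    sequence = rownames(counts),
    !!paste0("cpm_", genotypes[1]) := mean_a,
    !!paste0("cpm_", genotypes[2]) := mean_b,
    log2fc = log2fc, pvalue = pvalue, padj = padj
  )
  out <- call_de(out, p_threshold, fc_threshold, genotypes)
  structure(out,
    class = c("apomir_de", class(out)),
    genotypes = genotypes, dispersion = dispersion,
    p_threshold = p_threshold, fc_threshold = fc_threshold,
    lib_sizes = lib_sizes
  )
}

#' Apply the differential-expression call thresholds
#'
#' A tag is called only under the strict rule `padj < p_threshold` and
#' `|log2fc| > fc_threshold` — a tag at exactly `log2fc = 2` is **not**
#' called.
#'
#' @param results tibble with `log2fc` and `padj` columns.
#' @param p_threshold,fc_threshold thresholds (defaults 0.01 and 2).
#' @param genotypes length-2 genotype labels for call direction; defaults to
#'   the `genotypes` attribute when present.
#' @return `results` with a `call` column
#'   (`"up-in-<genotype>"` / `"ns"`).
#' @export
call_de <- function(results, p_threshold = 0.01, fc_threshold = 2,
                    genotypes = NULL) {
  genotypes <- genotypes %||% attr(results, "genotypes") %||% c("A", "B")
  dplyr::mutate(results, call = dplyr::case_when(
    .data$padj < p_threshold & .data$log2fc > fc_threshold ~
      paste0("up-in-", genotypes[1]),
    .data$padj < p_threshold & .data$log2fc < -fc_threshold ~
      paste0("up-in-", genotypes[2]),
    TRUE ~ "ns"
  ))
}

#' @export
print.apomir_de <- function(x, ...) {
  cat(sprintf(
    "<differential expression> %d tags | dispersion %.4f | %d called (padj < %g, |log2FC| > %g)\n",
    nrow(x), attr(x, "dispersion"), sum(x$call != "ns"),
    attr(x, "p_threshold"), attr(x, "fc_threshold")
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
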