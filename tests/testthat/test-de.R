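test_that("CPM normalization is count over library size times a million", {
  m <- matrix(c(10, 0, 20, 40), 2, 2,
              dimnames = list(c("t1", "t2"), c("L1", "L2")))
  cpm <- normalize_cpm(m, c(1e6, 1e6))
  expect_equal(cpm["t1", "L1"], 10)
  expect_equal(colSums(normalize_cpm(m)), c(L1 = 1e6, L2 = 1e6))
  expect_error(normalize_cpm(m, c(0, 1e6)), "positive")
})

test_that("dispersion estimation recovers the simulation truth", {
  # identical replicate columns: no overdispersion
  m <- matrix(rep(c(5, 50, 500), 4), ncol = 4,
              dimnames = list(NULL, paste0("L", 1:4)))
  expect_identical(
    estimate_common_dispersion(m, c("a", "a", "b", "b"), rep(1e6, 4)), 0
  )

  set.seed(71)
  mu <- rexp(1000, 1 / 100)
  pois <- matrix(rpois(4000, rep(mu, 4)), ncol = 4)
  phi_pois <- estimate_common_dispersion(pois, c("a", "a", "b", "b"),
                                         rep(1e6, 4))
  expect_lte(abs(phi_pois), 0.05)

  mu2 <- rexp(2000, 1 / 200)
  nb <- matrix(rnbinom(8000, mu = rep(mu2, 4), size = 1 / 0.2), ncol = 4)
  phi_nb <- estimate_common_dispersion(nb, c("a", "a", "b", "b"), rep(1e6, 4))
  expect_gte(phi_nb, 0.1)
  expect_lte(phi_nb, 0.3)

  expect_warning(
    phi0 <- estimate_common_dispersion(matrix(1:4, 2), c("a", "b"),
                                       c(1e6, 1e6)),
    "replicates"
  )
  expect_identical(phi0, 0)
})

test_that("the exact test matches closed forms at the boundaries", {
  expect_identical(exact_nb_test(7, 7, 1e6, 1e6), 1)
  expect_equal(exact_nb_test(0, 10, 1e6, 1e6), 2 * 0.5^10, tolerance = 1e-12)
  expect_error(exact_nb_test(-1, 3, 1e6, 1e6), "non-negative")
})

test_that("at zero dispersion the test equals conditional binomial enumeration", {
  for (n in c(1, 2, 5, 17, 60)) {
    for (y in 0:n) {
      probs <- dbinom(0:n, n, 0.5)
      oracle <- sum(probs[probs <= probs[y + 1] * (1 + 1e-12)])
      expect_equal(exact_nb_test(y, n - y, 1e6, 1e6), oracle,
                   tolerance = 1e-10)
    }
  }
  # unequal replicate numbers condition on kA/(kA+kB)
  p <- exact_nb_test(c(0, 0), 12, c(1e6, 1e6), 1e6)
  probs <- dbinom(0:12, 12, 2 / 3)
  expect_equal(p, sum(probs[probs <= probs[1] * (1 + 1e-12)]),
               tolerance = 1e-10)
})

test_that("positive dispersion widens the conditional distribution", {
  p0 <- exact_nb_test(2, 18, 1e6, 1e6, dispersion = 0)
  p2 <- exact_nb_test(2, 18, 1e6, 1e6, dispersion = 0.5)
  expect_gt(p2, p0)
})

test_that("BH adjustment equals the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041))
  expect_identical(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute-force definition: min over k >= i of p_(k) * m / k, capped at 1
  set.seed(72)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    m <- length(p)
    o <- order(p)
    brute <- numeric(m)
    for (r in seq_len(m)) {
      brute[o[r]] <- min(1, min(p[o][r:m] * m / (r:m)))
    }
    expect_equal(bh_adjust(p), brute, tolerance = 1e-12)
  }
})

test_that("DE calls use strict thresholds in both directions", {
  res <- tibble::tibble(
    log2fc = c(2.5, 2.0, -2.5, 0.1),
    padj = c(0.005, 0.005, 0.005, 0.5)
  )
  out <- call_de(res, genotypes = c("T", "O"))
  expect_identical(out$call, c("up-in-T", "ns", "up-in-O", "ns"))
})

test_that("de_test assembles results with finite fold changes and attributes", {
  set.seed(73)
  counts <- matrix(rpois(400, 40), ncol = 4,
                   dimnames = list(paste0("t", 1:100), c("A1", "A2", "B1", "B2")))
  counts[1, ] <- c(320, 300, 0, 0)  # detected in one genotype only
  design <- tibble::tibble(library = c("A1", "A2", "B1", "B2"),
                           genotype = c("g1", "g1", "g2", "g2"))
  de <- de_test(counts, design, lib_sizes = rep(1e5, 4))
  expect_true(all(is.finite(de$log2fc)))
  expect_true(all(de$padj >= de$pvalue))
  expect_identical(de$call[1], "up-in-g1")
  g <- glance(de)
  expect_identical(g$n_tags, 100L)
  expect_s3_class(tidy(de), "tbl_df")
  expect_false(inherits(tidy(de), "apomir_de"))
})

test_that("planted fold changes are detected with controlled FDR", {
  fx <- default_fixture()
  called <- tidy(fx$res$de)[tidy(fx$res$de)$call != "ns", ]
  truth <- fx$libs$de_truth
  sens <- sum(truth$sequence %in% called$sequence) / nrow(truth)
  expect_gte(sens, 0.9)
  fdr <- if (nrow(called)) {
    sum(!called$sequence %in% truth$sequence) / nrow(called)
  } else 0
  expect_lte(fdr, 0.05)
  # direction agrees with the planted genotype
  dir <- merge(called, truth, by = "sequence")
  expect_true(all(dir$call == paste0("up-in-", dir$genotype_up)))
})
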