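mk_mature <- function(...) {
  reference_set(c(...), "mature miRNAs", "mirna-mature")
}

test_that("known homology pairs classify with the expected mismatch counts", {
  db <- mk_mature(
    `ata-miR2275a-3p` = "UUUGUUUUUCUCCAAUAUCUCAU",
    `bdi-miR156h-3p`  = "GCUCACUGCUCUUCCUGUCAUC"
  )
  h1 <- classify_conserved("UUGUUUUUCUCCAAUAUCUCA", db)
  h1 <- h1[h1$db_id == "ata-miR2275a-3p", ]
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$mismatches, 0L)
  expect_equal(h1$coverage, 1.0)
  expect_identical(h1$offset, 1L)

  h2 <- classify_conserved("GCUCACUACUCUUCCUGUCACC", db)
  h2 <- h2[h2$db_id == "bdi-miR156h-3p" & h2$offset == 0, ]
  expect_identical(h2$mismatches, 2L)
  expect_equal(h2$coverage, 1.0)
  # the two substitutions sit at tag positions 8 and 21
  tag <- strsplit(as_dna("GCUCACUACUCUUCCUGUCACC"), "")[[1]]
  ref <- strsplit(as_dna("GCUCACUGCUCUUCCUGUCAUC"), "")[[1]]
  expect_identical(which(tag != ref), c(8L, 21L))
})

test_that("mismatch and coverage thresholds reject marginal hits", {
  set.seed(41)
  src <- rand_dna(21)
  db <- mk_mature(`osa-miR999a` = src)
  mut <- strsplit(src, "")[[1]]
  for (p in c(3, 9, 15)) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  expect_identical(nrow(classify_conserved(paste(mut, collapse = ""), db)), 0L)

  # 20-nt tag overlapping the db entry by only 17 nt: coverage 0.85 < 0.90
  tag20 <- paste0(substr(src, 5, 21), rand_dna(3))
  hits <- classify_conserved(tag20, db)
  expect_false(any(hits$aligned_length == 17))
  expect_error(classify_conserved(src, db, min_coverage = 0), "min_coverage")
})

test_that("the local scan equals the brute-force all-offsets oracle", {
  set.seed(42)
  for (rep in 1:40) {
    ref <- rand_dna(sample(30:90, 1))
    tag <- if (runif(1) < 0.5) {
      # embed a mutated copy so hits actually occur
      s <- sample(nchar(ref) - 21, 1)
      t <- strsplit(substr(ref, s, s + 20), "")[[1]]
      i <- sample(21, 2)
      t[i] <- sapply(t[i], function(b) setdiff(c("A", "C", "G", "T"), b)[1])
      paste(t, collapse = "")
    } else {
      rand_dna(sample(18:24, 1))
    }
    db <- mk_mature(`ath-miR321a` = ref)
    got <- classify_conserved(tag, db, max_mismatch = 2, min_coverage = 0.9)
    want <- oracle_local_scan(tag, ref, 2, 0.9)
    got <- got[order(got$offset), ]
    want <- want[order(want$offset), ]
    expect_identical(got$offset, want$offset)
    expect_identical(got$aligned_length, want$aligned_length)
    expect_identical(got$mismatches, want$mismatches)
  }
})

test_that("hits are monotone in the thresholds", {
  set.seed(43)
  db <- mk_mature(`osa-miR777a` = rand_dna(22), `osa-miR778a` = rand_dna(60))
  for (i in 1:20) {
    tag <- rand_dna(21)
    loose <- classify_conserved(tag, db, max_mismatch = 3, min_coverage = 0.8)
    strict <- classify_conserved(tag, db, max_mismatch = 2, min_coverage = 0.9)
    key <- function(h) paste(h$db_id, h$offset)
    expect_true(all(key(strict) %in% key(loose)))
  }
})

test_that("family names parse from database identifiers", {
  expect_identical(mirna_family(c("ata-miR2275a-3p", "osa-miR2275d")),
                   c("miR2275", "miR2275"))
  expect_identical(mirna_family("ppt-MIR894"), "miR894")
  expect_warning(fam <- mirna_family("not-a-db-id"), "unknown")
  expect_identical(fam, "unknown")
})

test_that("family summaries sum member counts per library", {
  set.seed(44)
  src <- rand_dna(21)
  db <- mk_mature(`ata-miR2275a-3p` = src)
  t1 <- src
  t2 <- strsplit(src, "")[[1]]; t2[15] <- setdiff(c("A","C","G","T"), t2[15])[1]
  t2 <- paste(t2, collapse = "")
  t3 <- strsplit(src, "")[[1]]; t3[17] <- setdiff(c("A","C","G","T"), t3[17])[1]
  t3 <- paste(t3, collapse = "")
  tags <- tibble::tibble(
    sequence = c(t1, t1, t2, t3),
    library = c("L1", "L2", "L1", "L2"),
    count = c(4L, 5L, 1L, 6L),
    label = "x"
  )
  hits <- classify_conserved(tags, db)
  fam <- summarize_families(hits, tags)
  expect_identical(fam$family, "miR2275")
  expect_identical(fam$L1, 5L)
  expect_identical(fam$L2, 11L)
  # count conservation: family totals equal conserved tag totals
  stats <- conserved_stats(fam)
  expect_identical(sum(fam$L1, fam$L2), sum(stats$conserved_count))
})

test_that("consensus naming takes the positional majority with letter suffixes", {
  db <- mk_mature(`gma-miR156d` = "UUGACAGAAGAUAGAGAGCAC")
  single <- tibble::tibble(sequence = as_dna("UUGACAGAAGAUAGAGAGCAC"),
                           library = "L1", count = 10L, label = "x")
  cons <- consensus_name(classify_conserved(single, db), single)
  expect_identical(cons$name, "ecu-miR156a")
  expect_identical(cons$consensus, "UUGACAGAAGAUAGAGAGCAC")

  # majority vote over {ACGT-like 21-mers}: two of three agree at the variant
  base <- as_dna("UUGACAGAAGAUAGAGAGCAC")
  v <- strsplit(base, "")[[1]]; v[21] <- "A"
  variant <- paste(v, collapse = "")
  tags <- tibble::tibble(sequence = c(base, base, variant),
                         library = "L1", count = c(5L, 4L, 3L), label = "x")
  cons2 <- consensus_name(classify_conserved(tags, db), tags)
  expect_identical(cons2$consensus, chartr("T", "U", base))
})

test_that("planted families are recovered from the synthetic experiment", {
  fx <- default_fixture()
  expect_setequal(fx$res$families$family,
                  unique(fx$refs$truth$families$family))
})
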