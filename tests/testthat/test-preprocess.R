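ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

make_read <- function(insert, adapter = ADAPTER, qual = NULL, id = "r1",
                      lib = "L1") {
  s <- paste0(insert, adapter)
  if (is.null(qual)) qual <- strrep("I", nchar(s))
  tibble::tibble(read_id = id, sequence = s, quality = qual, library = lib)
}

test_that("adapter trimming recovers the insert and enforces the length window", {
  set.seed(11)
  ins21 <- rand_dna(21)
  out <- trim_reads(make_read(ins21), ADAPTER)
  expect_identical(out$sequence, ins21)
  expect_identical(out$status, "kept")

  out16 <- trim_reads(make_read(rand_dna(16)), ADAPTER)
  expect_identical(out16$status, "too_short")
  out17 <- trim_reads(make_read(rand_dna(17)), ADAPTER)
  expect_identical(out17$status, "kept")
  out33 <- trim_reads(make_read(rand_dna(33)), ADAPTER)
  expect_identical(out33$status, "kept")
  out34 <- trim_reads(make_read(rand_dna(34)), ADAPTER)
  expect_identical(out34$status, "too_long")
})

test_that("low-quality 3' tails are removed and N-containing inserts dropped", {
  ins <- rand_dna(25)
  # last 4 insert bases below Q20 ('#' = Q2)
  q <- paste0(strrep("I", 21), strrep("#", 4), strrep("I", nchar(ADAPTER)))
  out <- trim_reads(make_read(ins, qual = q), ADAPTER)
  expect_identical(out$sequence, substr(ins, 1, 21))
  expect_identical(out$status, "kept")

  n_read <- make_read(paste0(rand_dna(10), "N", rand_dna(10)))
  expect_identical(trim_reads(n_read, ADAPTER)$status, "contains_n")
})

test_that("trimming is idempotent", {
  fx <- default_fixture()
  clean <- clean_reads(fx$res$trimmed)[1:500, ]
  again <- trim_reads(
    tibble::tibble(read_id = clean$read_id, sequence = clean$sequence,
                   quality = strrep("I", nchar(clean$sequence)),
                   library = clean$library),
    ADAPTER
  )
  expect_identical(again$sequence, clean$sequence)
  expect_true(all(again$status == "kept"))
})

test_that("malformed records raise a parse error with the record index", {
  bad <- tibble::tibble(read_id = c("a", "b"), sequence = c("ACGT", "ACGT"),
                        quality = c("IIII", "III"), library = "L1")
  expect_error(trim_reads(bad, ADAPTER), "index 2")
})

test_that("collapsing counts every distinct sequence once and conserves reads", {
  reads <- tibble::tibble(
    sequence = c(rep(strrep("A", 20), 5), rep(strrep("C", 20), 3),
                 rep(strrep("G", 20), 2)),
    library = c(rep("L1", 8), rep("L2", 2))
  )
  tags <- collapse_tags(reads)
  expect_identical(nrow(tags), 3L)
  expect_identical(tags$count[tags$sequence == strrep("A", 20)], 5L)
  expect_identical(tags$label[tags$sequence == strrep("A", 20)], "L1_5")
  expect_identical(sum(tags$count), nrow(reads))
})

test_that("collapse matches a brute-force multiset count on 10k random reads", {
  set.seed(21)
  pool <- replicate(300, rand_dna(sample(17:33, 1)))
  seqs <- sample(pool, 1e4, replace = TRUE)
  tags <- collapse_tags(tibble::tibble(sequence = seqs, library = "L1"))
  naive <- table(seqs)
  expect_identical(nrow(tags), length(naive))
  expect_identical(
    tags$count[match(names(naive), tags$sequence)],
    as.integer(naive)
  )
})

test_that("the minimum count filter keeps the boundary and reports percentages", {
  tags <- tibble::tibble(
    sequence = replicate(4, rand_dna(21)), library = "L1",
    count = c(1L, 2L, 3L, 5L),
    label = paste0("L1_", c(1, 2, 3, 5))
  )
  kept <- filter_min_count(tags, 3)
  expect_setequal(kept$count, c(3L, 5L))
  summ <- filter_summary(kept)
  expect_identical(summ$discarded_reads, 3L)
  expect_equal(summ$pct_discarded, 3 / 11 * 100, tolerance = 1e-12)
  expect_error(filter_min_count(tags, 0), "min_count")
})

test_that("raw reads partition into kept plus discarded at every step", {
  fx <- default_fixture()
  trimmed <- fx$res$trimmed
  expect_identical(nrow(trimmed), nrow(fx$libs$reads))
  expect_identical(sum(trimmed$status == "kept") +
                     sum(trimmed$status != "kept"), nrow(trimmed))
  tags <- collapse_tags(clean_reads(trimmed))
  expect_identical(sum(tags$count), sum(trimmed$status == "kept"))
  summ <- filter_summary(fx$res$tags)
  expect_identical(summ$included_reads + summ$discarded_reads,
                   summ$clean_reads)
})

test_that("length profiles sum to the read count and report modes", {
  reads <- tibble::tibble(sequence = c(rep(strrep("A", 21), 5),
                                       rep(strrep("C", 24), 3)),
                          library = "L1")
  prof <- length_profile(reads)
  expect_identical(sum(prof$n), 8L)
  expect_identical(profile_modes(prof), c(21L, 24L))

  one <- length_profile(tibble::tibble(sequence = rep(strrep("A", 21), 3)))
  expect_identical(profile_modes(one), 21L)
  expect_error(length_profile(tibble::tibble(sequence = character())),
               "empty")
})
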