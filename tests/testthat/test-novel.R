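mk_tx <- function(...) reference_set(c(...), "transcriptome", "transcriptome")

test_that("exact transcriptome mapping is exact, forward-strand, multi-mapped", {
  set.seed(51)
  tx_seq <- rand_dna(300)
  tx <- mk_tx(t1 = tx_seq)
  tag <- substr(tx_seq, 51, 71)
  hits <- map_exact(tag, tx)
  expect_identical(hits$start, 50L)
  expect_identical(hits$end, 71L)

  mut <- strsplit(tag, "")[[1]]
  mut[10] <- setdiff(c("A", "C", "G", "T"), mut[10])[1]
  expect_identical(nrow(map_exact(paste(mut, collapse = ""), tx)), 0L)

  # reverse-complement matches are NOT reported (oriented mRNA)
  expect_identical(nrow(map_exact(oracle_revcomp(tag), tx)), 0L)

  dup <- paste0(tx_seq, tx_seq)   # two copies -> two positions
  expect_identical(nrow(map_exact(tag, mk_tx(t2 = dup))), 2L)
})

test_that("exact mapping equals brute-force substring search on random data", {
  set.seed(52)
  tx_seqs <- setNames(replicate(20, rand_dna(sample(100:400, 1))),
                      paste0("tx", 1:20))
  tx <- reference_set(tx_seqs, "transcriptome", "transcriptome")
  tags <- c(
    replicate(150, rand_dna(sample(17:25, 1))),
    # planted substrings
    vapply(sample(20, 50, replace = TRUE), function(j) {
      s <- tx_seqs[[j]]
      st <- sample(nchar(s) - 21, 1)
      substr(s, st, st + 20)
    }, character(1))
  )
  tags <- unique(tags)
  got <- map_exact(tags, tx)
  for (id in names(tx_seqs)) {
    sub <- got[got$transcript_id == id, ]
    want <- do.call(rbind, lapply(tags, function(tg) {
      o <- oracle_end_to_end(tg, tx_seqs[[id]], 0)
      if (nrow(o)) data.frame(sequence = tg, start = o$start - 1) else NULL
    }))
    if (is.null(want)) {
      expect_identical(nrow(sub), 0L)
    } else {
      expect_identical(
        sort(paste(sub$sequence, sub$start)),
        sort(paste(want$sequence, want$start))
      )
    }
  }
})

test_that("coverage profiles compute breadth and merge loci across small gaps", {
  hits1 <- tibble::tibble(sequence = "x", transcript_id = "t1",
                          start = 10L, end = 31L)
  prof1 <- profile_transcript(hits1, 300)
  expect_equal(prof1$breadth, 21 / 300)

  tile <- tibble::tibble(
    sequence = paste0("s", 1:15), transcript_id = "t1",
    start = seq(0L, 280L, by = 20L), end = seq(20L, 300L, by = 20L)
  )
  expect_equal(profile_transcript(tile, 300)$breadth, 1.0)

  two <- tibble::tibble(sequence = c("a", "b"), transcript_id = "t1",
                        start = c(10L, 25L), end = c(31L, 46L))
  prof2 <- profile_transcript(two, 100, merge_gap = 5)
  expect_identical(nrow(prof2$loci), 1L)
  expect_identical(prof2$loci$start, 10L)
  expect_identical(prof2$loci$end, 46L)

  # disjoint runs separated by more than the merge gap stay separate
  far <- tibble::tibble(sequence = c("a", "b"), transcript_id = "t1",
                        start = c(0L, 50L), end = c(21L, 71L))
  expect_identical(nrow(profile_transcript(far, 100, merge_gap = 5)$loci), 2L)

  oob <- tibble::tibble(sequence = "a", transcript_id = "t1",
                        start = 290L, end = 311L)
  expect_error(profile_transcript(oob, 300), "bounds")
})

test_that("degradation calls follow breadth, locus count and width rules", {
  tile <- tibble::tibble(
    sequence = paste0("s", 1:15), transcript_id = "t1",
    start = seq(0L, 280L, by = 20L), end = seq(20L, 300L, by = 20L)
  )
  degr <- classify_degradation(profile_transcript(tile, 300))
  expect_identical(degr$call, "degradation")
  expect_identical(nrow(degr$candidates), 0L)

  one <- tibble::tibble(sequence = "a", transcript_id = "t1",
                        start = 100L, end = 122L)
  cand <- classify_degradation(profile_transcript(one, 300))
  expect_identical(cand$call, "candidate")
  expect_identical(nrow(cand$candidates), 1L)
  expect_identical(cand$candidates$start, 100L)

  # a single locus wider than max_locus_width is degradation-like
  wide <- tibble::tibble(sequence = c("a", "b"), transcript_id = "t1",
                         start = c(100L, 120L), end = c(122L, 142L))
  expect_identical(classify_degradation(profile_transcript(wide, 300))$call,
                   "degradation")
  expect_error(
    classify_degradation(profile_transcript(one, 300), breadth_threshold = 2),
    "breadth_threshold"
  )
})

test_that("degradation calls are monotone in breadth and order-invariant", {
  set.seed(53)
  base <- tibble::tibble(
    sequence = paste0("s", 1:10), transcript_id = "t1",
    start = as.integer(seq(0, 225, by = 25)),
    end = as.integer(seq(0, 225, by = 25) + 21)
  )
  prof <- profile_transcript(base, 250)
  call0 <- classify_degradation(prof)$call
  # adding covering tags can only push the call toward degradation
  more <- dplyr::bind_rows(base, tibble::tibble(
    sequence = paste0("extra", 1:10), transcript_id = "t1",
    start = as.integer(seq(2, 227, by = 25)),
    end = as.integer(seq(2, 227, by = 25) + 21)
  ))
  call1 <- classify_degradation(profile_transcript(more, 250))$call
  if (call0 == "degradation") expect_identical(call1, "degradation")

  shuffled <- more[sample(nrow(more)), ]
  expect_identical(classify_degradation(profile_transcript(shuffled, 250)),
                   classify_degradation(profile_transcript(more, 250)))
})

test_that("candidates inherit relaxed-homology names or serial fallbacks", {
  set.seed(54)
  src <- rand_dna(21)
  mature <- reference_set(c(`osa-miR5049b` = src), "mature", "mirna-mature")
  near <- strsplit(src, "")[[1]]
  near[c(3, 10, 15)] <- sapply(near[c(3, 10, 15)],
                               function(b) setdiff(c("A","C","G","T"), b)[1])
  near <- paste(near, collapse = "")
  cands <- tibble::tibble(
    sequence = c(near, rand_dna(21)),
    transcript_id = c("t1", "t2"), start = c(10L, 10L), end = c(31L, 31L),
    n_tags = 1L, total_count = c(50, 20)
  )
  named <- name_novel(cands, mature)
  expect_identical(named$name[named$sequence == near], "ecu-miR5049")
  expect_identical(named$name[named$sequence != near], "ecu-novel-1")

  # two candidates of the same family receive letter suffixes by count order
  near2 <- strsplit(src, "")[[1]]
  near2[c(4, 11, 16)] <- sapply(near2[c(4, 11, 16)],
                                function(b) setdiff(c("A","C","G","T"), b)[1])
  near2 <- paste(near2, collapse = "")
  both <- tibble::tibble(
    sequence = c(near, near2), transcript_id = c("t1", "t2"),
    start = 10L, end = 31L, n_tags = 1L, total_count = c(50, 80)
  )
  named2 <- name_novel(both, mature)
  expect_identical(named2$name[named2$sequence == near2], "ecu-miR5049a")
  expect_identical(named2$name[named2$sequence == near], "ecu-miR5049b")
})

test_that("no classified-conserved tag reaches the discovery stage", {
  fx <- default_fixture()
  conserved_seqs <- unique(fx$res$conserved_hits$sequence)
  cand_tags <- unlist(transcript_calls(fx$res$novel)$transcript_id)
  novel_input <- fx$res$depured[
    !fx$res$depured$sequence %in% conserved_seqs, ]
  expect_false(any(fx$res$novel$sequence %in% conserved_seqs))
  expect_true(all(fx$res$novel$sequence %in% novel_input$sequence))
})
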