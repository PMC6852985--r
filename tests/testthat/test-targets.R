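# helper: build a target window complementary to `mirna` except at the given
# miRNA positions, where the opposite base is replaced
window_for <- function(mirna, changes = list()) {
  mv <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  ta <- unname(COMP[mv])              # target aligned to miRNA 5'->3'
  for (ch in changes) ta[ch$pos] <- ch$base
  paste(rev(ta), collapse = "")
}

# the target base that turns miRNA position `pos` into a G:U wobble
wobble_base <- function(mirna, pos) {
  b <- substr(chartr("U", "T", toupper(mirna)), pos, pos)
  if (b == "G") "T" else if (b == "T") "G" else
    stop("position cannot form a wobble")
}

test_that("the golden duplex set scores as hand-computed", {
  set.seed(61)
  # a miRNA whose position 10 is G (so the central window can carry a wobble)
  mirna <- "UAGCACUAUGAUGAAGCCCUA"
  stopifnot(substr(chartr("U", "T", mirna), 10, 10) == "G")
  p <- scoring_params()

  perfect <- score_duplex(mirna, window_for(mirna), p)
  expect_true(perfect$accepted)
  expect_identical(perfect$expectation, 0)
  expect_identical(perfect$mode, "cleavage")
  expect_identical(call_mode(perfect, p), "cleavage")

  # reverse-complementing both strands of a perfect duplex leaves it perfect
  flipped <- score_duplex(revcomp(as_dna(mirna)),
                          revcomp(window_for(mirna)), p)
  expect_identical(flipped$expectation, 0)

  # a true mismatch at seed position 3 rejects outright
  mm3 <- window_for(mirna, list(list(pos = 3, base = "A")))
  expect_false(score_duplex(mirna, mm3, p)$accepted)

  # single central G:U at position 10: 0.5 doubled in the seed -> 1.0,
  # translational inhibition
  gu10 <- window_for(mirna, list(list(pos = 10, base = wobble_base(mirna, 10))))
  s10 <- score_duplex(mirna, gu10, p)
  expect_true(s10$accepted)
  expect_equal(s10$expectation, 1.0)
  expect_identical(s10$mode, "translational-inhibition")

  # single mismatch at position 15 (outside the seed): penalty 1.0, cleavage
  mm15 <- window_for(mirna, list(list(pos = 15, base = "C")))
  s15 <- score_duplex(mirna, mm15, p)
  expect_true(s15$accepted)
  expect_equal(s15$expectation, 1.0)
  expect_identical(s15$mode, "cleavage")

  # G:U at position 16 only (outside 9-11): cleavage
  gu16 <- window_for(mirna, list(list(pos = 16, base = wobble_base(mirna, 16))))
  s16 <- score_duplex(mirna, gu16, p)
  expect_true(s16$accepted)
  expect_identical(s16$mode, "cleavage")

  # expectation above the cap rejects: three mismatches outside the seed
  over <- window_for(mirna, list(list(pos = 14, base = "C"),
                                 list(pos = 15, base = "C"),
                                 list(pos = 16, base = "A")))
  expect_false(score_duplex(mirna, over, p)$accepted)
})

test_that("windows longer than the miRNA are rejected (no target bulges)", {
  set.seed(62)
  mirna <- rand_dna(21)
  long_window <- rand_dna(23)
  out <- score_duplex(mirna, long_window)
  expect_false(out$accepted)
  expect_identical(out$reject_reason, "target_bulge_required")
})

test_that("a single miRNA bulge is scored at gap penalty", {
  set.seed(63)
  mirna <- rand_dna(21)
  # remove the target base opposite miRNA position 15 -> miRNA bulge at 15
  mv <- strsplit(mirna, "")[[1]]
  ta <- unname(COMP[mv])
  window <- paste(rev(ta[-15]), collapse = "")
  out <- score_duplex(mirna, window)
  expect_true(out$accepted)
  expect_equal(out$expectation, 2.0)
  expect_identical(out$pairing[15], "BULGE")
})

test_that("degrading a pair never decreases the expectation", {
  set.seed(64)
  p <- scoring_params(max_expectation = 100)  # keep everything comparable
  for (i in 1:25) {
    mirna <- rand_dna(21)
    pos <- sample(14:21, 1)       # outside the seed so nothing rejects
    wc <- score_duplex(mirna, window_for(mirna), p)$expectation
    base <- substr(mirna, pos, pos)
    gu_possible <- base %in% c("G", "T")
    if (gu_possible) {
      gu <- score_duplex(
        mirna,
        window_for(mirna, list(list(pos = pos, base = wobble_base(mirna, pos)))),
        p
      )$expectation
      expect_gte(gu, wc)
    }
    mm_base <- setdiff(c("A", "C", "G", "T"),
                       c(COMP[base], if (gu_possible) wobble_base(mirna, pos)))[1]
    mm <- score_duplex(
      mirna, window_for(mirna, list(list(pos = pos, base = mm_base))), p
    )$expectation
    expect_gte(mm, wc)
    if (gu_possible) expect_gte(mm, gu)
  }
})

test_that("transcript scans find planted sites and nothing else", {
  set.seed(65)
  mirna <- rand_dna(21)
  site <- oracle_revcomp(mirna)
  tx <- paste0(rand_dna(150), site, rand_dna(150))
  sites <- scan_transcript(mirna, tx)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 150L)
  expect_identical(sites$expectation, 0)

  none <- scan_transcript(mirna, rand_dna(400))
  expect_identical(nrow(none), 0L)
})

test_that("UPE filtering requires a backend and removes inaccessible sites", {
  set.seed(66)
  mirna <- rand_dna(21)
  tx <- paste0(rand_dna(60), oracle_revcomp(mirna), rand_dna(60))
  expect_error(scan_transcript(mirna, tx, filter_upe = TRUE), "backend")
  with_upe <- scan_transcript(mirna, tx, upe_backend = upe_stub)
  expect_true(all(!is.na(with_upe$upe)))
  strict <- scoring_params(upe_max = 0)
  expect_identical(
    nrow(scan_transcript(mirna, tx, strict, upe_backend = upe_stub)), 0L
  )
})

test_that("planted target sites are recovered with zero spurious calls", {
  fx <- default_fixture()
  planted <- fx$refs$truth$target_sites
  strict <- fx$res$targets[fx$res$targets$expectation <= 1.0, ]
  # each planted site appears at its exact interval
  for (i in seq_len(nrow(planted))) {
    hit <- strict[strict$transcript_id == planted$transcript_id[i] &
                    strict$start == planted$start[i] &
                    strict$end == planted$end[i], ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$expectation, 0)
  }
  # and nothing else survives the strict expectation cutoff
  expect_identical(nrow(strict), nrow(planted))
})

test_that("repression-consistent interactions are flagged correctly", {
  targets <- tibble::tibble(
    mirna_id = c("miR-A", "miR-A", "miR-B"),
    transcript_id = c("t1", "t2", "t3")
  )
  de <- tibble::tibble(mirna_id = c("miR-A", "miR-B"),
                       up_in = c("sexual", NA))
  presence <- tibble::tibble(
    transcript_id = c("t1", "t2", "t2", "t3"),
    genotype = c("apomictic", "apomictic", "sexual", "sexual"),
    detected = TRUE
  )
  out <- link_expression(targets, de, presence)
  expect_identical(out$status[out$transcript_id == "t1"],
                   "repression-consistent")
  expect_identical(out$status[out$transcript_id == "t2"], "partial")
  expect_false("miR-B" %in% out$mirna_id)   # no DE call -> no rows
  empty <- link_expression(targets,
                           tibble::tibble(mirna_id = character(),
                                          up_in = character()),
                           presence)
  expect_identical(nrow(empty), 0L)
})
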