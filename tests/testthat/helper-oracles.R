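# Independent brute-force oracles. These deliberately re-derive every result
# from first principles with plain R loops / vectorized substring scans, and
# never call into the package's matching or scoring internals.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# every end-to-end placement of `tag` on `refseq` with <= max_mm substitutions
oracle_end_to_end <- function(tag, refseq, max_mm) {
  w <- nchar(tag)
  L <- nchar(refseq)
  if (w > L) return(data.frame(start = integer(), mismatches = integer()))
  starts <- 1:(L - w + 1)
  subs <- substring(refseq, starts, starts + w - 1)
  mm <- vapply(subs, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(tag, "")[[1]])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(start = starts[mm <= max_mm], mismatches = mm[mm <= max_mm])
}

# every diagonal placement (overhangs allowed) with coverage and mismatch
# thresholds, as plain nested loops
oracle_local_scan <- function(tag, refseq, max_mm, min_cov) {
  tv <- strsplit(tag, "")[[1]]
  rv <- strsplit(refseq, "")[[1]]
  w <- length(tv); L <- length(rv)
  out <- list()
  for (d in (-(w - 1)):(L - 1)) {
    i0 <- max(1, 1 - d)
    i1 <- min(w, L - d)
    alen <- i1 - i0 + 1
    if (alen < 1 || alen / w < min_cov - 1e-12) next
    mm <- sum(tv[i0:i1] != rv[(d + i0):(d + i1)])
    if (mm <= max_mm) {
      out[[length(out) + 1]] <- data.frame(offset = as.integer(d),
                                           aligned_length = as.integer(alen),
                                           mismatches = as.integer(mm))
    }
  }
  if (!length(out)) {
    return(data.frame(offset = integer(), aligned_length = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# independent duplex scorer: penalties accumulated position by position in a
# plain loop; returns NULL for rejected duplexes
oracle_duplex <- function(mirna, window, max_expectation = 2.5,
                          seed = 2:13, central = 9:11,
                          pen_mm = 1, pen_gu = 0.5, pen_bulge = 2,
                          seed_mult = 2) {
  mv <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  wv <- strsplit(chartr("Uu", "Tt", toupper(window)), "")[[1]]
  n <- length(mv); Lw <- length(wv)
  if (Lw > n) return(NULL)                       # would need a target bulge
  if (n - Lw > 1) return(NULL)
  bulges <- if (Lw == n) list(NULL) else as.list(2:(n - 1))
  best <- NULL
  for (b in bulges) {
    ta <- rev(wv)
    if (!is.null(b)) ta <- append(ta, NA_character_, after = b - 1)
    total <- 0
    ok <- TRUE
    nonwc_central <- FALSE
    for (i in seq_len(n)) {
      t <- ta[i]
      if (is.na(t)) {
        p <- pen_bulge
        nonwc <- TRUE
      } else if (t == COMP[mv[i]]) {
        p <- 0; nonwc <- FALSE
      } else if ((mv[i] == "G" && t == "T") || (mv[i] == "T" && t == "G")) {
        p <- pen_gu; nonwc <- TRUE
      } else {
        if (i %in% seed) { ok <- FALSE; break }   # true mismatch in the seed
        p <- pen_mm; nonwc <- TRUE
      }
      if (i %in% seed) p <- p * seed_mult
      if (nonwc && i %in% central) nonwc_central <- TRUE
      total <- total + p
    }
    if (!ok || total > max_expectation) next
    if (is.null(best) || total < best$expectation) {
      best <- list(expectation = total,
                   mode = if (nonwc_central) "translational-inhibition" else "cleavage")
    }
  }
  best
}

# exhaustive window enumeration + the same greedy overlap reduction, built on
# the oracle scorer only
oracle_scan <- function(mirna, transcript, max_expectation = 2.5) {
  m <- chartr("Uu", "Tt", toupper(mirna))
  tx <- chartr("Uu", "Tt", toupper(transcript))
  n <- nchar(m); L <- nchar(tx)
  rows <- list()
  for (w in c(n, n - 1)) {
    if (w > L || w < 1) next
    for (s in 1:(L - w + 1)) {
      sc <- oracle_duplex(m, substr(tx, s, s + w - 1),
                          max_expectation = max_expectation)
      if (!is.null(sc)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = s - 1, end = s - 1 + w,
          expectation = sc$expectation, mode = sc$mode
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      expectation = numeric(), mode = character()))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$expectation, cand$start), ]
  keep <- rep(FALSE, nrow(cand))
  ts <- integer(0); te <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < te & cand$end[i] > ts)) {
      keep[i] <- TRUE
      ts <- c(ts, cand$start[i]); te <- c(te, cand$end[i])
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# random DNA of given length
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
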