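#' Trim adapters and low-quality tails from raw small-RNA reads
#'
#' Implements the read cleanup step of a small-RNA pipeline: the 3' adapter is
#' removed at the leftmost position where a read suffix matches a prefix of
#' the adapter over at least `min_overlap` exact bases; trailing bases below
#' `quality_cutoff` are then removed; finally the insert is kept only if its
#' length falls in `[min_len, max_len]` and (by default) contains no N.
#'
#' Trimming is idempotent: the kept insert precedes the leftmost adapter
#' match, so re-trimming changes nothing.
#'
#' @param reads tibble with columns `read_id`, `sequence`, `quality` and
#'   (optionally) `library`, as returned by [read_fastq()] or
#'   [sim_libraries()].
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param quality_cutoff Phred score below which trailing bases are removed
#'   (default Q20).
#' @param min_overlap minimum exact suffix-prefix overlap to call an adapter.
#' @param min_len,max_len retained insert length window (defaults 17-33 nt).
#' @param discard_n drop inserts containing N (they cannot be matched ungapped
#'   without ambiguity rules).
#' @return a tibble of class `trimmed_reads` with columns `read_id`,
#'   `library`, `sequence` (the trimmed insert), `length`, and `status`
#'   (`"kept"`, `"too_short"`, `"too_long"`, or `"contains_n"`). Use
#'   [clean_reads()] to keep only the clean inserts.
#' @export
#' @examples
#' reads <- tibble::tibble(
#'   read_id = "r1",
#'   sequence = paste0("TTGACAGAAGATAGAGAGCAC", "TGGAATTCTCGGGTGCCAAGG"),
#'   quality = strrep("I", 42), library = "L1"
#' )
#' trim_reads(reads, adapter = "TGGAATTCTCGGGTGCCAAGG")
trim_reads <- function(reads, adapter, quality_cutoff = 20, min_overlap = 8,
                       min_len = 17, max_len = 33, discard_n = TRUE) {
  stopifnot(is.data.frame(reads))
  need <- c("read_id", "sequence", "quality")
  if (!all(need %in% names(reads))) {
    abort("`reads` must have columns read_id, sequence, quality.")
  }
  adapter <- as_dna(adapter)
  if (nchar(adapter) < 8) abort("`adapter` must be at least 8 nt.")
  if (min_overlap < 1 || min_overlap > nchar(adapter)) {
    abort("`min_overlap` must lie in [1, nchar(adapter)].")
  }
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    abort(sprintf(
      "Malformed FASTQ record(s): sequence/quality length mismatch at index %s.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }

  seqs <- as_dna(reads$sequence)
  L <- nchar(seqs)
  alen <- nchar(adapter)
  key <- substr(adapter, 1, min_overlap)

  # leftmost suffix-prefix overlap >= min_overlap, exact matching
  insert_len <- L
  from <- rep.int(1L, length(seqs))
  todo <- seq_along(seqs)
  while (length(todo)) {
    hit <- regexpr(key, substring(seqs[todo], from[todo], L[todo]), fixed = TRUE)
    found <- hit > 0L
    pos <- from[todo] + as.integer(hit) - 1L       # candidate adapter start
    cand <- todo[found]
    if (length(cand) == 0L) break
    pos <- pos[found]
    ov <- pmin(L[cand] - pos + 1L, alen)
    ok <- substring(seqs[cand], pos, pos + ov - 1L) == substring(adapter, 1, ov)
    insert_len[cand[ok]] <- pos[ok] - 1L
    # failed verification: resume the search one base past the candidate
    from[cand[!ok]] <- pos[!ok] + 1L
    todo <- cand[!ok]
    todo <- todo[from[todo] + min_overlap - 1L <= L[todo]]
  }

  # 3' quality trimming within the insert
  qmin_char <- 33L + as.integer(quality_cutoff)
  has_tail <- insert_len > 0L
  if (any(has_tail)) {
    last_q <- substring(reads$quality, insert_len, insert_len)
    last_ok <- rep.int(TRUE, length(seqs))
    nz <- has_tail & nzchar(last_q)
    if (any(nz)) {
      last_ok[nz] <- utf8ToInt(paste(last_q[nz], collapse = "")) >= qmin_char
    }
    fix <- which(has_tail & !last_ok)
    for (i in fix) {
      qi <- utf8ToInt(substr(reads$quality[i], 1L, insert_len[i]))
      keep <- which(qi >= qmin_char)
      insert_len[i] <- if (length(keep)) max(keep) else 0L
    }
  }

  insert <- substring(seqs, 1L, insert_len)
  status <- dplyr::case_when(
    insert_len < min_len ~ "too_short",
    insert_len > max_len ~ "too_long",
    discard_n & grepl("N", insert, fixed = TRUE) ~ "contains_n",
    TRUE ~ "kept"
  )
  out <- tibble(
    read_id = reads$read_id,
    library = if ("library" %in% names(reads)) reads$library else "library1",
    sequence = insert,
    length = insert_len,
    status = status
  )
  class(out) <- c("trimmed_reads", class(out))
  out
}

#' Keep only the clean reads of a trimmed read table
#'
#' @param trimmed output of [trim_reads()].
#' @return tibble of kept reads.
#' @export
clean_reads <- function(trimmed) {
  dplyr::filter(as_tibble(trimmed), .data$status == "kept")
}

#' Collapse clean reads into counted sequence tags
#'
#' Each library is collapsed separately: one tag per distinct sequence, with
#' its read count and a `LIBRARY_count` label (the conventional tag naming of
#' collapsed small-RNA libraries). The sum of tag counts equals the number of
#' clean reads per library.
#'
#' @param clean tibble of clean reads with `sequence` and `library` columns
#'   (e.g. [clean_reads()] output).
#' @return tibble with columns `sequence`, `library`, `count`, `label`.
#' @export
collapse_tags <- function(clean) {
  clean <- as_tibble(clean)
  if ("status" %in% names(clean)) clean <- dplyr::filter(clean, .data$status == "kept")
  if (!all(c("sequence", "library") %in% names(clean))) {
    abort("`clean` must have `sequence` and `library` columns.")
  }
  clean |>
    dplyr::count(.data$library, .data$sequence, name = "count") |>
    dplyr::mutate(label = paste0(.data$library, "_", .data$count)) |>
    dplyr::select("sequence", "library", "count", "label")
}

#' Apply the minimum tag count filter
#'
#' Tags with a per-library read count below `min_count` are discarded, the
#' standard depth filter of small-RNA library analysis (default: counts below
#' 3 are dropped; a tag with count exactly 3 is kept). The per-library
#' accounting (clean reads, included/discarded reads, percent discarded) is
#' attached as the `"filter_summary"` attribute and returned by
#' [filter_summary()].
#'
#' @param tags tag table from [collapse_tags()].
#' @param min_count minimum per-library count (>= 1).
#' @return the kept tags, with a `filter_summary` attribute.
#' @export
filter_min_count <- function(tags, min_count = 3) {
  if (min_count < 1) abort("`min_count` must be >= 1.")
  if (any(tags$count < 0)) abort("Tag counts must be non-negative.")
  kept <- dplyr::filter(tags, .data$count >= min_count)
  summ <- tags |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(
      clean_reads = sum(.data$count),
      tags_total = dplyr::n(),
      tags_kept = sum(.data$count >= min_count),
      included_reads = sum(.data$count[.data$count >= min_count]),
      discarded_reads = sum(.data$count[.data$count < min_count]),
      pct_discarded = 100 * .data$discarded_reads / .data$clean_reads,
      .groups = "drop"
    )
  attr(kept, "filter_summary") <- summ
  attr(kept, "min_count") <- min_count
  kept
}

#' @rdname filter_min_count
#' @param x output of [filter_min_count()].
#' @export
filter_summary <- function(x) attr(x, "filter_summary")

#' Library description report
#'
#' Per-library summary in the shape of a sequencing-study "description of
#' libraries" table: clean read count, average insert size, number of tags at
#' the minimum count, included and discarded reads, and percent discarded.
#'
#' @param trimmed output of [trim_reads()] (clean reads are selected
#'   internally).
#' @param min_count minimum per-library tag count.
#' @return a tibble, one row per library.
#' @export
library_description <- function(trimmed, min_count = 3) {
  clean <- clean_reads(trimmed)
  tags <- collapse_tags(clean)
  kept <- filter_min_count(tags, min_count)
  avg <- clean |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(avg_size = mean(.data$length), .groups = "drop")
  filter_summary(kept) |>
    dplyr::left_join(avg, by = "library") |>
    dplyr::transmute(
      library = .data$library,
      n_reads = .data$clean_reads,
      avg_size = round(.data$avg_size, 1),
      n_tags = .data$tags_kept,
      included_reads = .data$included_reads,
      discarded_reads = .data$discarded_reads,
      pct_discarded = round(.data$pct_discarded, 2)
    )
}

#' Insert length distribution and modal lengths
#'
#' Histogram of clean-read lengths (per library when a `library` column is
#' present). Modal lengths are the local maxima of the pooled histogram,
#' reported in descending frequency order; healthy plant small-RNA libraries
#' show two peaks, at 21 nt (miRNA-sized) and 24 nt (heterochromatic
#' siRNA-sized).
#'
#' @param clean clean reads ([clean_reads()] output) or any tibble with
#'   `length` (or `sequence`) and optionally `library` columns.
#' @return tibble of class `length_profile` with columns `library` (if
#'   grouped), `length`, `n`; attribute `"modes"` holds the pooled modal
#'   lengths.
#' @export
length_profile <- function(clean) {
  clean <- as_tibble(clean)
  if ("status" %in% names(clean)) clean <- dplyr::filter(clean, .data$status == "kept")
  if (nrow(clean) == 0) abort("Cannot profile an empty read set.")
  if (!"length" %in% names(clean)) clean$length <- nchar(clean$sequence)
  grouped <- "library" %in% names(clean)
  hist <- if (grouped) {
    dplyr::count(clean, .data$library, .data$length, name = "n")
  } else {
    dplyr::count(clean, .data$length, name = "n")
  }
  pooled <- clean |> dplyr::count(.data$length, name = "n") |>
    dplyr::arrange(.data$length)
  # fill absent lengths with zeros so modes are local maxima on a full grid
  grid <- tibble(length = seq(min(pooled$length), max(pooled$length)))
  pooled <- dplyr::left_join(grid, pooled, by = "length") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  n <- pooled$n
  lo <- c(-Inf, n[-length(n)])
  hi <- c(n[-1], -Inf)
  is_mode <- n > lo & n >= hi
  modes <- pooled$length[is_mode][order(-n[is_mode])]
  structure(hist, class = c("length_profile", class(hist)), modes = modes)
}

#' @rdname length_profile
#' @param x a `length_profile`.
#' @export
profile_modes <- function(x) attr(x, "modes")
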