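#' Map tags exactly onto the reference transcriptome
#'
#' Exact, end-to-end, forward-strand matching of tags against transcripts
#' (no mismatches, no gaps); multi-mapping tags are retained with all their
#' positions. Transcript intervals are reported 0-based half-open, the
#' coordinate convention used throughout the discovery module.
#'
#' @param tags character vector of tag sequences or tag table with a
#'   `sequence` column.
#' @param transcriptome a [reference_set()] of transcripts.
#' @return tibble with columns `sequence`, `transcript_id`, `start`, `end`.
#' @export
map_exact <- function(tags, transcriptome) {
  stopifnot(inherits(transcriptome, "reference_set"))
  seqs <- .tag_sequences(tags)
  if (length(seqs) == 0) {
    return(tibble(sequence = character(), transcript_id = character(),
                  start = integer(), end = integer()))
  }
  out <- vector("list", nrow(transcriptome))
  for (j in seq_len(nrow(transcriptome))) {
    hits <- .match_end_to_end(seqs, transcriptome$sequence[j], 0L)
    if (nrow(hits) == 0) next
    out[[j]] <- tibble(
      sequence = seqs[hits$query],
      transcript_id = transcriptome$id[j],
      start = hits$start - 1L,
      end = hits$start - 1L + nchar(seqs[hits$query])
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(sequence = character(), transcript_id = character(),
                  start = integer(), end = integer()))
  }
  res
}

#' Coverage profile of one transcript
#'
#' Builds the per-position depth vector of a transcript from its mapped tags
#' (weighted by read count by default, since degradation signal is
#' abundance-driven), the breadth (fraction of covered positions), and the
#' merged loci: maximal runs of covered positions, with runs separated by at
#' most `merge_gap` uncovered bases merged into one locus.
#'
#' @param hits [map_exact()] rows for one transcript.
#' @param transcript_length transcript length in nt.
#' @param tags optional tag table (`sequence`, `count`) supplying read-count
#'   weights; without it every tag weighs 1.
#' @param weight_by_count weight depth by read counts (default) or by unique
#'   tags.
#' @param merge_gap maximum uncovered gap (nt) bridged when merging loci.
#' @return object of class `coverage_profile`: list with `transcript_id`,
#'   `length`, `depth` (numeric vector), `breadth`, and `loci` (tibble
#'   `start`, `end`, `n_tags`, `tags` list-column; 0-based half-open).
#' @export
profile_transcript <- function(hits, transcript_length, tags = NULL,
                               weight_by_count = TRUE, merge_gap = 5) {
  stopifnot(length(unique(hits$transcript_id)) <= 1)
  if (nrow(hits) > 0 &&
      (min(hits$start) < 0 || max(hits$end) > transcript_length)) {
    abort("Hit outside transcript bounds; integrity violation.")
  }
  wt <- rep(1, nrow(hits))
  if (weight_by_count && !is.null(tags) && nrow(hits) > 0) {
    cnt <- tags |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    wt <- cnt$count[match(hits$sequence, cnt$sequence)]
    wt[is.na(wt)] <- 1
  }
  depth <- numeric(transcript_length)
  for (i in seq_len(nrow(hits))) {
    span <- (hits$start[i] + 1L):hits$end[i]
    depth[span] <- depth[span] + wt[i]
  }
  covered <- depth > 0
  breadth <- mean(covered)

  loci <- tibble(start = integer(), end = integer(), n_tags = integer(),
                 tags = list())
  if (any(covered)) {
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- tibble(start = starts[r$values] - 1L, end = ends[r$values])
    # merge runs separated by <= merge_gap uncovered positions
    merged <- runs[1, ]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        if (runs$start[i] - merged$end[nrow(merged)] <= merge_gap) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- dplyr::bind_rows(merged, runs[i, ])
        }
      }
    }
    loci <- merged |>
      dplyr::rowwise() |>
      dplyr::mutate(
        tags = list(unique(hits$sequence[hits$start < .data$end &
                                           hits$end > .data$start])),
        n_tags = length(.data$tags)
      ) |>
      dplyr::ungroup() |>
      dplyr::select("start", "end", "n_tags", "tags")
  }
  structure(list(
    transcript_id = if (nrow(hits)) hits$transcript_id[1] else NA_character_,
    length = transcript_length, depth = depth, breadth = breadth,
    loci = loci, merge_gap = merge_gap, weight_by_count = weight_by_count
  ), class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile %s> length %d nt | breadth %.3f | %d locus(i)\n",
              x$transcript_id, x$length, x$breadth, nrow(x$loci)))
  invisible(x)
}

#' Classify a coverage profile as degradation or candidate loci
#'
#' A transcript whose reads tile it across its length is interpreted as
#' mRNA-turnover (degradation) signal rather than a miRNA locus. The visual
#' "covered across its entire length" call is operationalized as: degradation
#' iff breadth >= `breadth_threshold`, or more than `max_loci` loci, or any
#' locus wider than `max_locus_width`. Otherwise each locus yields one novel
#' candidate, represented by its highest-count member tag. The call is
#' monotone in breadth: adding covering tags can never turn a degradation
#' call into a candidate.
#'
#' @param profile a [profile_transcript()] result.
#' @param breadth_threshold breadth at or above which the transcript is
#'   degradation (default 0.8).
#' @param max_loci maximum number of loci for a candidate transcript.
#' @param max_locus_width maximum locus width (nt) for a candidate locus.
#' @param tags optional tag table used to pick the highest-count
#'   representative and report per-locus counts.
#' @return list with `call` (`"degradation"` or `"candidate"`) and
#'   `candidates` (tibble: `sequence`, `transcript_id`, `start`, `end`,
#'   `n_tags`, `total_count`; empty for degradation calls).
#' @export
classify_degradation <- function(profile, breadth_threshold = 0.8,
                                 max_loci = 2, max_locus_width = 30,
                                 tags = NULL) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (breadth_threshold <= 0 || breadth_threshold > 1) {
    abort("`breadth_threshold` must lie in (0, 1].")
  }
  if (max_loci < 1 || max_locus_width < 1) {
    abort("`max_loci` and `max_locus_width` must be positive.")
  }
  loci <- profile$loci
  degraded <- profile$breadth >= breadth_threshold ||
    nrow(loci) > max_loci ||
    (nrow(loci) > 0 && any(loci$end - loci$start > max_locus_width))
  empty <- tibble(sequence = character(), transcript_id = character(),
                  start = integer(), end = integer(), n_tags = integer(),
                  total_count = numeric())
  if (degraded || nrow(loci) == 0) {
    return(list(call = if (degraded) "degradation" else "candidate",
                candidates = empty))
  }
  cnt <- if (!is.null(tags)) {
    tags |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  } else {
    tibble(sequence = character(), count = numeric())
  }
  cands <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    members <- loci$tags[[i]]
    w <- cnt$count[match(members, cnt$sequence)]
    w[is.na(w)] <- 1
    tibble(
      sequence = members[which.max(w)],
      transcript_id = profile$transcript_id,
      start = loci$start[i], end = loci$end[i],
      n_tags = loci$n_tags[i], total_count = sum(w)
    )
  })
  list(call = "candidate", candidates = cands)
}

#' Discover novel miRNA candidates from non-conserved depured tags
#'
#' End-to-end wrapper: maps tags exactly onto the transcriptome, profiles
#' every transcript with hits, discards degradation-tiled transcripts, and
#' collects localized candidate loci.
#'
#' @param tags tag table of non-conserved depured tags (`sequence`,
#'   `library`, `count`).
#' @param transcriptome a [reference_set()].
#' @inheritParams classify_degradation
#' @inheritParams profile_transcript
#' @return tibble of candidates (see [classify_degradation()]); attribute
#'   `"transcript_calls"` holds one row per mapped transcript
#'   (`transcript_id`, `breadth`, `n_loci`, `call`), attribute
#'   `"thresholds"` the parameters used.
#' @export
discover_novel <- function(tags, transcriptome, breadth_threshold = 0.8,
                           max_loci = 2, max_locus_width = 30, merge_gap = 5,
                           weight_by_count = TRUE) {
  hits <- map_exact(tags, transcriptome)
  tx_ids <- unique(hits$transcript_id)
  calls <- vector("list", length(tx_ids))
  cands <- vector("list", length(tx_ids))
  for (i in seq_along(tx_ids)) {
    id <- tx_ids[i]
    tl <- nchar(transcriptome$sequence[transcriptome$id == id])
    prof <- profile_transcript(hits[hits$transcript_id == id, ], tl,
                               tags = if (is.data.frame(tags)) tags else NULL,
                               weight_by_count = weight_by_count,
                               merge_gap = merge_gap)
    cl <- classify_degradation(prof, breadth_threshold, max_loci,
                               max_locus_width,
                               tags = if (is.data.frame(tags)) tags else NULL)
    calls[[i]] <- tibble(transcript_id = id, breadth = prof$breadth,
                         n_loci = nrow(prof$loci), call = cl$call)
    cands[[i]] <- cl$candidates
  }
  out <- dplyr::bind_rows(cands)
  if (nrow(out) == 0) {
    out <- tibble(sequence = character(), transcript_id = character(),
                  start = integer(), end = integer(), n_tags = integer(),
                  total_count = numeric())
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$total_count))
  attr(out, "transcript_calls") <- dplyr::bind_rows(calls)
  attr(out, "thresholds") <- list(
    breadth_threshold = breadth_threshold, max_loci = max_loci,
    max_locus_width = max_locus_width, merge_gap = merge_gap,
    weight_by_count = weight_by_count
  )
  out
}

#' @rdname discover_novel
#' @param x output of [discover_novel()].
#' @export
transcript_calls <- function(x) attr(x, "transcript_calls")

#' Provisional names for novel miRNA candidates
#'
#' Candidates are searched against the mature miRNA database under relaxed
#' homology settings (default: up to 5 mismatches, coverage >= 0.7). A
#' candidate with a best hit inherits the hit's family name
#' (`<prefix>-miR<family>`, letter suffixes by descending count when several
#' candidates share a family); candidates without any hit receive serial
#' names `<prefix>-novel-1`, `-2`, ... in descending count order.
#'
#' @param candidates [discover_novel()] output.
#' @param mature mature-miRNA [reference_set()].
#' @param prefix species prefix (default `"ecu"`).
#' @param max_mismatch,min_coverage relaxed homology thresholds.
#' @return `candidates` with `name` and `homolog` columns added.
#' @export
name_novel <- function(candidates, mature, prefix = "ecu",
                       max_mismatch = 5, min_coverage = 0.7) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, name = character(0), homolog = character(0)))
  }
  hits <- classify_conserved(candidates$sequence, mature,
                             max_mismatch = max_mismatch,
                             min_coverage = min_coverage)
  best <- if (nrow(hits)) .best_hits(hits) else
    tibble(sequence = character(), db_id = character(), family = character())
  out <- candidates |>
    dplyr::left_join(dplyr::select(best, "sequence", homolog = "db_id",
                                   family = "family"),
                     by = "sequence") |>
    dplyr::arrange(dplyr::desc(.data$total_count))
  named <- character(nrow(out))
  with_fam <- !is.na(out$family)
  for (fam in unique(out$family[with_fam])) {
    idx <- which(with_fam & out$family == fam)
    named[idx] <- if (length(idx) == 1) {
      paste0(prefix, "-", fam)
    } else {
      paste0(prefix, "-", fam, letters[seq_along(idx)])
    }
  }
  named[!with_fam] <- paste0(prefix, "-novel-", seq_len(sum(!with_fam)))
  out$name <- named
  dplyr::select(out, -"family")
}
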