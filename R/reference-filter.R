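#' End-to-end ungapped matching of tags against a reference set
#'
#' Finds every position (and strand, per the reference's strand policy) where
#' a tag aligns end-to-end against a reference sequence with at most
#' `max_mismatch` substitutions — the in-package equivalent of a
#' zero/low-mismatch short-read aligner run used for contamination
#' subtraction. Correctness is defined by the exhaustive sliding-window scan
#' over all offsets and strands; the implementation uses Biostrings
#' dictionary/pattern matching and is tested against a brute-force oracle.
#'
#' @param tags character vector of tag sequences, or a tag table with a
#'   `sequence` column.
#' @param ref a [reference_set()].
#' @param max_mismatch maximum substitutions (>= 0).
#' @return tibble with columns `sequence`, `ref_id`, `strand`, `start`
#'   (1-based, on the reference forward strand), `end`, `mismatches`.
#' @export
ungapped_match <- function(tags, ref, max_mismatch = 0) {
  if (max_mismatch < 0) abort("`max_mismatch` must be >= 0.")
  stopifnot(inherits(ref, "reference_set"))
  seqs <- .tag_sequences(tags)
  seqs <- seqs[nchar(seqs) > 0]
  if (length(seqs) == 0 || nrow(ref) == 0) {
    return(tibble(sequence = character(), ref_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  mismatches = integer()))
  }
  strands <- if (attr(ref, "strand_policy") == "both") c("+", "-") else "+"

  out <- vector("list", nrow(ref) * length(strands))
  k <- 0L
  for (j in seq_len(nrow(ref))) {
    subject <- ref$sequence[j]
    for (strand in strands) {
      qry <- if (strand == "+") seqs else revcomp(seqs)
      hits <- .match_end_to_end(qry, subject, max_mismatch)
      if (nrow(hits) == 0) next
      k <- k + 1L
      out[[k]] <- tibble(
        sequence = seqs[hits$query],
        ref_id = ref$id[j],
        strand = strand,
        start = hits$start,
        end = hits$start + nchar(seqs[hits$query]) - 1L,
        mismatches = hits$mismatches
      )
    }
  }
  if (k == 0L) {
    return(tibble(sequence = character(), ref_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  mismatches = integer()))
  }
  dplyr::bind_rows(out[seq_len(k)])
}

# match a character vector of queries end-to-end against one subject string;
# returns a data frame (query index, start, mismatches). Exact matching uses
# a substring hash over the subject (one `match()` per tag width); mismatch
# matching delegates to Biostrings pattern matching.
.match_end_to_end <- function(qry, subject, max_mismatch) {
  empty <- data.frame(query = integer(), start = integer(),
                      mismatches = integer())
  L <- nchar(subject)
  if (max_mismatch == 0) {
    res <- list()
    for (w in unique(nchar(qry))) {
      if (w > L) next
      idx <- which(nchar(qry) == w)
      subs <- substring(subject, 1:(L - w + 1L), w:L)
      m <- match(subs, qry[idx])
      found <- which(!is.na(m))
      if (length(found)) {
        res[[length(res) + 1L]] <- data.frame(
          query = idx[m[found]], start = found, mismatches = 0L
        )
      }
    }
    if (!length(res)) return(empty)
    return(do.call(rbind, res))
  }
  subj <- Biostrings::DNAString(subject)
  res <- list()
  for (i in seq_along(qry)) {
    pat <- Biostrings::DNAString(qry[i])
    if (length(pat) > L) next
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
    if (length(m) == 0) next
    st <- Biostrings::start(m)
    mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st)
    res[[length(res) + 1L]] <- data.frame(query = i, start = st, mismatches = mm)
  }
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

#' Subtract tags matching a reference set
#'
#' Removes every tag with at least one ungapped end-to-end match to the
#' reference (an exact partition: each input tag is either aligned or not) and
#' records a per-library stage report row with aligned / non-aligned counts
#' and percentages of the stage input.
#'
#' @param tags tag table (long format: `sequence`, `library`, `count`).
#' @param ref a [reference_set()].
#' @param max_mismatch maximum substitutions for a subtraction hit. The
#'   default 0 mirrors the zero-mismatch aligner setting conventionally used
#'   for contamination filtering.
#' @param stage stage name recorded in the report (defaults to the reference
#'   set name).
#' @return the non-aligned tags; stage rows accumulate in the
#'   `"depuration"` attribute.
#' @export
subtract_reference <- function(tags, ref, max_mismatch = 0, stage = NULL) {
  stage <- stage %||% attr(ref, "name")
  hits <- ungapped_match(tags, ref, max_mismatch)
  aligned_seqs <- unique(hits$sequence)
  is_aligned <- tags$sequence %in% aligned_seqs
  report <- tags |>
    dplyr::mutate(aligned = is_aligned) |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(
      input_tags = dplyr::n(),
      aligned = sum(.data$aligned),
      non_aligned = .data$input_tags - .data$aligned,
      pct_aligned = round(100 * .data$aligned / .data$input_tags, 2),
      pct_non_aligned = round(100 * .data$non_aligned / .data$input_tags, 2),
      .groups = "drop"
    ) |>
    dplyr::mutate(stage = stage, .before = 1)
  kept <- tags[!is_aligned, , drop = FALSE]
  attr(kept, "depuration") <- dplyr::bind_rows(attr(tags, "depuration"), report)
  kept
}

#' Depure the tag set against organellar and ncRNA references
#'
#' Applies the three contamination subtractions in the fixed order
#' mitochondria -> chloroplast -> ncRNA (so reported percentages nest, each
#' relative to its stage input), then appends the final depured tag counts and
#' percentages relative to the processed input. The remaining "depured" tags
#' are the substrate for miRNA annotation.
#'
#' @param tags tag table after [filter_min_count()].
#' @param mitochondria,chloroplast,ncrna the three [reference_set()]s.
#' @param max_mismatch maximum substitutions for subtraction hits (default 0).
#' @return the depured tags with attribute `"depuration_report"`, retrievable
#'   with [depuration_report()].
#' @export
depure <- function(tags, mitochondria, chloroplast, ncrna, max_mismatch = 0) {
  for (r in list(mitochondria, chloroplast, ncrna)) {
    if (!inherits(r, "reference_set")) {
      abort("`mitochondria`, `chloroplast` and `ncrna` must be reference_set objects.")
    }
  }
  input <- tags |> dplyr::count(.data$library, name = "processed_tags")
  out <- tags |>
    subtract_reference(mitochondria, max_mismatch, stage = "mitochondria") |>
    subtract_reference(chloroplast, max_mismatch, stage = "chloroplast") |>
    subtract_reference(ncrna, max_mismatch, stage = "ncRNA")
  final <- out |>
    dplyr::count(.data$library, name = "depured_tags") |>
    dplyr::left_join(input, by = "library") |>
    dplyr::mutate(pct_depured = round(100 * .data$depured_tags /
                                        .data$processed_tags, 2))
  report <- list(stages = attr(out, "depuration"), depured = final)
  attr(out, "depuration") <- NULL
  attr(out, "depuration_report") <- report
  out
}

#' @rdname depure
#' @param x output of [depure()].
#' @export
depuration_report <- function(x) attr(x, "depuration_report")
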