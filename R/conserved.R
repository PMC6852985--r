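#' Classify tags as conserved miRNAs by ungapped homology
#'
#' A depured tag is classified as a conserved miRNA when it has at least one
#' maximal ungapped local alignment to a mature or hairpin miRNA database
#' entry with at most `max_mismatch` substitutions and coverage (aligned
#' length / tag length) of at least `min_coverage`. Tags may overhang either
#' end of a database entry; coverage is defined against the tag so that tags
#' shorter than a hairpin can still reach full coverage. Matching is
#' forward-strand only, as mature miRNA databases are single-stranded.
#'
#' @param tags character vector of tag sequences or a tag table with a
#'   `sequence` column.
#' @param mature mature-miRNA [reference_set()].
#' @param hairpin optional hairpin/precursor [reference_set()].
#' @param max_mismatch maximum substitutions (default 2).
#' @param min_coverage minimum tag coverage in (0, 1] (default 0.90).
#' @return tibble with one row per qualifying hit: `sequence`, `db_id`,
#'   `db_class` (`"mature"`/`"hairpin"`), `offset` (0-based position of tag
#'   base 1 in database coordinates; negative = 5' overhang),
#'   `aligned_length`, `mismatches`, `coverage`.
#' @export
#' @examples
#' db <- reference_set(c(`ata-miR2275a-3p` = "UUUGUUUUUCUCCAAUAUCUCAU"),
#'                     "mature", "mirna-mature")
#' classify_conserved("UUGUUUUUCUCCAAUAUCUCA", db)
classify_conserved <- function(tags, mature, hairpin = NULL,
                               max_mismatch = 2, min_coverage = 0.90) {
  if (min_coverage <= 0 || min_coverage > 1) {
    abort("`min_coverage` must lie in (0, 1].")
  }
  if (max_mismatch < 0) abort("`max_mismatch` must be >= 0.")
  stopifnot(inherits(mature, "reference_set"))
  seqs <- .tag_sequences(tags)
  dbs <- list(mature = mature)
  if (!is.null(hairpin)) dbs$hairpin <- hairpin

  out <- purrr::imap(dbs, function(db, cls) {
    if (nrow(db) == 0 || length(seqs) == 0) return(NULL)
    hits <- local_scan_cpp(seqs, db$sequence, as.integer(max_mismatch),
                           min_coverage)
    if (nrow(hits) == 0) return(NULL)
    tibble(
      sequence = seqs[hits$tag],
      db_id = db$id[hits$ref],
      db_class = cls,
      offset = hits$offset,
      aligned_length = hits$aligned_length,
      mismatches = hits$mismatches,
      coverage = hits$aligned_length / nchar(seqs[hits$tag])
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(sequence = character(), db_id = character(),
                  db_class = character(), offset = integer(),
                  aligned_length = integer(), mismatches = integer(),
                  coverage = numeric()))
  }
  out
}

# one best hit per tag: mature-set hits take precedence for family naming,
# then fewest mismatches, longest alignment, lexicographically smallest db id
.best_hits <- function(hits) {
  hits |>
    dplyr::mutate(.mature = .data$db_class == "mature") |>
    dplyr::arrange(.data$sequence, dplyr::desc(.data$.mature),
                   .data$mismatches, dplyr::desc(.data$aligned_length),
                   .data$db_id) |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE) |>
    dplyr::select(-".mature") |>
    dplyr::mutate(family = mirna_family(.data$db_id))
}

#' Aggregate conserved-miRNA hits into family summaries
#'
#' Each conserved tag is assigned to the family of its best hit (mature
#' database entries take precedence over hairpin-only hits; ties broken by
#' fewest mismatches, longest alignment, then smallest identifier) and
#' counted once. Families are summarised with member tag counts and summed
#' per-library read counts, ordered by number of member tags. The
#' conserved-miRNA fraction statistics — both over unique tags and over total
#' read counts, the two conventional denominators — are attached as the
#' `"conserved_stats"` attribute.
#'
#' @param hits output of [classify_conserved()].
#' @param tags the depured tag table the hits were computed from (long
#'   format: `sequence`, `library`, `count`).
#' @return tibble with columns `family`, `n_tags`, one count column per
#'   library, plus attribute `"conserved_stats"` (see [conserved_stats()]).
#' @export
summarize_families <- function(hits, tags) {
  lib_levels <- unique(tags$library)
  if (nrow(hits) == 0) {
    empty <- tibble(family = character(), n_tags = integer())
    attr(empty, "conserved_stats") <- tags |>
      dplyr::group_by(.data$library) |>
      dplyr::summarise(depured_tags = dplyr::n(),
                       total_count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(conserved_tags = 0L, pct_conserved_tags = 0,
                    conserved_count = 0, pct_conserved_count = 0)
    return(empty)
  }
  best <- .best_hits(hits)
  member <- dplyr::inner_join(tags, dplyr::select(best, "sequence", "family"),
                              by = "sequence")
  fam <- member |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_tags = dplyr::n_distinct(.data$sequence),
                     .groups = "drop")
  counts <- member |>
    dplyr::group_by(.data$family, .data$library) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "library", values_from = "count",
                       values_fill = 0L)
  out <- fam |>
    dplyr::left_join(counts, by = "family") |>
    dplyr::arrange(dplyr::desc(.data$n_tags), .data$family)

  stats <- tags |>
    dplyr::mutate(conserved = .data$sequence %in% best$sequence) |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(
      depured_tags = dplyr::n(),
      conserved_tags = sum(.data$conserved),
      pct_conserved_tags = round(100 * .data$conserved_tags /
                                   .data$depured_tags, 2),
      total_count = sum(.data$count),
      conserved_count = sum(.data$count[.data$conserved]),
      pct_conserved_count = round(100 * .data$conserved_count /
                                    .data$total_count, 2),
      .groups = "drop"
    )
  stats <- stats[match(lib_levels, stats$library), , drop = FALSE]
  attr(out, "conserved_stats") <- stats
  out
}

#' @rdname summarize_families
#' @param x output of [summarize_families()].
#' @export
conserved_stats <- function(x) attr(x, "conserved_stats")

#' Consensus sequences and species-prefixed names for conserved miRNAs
#'
#' Within each family, member tags are grouped by the database entry of their
#' best hit and aligned at their hit offsets; the consensus is the positional
#' majority over members (ties broken by the member with the larger total
#' count, then alphabetically). Clusters with identical consensus sequences
#' merge, and the surviving clusters receive letter suffixes `a`, `b`, ... in
#' descending total-count order, yielding names such as `ecu-miR2275a`.
#'
#' @param hits output of [classify_conserved()].
#' @param tags the depured tag table (for member counts).
#' @param prefix genus-species prefix for assigned names (default `"ecu"`).
#' @return tibble with columns `name`, `family`, `anchor` (database entry the
#'   cluster is aligned to), `consensus` (RNA alphabet), `n_tags`,
#'   `total_count`.
#' @export
consensus_name <- function(hits, tags, prefix = "ecu") {
  if (nrow(hits) == 0) {
    return(tibble(name = character(), family = character(),
                  anchor = character(), consensus = character(),
                  n_tags = integer(), total_count = numeric()))
  }
  best <- .best_hits(hits)
  tag_count <- tags |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(total_count = sum(.data$count), .groups = "drop")
  best <- dplyr::left_join(best, tag_count, by = "sequence") |>
    dplyr::mutate(total_count = dplyr::coalesce(.data$total_count, 0))

  clusters <- best |>
    dplyr::group_by(.data$family, .data$db_id) |>
    dplyr::group_map(function(g, key) {
      span0 <- min(g$offset)
      span1 <- max(g$offset + nchar(g$sequence))
      width <- span1 - span0
      cons <- character(width)
      for (p in seq_len(width)) {
        pos <- span0 + p - 1L              # db coordinate of this column
        i <- pos - g$offset + 1L           # 1-based position within each tag
        here <- i >= 1L & i <= nchar(g$sequence)
        if (!any(here)) next
        base <- substring(g$sequence[here], i[here], i[here])
        wt <- g$total_count[here]
        votes <- tapply(rep(1L, length(base)), base, sum)
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1L) {
          # tie: prefer the base of the most abundant member, then A<C<G<T
          by_count <- tapply(wt, base, max)[top]
          top <- sort(top[by_count == max(by_count)])[1]
        }
        cons[p] <- top
      }
      tibble(
        family = key$family, anchor = key$db_id,
        consensus = paste(cons[nzchar(cons)], collapse = ""),
        n_tags = nrow(g), total_count = sum(g$total_count)
      )
    }) |>
    dplyr::bind_rows()

  clusters |>
    dplyr::group_by(.data$family, .data$consensus) |>
    dplyr::summarise(
      anchor = .data$anchor[which.max(.data$total_count)],
      n_tags = sum(.data$n_tags), total_count = sum(.data$total_count),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$family) |>
    dplyr::arrange(dplyr::desc(.data$total_count), .by_group = TRUE) |>
    dplyr::mutate(name = paste0(prefix, "-", .data$family,
                                letters[dplyr::row_number()])) |>
    dplyr::ungroup() |>
    dplyr::mutate(consensus = chartr("T", "U", .data$consensus)) |>
    dplyr::select("name", "family", "anchor", "consensus", "n_tags",
                  "total_count")
}
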