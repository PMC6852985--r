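#' Parameters for miRNA-target complementarity scoring
#'
#' The scoring scheme follows the plant-target-prediction convention: the
#' miRNA is aligned antiparallel to a transcript window and accumulates an
#' expectation penalty per position — 0 for a Watson-Crick pair, 0.5 for a
#' G:U wobble, 1.0 for a mismatch, 2.0 for a bulged (unpaired) miRNA base —
#' with penalties doubled inside the seed region (miRNA positions 2-13 from
#' the 5' end). A duplex is rejected outright if any true mismatch (non-WC,
#' non-wobble) falls in the seed, if the alignment would require a bulge on
#' the target side, or if the total expectation exceeds `max_expectation`.
#' A non-WC pair in the central window (positions 9-11) switches the
#' predicted inhibition mode from cleavage to translational inhibition.
#'
#' @param max_expectation maximum accepted expectation penalty (default 2.5).
#' @param hsp_size window length used for complementarity scoring (default
#'   20 nt).
#' @param seed_start,seed_end seed region, 1-based miRNA positions from the
#'   5' end (default 2-13).
#' @param seed_mismatches_allowed true mismatches allowed in the seed
#'   (default 0; wobbles are allowed but penalized).
#' @param central_start,central_end central window whose non-WC pairs call
#'   translational inhibition (default 9-11; must lie within the seed).
#' @param upe_max maximum energy to unpair the target site (accessibility
#'   filter, default 20).
#' @param flank_up,flank_down flanking lengths around the site used for the
#'   accessibility computation (defaults 17 and 13 nt).
#' @param target_bulges_allowed whether bulges on the target sequence are
#'   allowed (default `FALSE`).
#' @param penalty_mismatch,penalty_gu,penalty_bulge,seed_multiplier penalty
#'   table (defaults 1.0, 0.5, 2.0, 2.0).
#' @param max_mirna_bulges maximum bulged miRNA bases per duplex (default 1).
#' @return a list of class `scoring_params`.
#' @export
scoring_params <- function(max_expectation = 2.5, hsp_size = 20,
                           seed_start = 2, seed_end = 13,
                           seed_mismatches_allowed = 0,
                           central_start = 9, central_end = 11,
                           upe_max = 20, flank_up = 17, flank_down = 13,
                           target_bulges_allowed = FALSE,
                           penalty_mismatch = 1.0, penalty_gu = 0.5,
                           penalty_bulge = 2.0, seed_multiplier = 2.0,
                           max_mirna_bulges = 1) {
  p <- list(
    max_expectation = max_expectation, hsp_size = hsp_size,
    seed_start = seed_start, seed_end = seed_end,
    seed_mismatches_allowed = seed_mismatches_allowed,
    central_start = central_start, central_end = central_end,
    upe_max = upe_max, flank_up = flank_up, flank_down = flank_down,
    target_bulges_allowed = target_bulges_allowed,
    penalty_mismatch = penalty_mismatch, penalty_gu = penalty_gu,
    penalty_bulge = penalty_bulge, seed_multiplier = seed_multiplier,
    max_mirna_bulges = max_mirna_bulges
  )
  nonneg <- c("max_expectation", "upe_max", "flank_up", "flank_down",
              "penalty_mismatch", "penalty_gu", "penalty_bulge",
              "seed_multiplier")
  if (any(unlist(p[nonneg]) < 0)) abort("Thresholds and penalties must be non-negative.")
  if (central_start < seed_start || central_end > seed_end) {
    abort("The central window must lie within the seed region.")
  }
  if (seed_start < 1 || seed_end < seed_start) abort("Invalid seed region.")
  structure(p, class = "scoring_params")
}

# Vectorized screen over all window offsets of one width: returns the offsets
# that could possibly be accepted, using a lower bound on the number of
# non-Watson-Crick pairs. Every surviving offset is re-scored exactly, so the
# screen never changes results — each non-WC pair costs at least
# min(penalty_gu, penalty_mismatch) and a bulged variant additionally costs at
# least penalty_bulge, bounding how many non-WC pairs an accepted duplex can
# contain.
.candidate_offsets <- function(mv, txv, w, params) {
  n <- length(mv)
  L <- length(txv)
  S <- L - w + 1L
  if (S < 1L) return(integer())
  min_cost <- min(params$penalty_gu, params$penalty_mismatch)
  if (min_cost <= 0) return(seq_len(S))
  cm <- unname(.comp[mv])
  if (w == n) {
    idx <- outer(-seq_len(n), seq_len(S), "+") + n   # [i, s] -> s + n - i
    bad <- matrix(txv[idx] != cm, n, S)
    max_bad <- floor(params$max_expectation / min_cost)
    return(which(colSums(bad) <= max_bad))
  }
  # one bulged miRNA base (w == n - 1): pairing agrees with the "bulge last"
  # variant left of the bulge and the "bulge first" variant right of it, so a
  # position that is non-WC in both variants stays non-WC wherever the bulge
  # lands (minus the one position the bulge itself absorbs)
  budget <- params$max_expectation - params$penalty_bulge
  if (budget < 0) return(integer())
  idx_e <- outer(-seq_len(n - 1L), seq_len(S), "+") + n - 1L
  bad_e <- matrix(txv[idx_e] != cm[seq_len(n - 1L)], n - 1L, S)
  idx_b <- outer(-(2:n), seq_len(S), "+") + n
  bad_b <- matrix(txv[idx_b] != cm[2:n], n - 1L, S)
  mid <- if (n > 2L) {
    colSums(bad_e[-1L, , drop = FALSE] & bad_b[-(n - 1L), , drop = FALSE])
  } else 0L
  lower <- bad_e[1L, ] + bad_b[n - 1L, ] + mid - 1L
  max_bad <- floor(budget / min_cost)
  which(lower <= max_bad)
}

# classify pairs of (miRNA base, opposite target base): WC / GU / MM
.pair_class <- function(m, t) {
  wc <- t == .comp[m]
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

.PAIR_SYMBOL <- c(WC = "|", GU = "o", MM = "x", BULGE = "-")

#' Score one miRNA-target duplex
#'
#' Aligns the miRNA (5'->3') antiparallel against a transcript window
#' (3'->5') and computes the expectation penalty described in
#' [scoring_params()]. A window one base shorter than the miRNA is scored by
#' trying every interior bulged miRNA position and keeping the cheapest
#' accepted variant; windows longer than the miRNA would require target-side
#' bulges and are rejected.
#'
#' @param mirna miRNA sequence, 5'->3' (17-26 nt; RNA or DNA alphabet).
#' @param window transcript subsequence (5'->3').
#' @param params a [scoring_params()].
#' @return a list of class `duplex_score`: `accepted`, `expectation`,
#'   `mode` (`"cleavage"` / `"translational-inhibition"` / `NA` if rejected),
#'   `pairing` (per-miRNA-position classes `WC`/`GU`/`MM`/`BULGE`),
#'   `pairing_string` (compact rendering, 5'->3': `|` WC, `o` G:U, `x`
#'   mismatch, `-` bulge), `reject_reason`.
#' @export
#' @examples
#' p <- scoring_params()
#' m <- "UGGAAGACUAGUGAUUUUGUUGU"
#' score_duplex(substr(m, 1, 21), revcomp(substr(m, 1, 21)), p)$expectation
score_duplex <- function(mirna, window, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  m <- as_dna(mirna); w <- as_dna(window)
  if (grepl("[^ACGT]", m) || grepl("[^ACGT]", w)) {
    abort("Sequences must be over the A/C/G/T(U) alphabet.")
  }
  n <- nchar(m)
  if (n < 17 || n > 26) abort("miRNA length must be 17-26 nt.")
  res <- .score_variants(strsplit(m, "")[[1]], strsplit(w, "")[[1]], params)
  res
}

# core scorer on character vectors; returns the best accepted variant or a
# rejection record
.score_variants <- function(mv, wv, params) {
  n <- length(mv)
  Lw <- length(wv)
  seed <- seq(params$seed_start, min(params$seed_end, n))
  central <- seq(params$central_start, min(params$central_end, n))
  mult <- rep(1, n); mult[seed] <- params$seed_multiplier

  reject <- function(reason) {
    structure(list(accepted = FALSE, expectation = NA_real_, mode = NA_character_,
                   pairing = NULL, pairing_string = NA_character_,
                   reject_reason = reason), class = "duplex_score")
  }
  if (Lw > n) {
    if (!params$target_bulges_allowed) return(reject("target_bulge_required"))
    return(reject("target_bulges_unsupported"))
  }
  n_bulge <- n - Lw
  if (n_bulge > params$max_mirna_bulges) return(reject("window_too_short"))

  eval_variant <- function(bulge_at) {
    pairing <- character(n)
    pen <- numeric(n)
    paired <- setdiff(seq_len(n), bulge_at)
    rank <- seq_along(paired)                    # position in the window pairing
    tpos <- Lw - rank + 1L                       # antiparallel target index
    cls <- .pair_class(mv[paired], wv[tpos])
    pairing[paired] <- cls
    pen[paired] <- c(WC = 0, GU = params$penalty_gu,
                     MM = params$penalty_mismatch)[cls]
    if (length(bulge_at)) {
      pairing[bulge_at] <- "BULGE"
      pen[bulge_at] <- params$penalty_bulge
    }
    if (sum(pairing[seed] == "MM") > params$seed_mismatches_allowed) {
      return(NULL)
    }
    expectation <- sum(pen * mult)
    if (expectation > params$max_expectation) return(NULL)
    mode <- if (any(pairing[central] != "WC")) "translational-inhibition" else "cleavage"
    list(expectation = expectation, pairing = pairing, mode = mode)
  }

  variants <- if (n_bulge == 0L) {
    list(eval_variant(integer(0)))
  } else {
    # one bulged miRNA base; terminal bases cannot bulge
    lapply(2:(n - 1L), function(k) eval_variant(k))
  }
  variants <- variants[!vapply(variants, is.null, logical(1))]
  if (!length(variants)) {
    # distinguish seed rejection from expectation rejection for the no-bulge case
    return(reject("seed_mismatch_or_expectation"))
  }
  best <- variants[[which.min(vapply(variants, `[[`, numeric(1), "expectation"))]]
  structure(list(
    accepted = TRUE, expectation = best$expectation, mode = best$mode,
    pairing = best$pairing,
    pairing_string = paste(.PAIR_SYMBOL[best$pairing], collapse = ""),
    reject_reason = NA_character_
  ), class = "duplex_score")
}

#' Inhibition mode of an accepted duplex
#'
#' Translational inhibition is called when any non-Watson-Crick pair (wobble
#' or bulge) occupies the central window; otherwise the duplex is predicted
#' to direct cleavage.
#'
#' @param duplex a `duplex_score` from [score_duplex()].
#' @param params a [scoring_params()].
#' @return `"cleavage"` or `"translational-inhibition"`.
#' @export
call_mode <- function(duplex, params = scoring_params()) {
  if (!isTRUE(duplex$accepted)) abort("Mode is defined only for accepted duplexes.")
  central <- seq(params$central_start,
                 min(params$central_end, length(duplex$pairing)))
  if (any(duplex$pairing[central] != "WC")) "translational-inhibition" else "cleavage"
}

#' Deterministic site-accessibility stub backend
#'
#' A sequence-composition heuristic for the energy required to unpair a
#' target site plus flanks: 0.3 per G/C and 0.1 per A/T base. It is a
#' deterministic, dependency-free backend for tests and default pipelines;
#' plug in a partition-function folder via the `upe_backend` argument of
#' [scan_transcript()] for thermodynamic accessibility.
#'
#' @param x character vector of site-plus-flank sequences.
#' @return numeric vector of opening energies.
#' @export
upe_stub <- function(x) {
  x <- as_dna(x)
  gc <- nchar(gsub("[^GC]", "", x))
  at <- nchar(gsub("[^AT]", "", x))
  0.3 * gc + 0.1 * at
}

#' Scan a transcript for miRNA target sites
#'
#' Evaluates every window offset of the transcript (window lengths equal to
#' the miRNA length and, when miRNA bulges are permitted, one base shorter),
#' scores each with [score_duplex()]'s rules, and reduces overlapping
#' accepted sites to the local-minimum-expectation site. When an
#' accessibility backend is supplied, sites whose opening energy over the
#' site plus `flank_up`/`flank_down` flanks exceeds `upe_max` are removed.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcript transcript sequence (5'->3'), at least `hsp_size` long.
#' @param params a [scoring_params()].
#' @param upe_backend optional function mapping site-plus-flank sequences to
#'   opening energies (e.g. [upe_stub()]).
#' @param filter_upe apply the `upe_max` filter (requires a backend).
#' @return tibble with columns `start`, `end` (0-based half-open transcript
#'   coordinates), `expectation`, `mode`, `upe` (`NA` without a backend),
#'   `pairing` (compact duplex rendering, miRNA 5'->3').
#' @export
scan_transcript <- function(mirna, transcript, params = scoring_params(),
                            upe_backend = NULL, filter_upe = !is.null(upe_backend)) {
  stopifnot(inherits(params, "scoring_params"))
  if (filter_upe && is.null(upe_backend)) {
    abort("UPE filtering requested but no accessibility backend supplied.")
  }
  m <- as_dna(mirna); tx <- as_dna(transcript)
  n <- nchar(m); L <- nchar(tx)
  if (L < params$hsp_size) abort("Transcript shorter than the scoring window.")
  mv <- strsplit(m, "")[[1]]
  txv <- strsplit(tx, "")[[1]]

  widths <- n
  if (params$max_mirna_bulges >= 1L && n - 1L >= 1L) widths <- c(n, n - 1L)
  cand <- list()
  for (w in widths) {
    if (w > L) next
    offsets <- .candidate_offsets(mv, txv, w, params)
    for (s in offsets) {
      sc <- .score_variants(mv, txv[s:(s + w - 1L)], params)
      if (sc$accepted) {
        cand[[length(cand) + 1L]] <- tibble(
          start = s - 1L, end = s - 1L + w,
          expectation = sc$expectation, mode = sc$mode,
          pairing = sc$pairing_string
        )
      }
    }
  }
  empty <- tibble(start = integer(), end = integer(), expectation = numeric(),
                  mode = character(), upe = numeric(), pairing = character())
  if (!length(cand)) return(empty)
  cand <- dplyr::bind_rows(cand) |>
    dplyr::arrange(.data$expectation, .data$start)

  # greedy reduction: keep each local-minimum-expectation site, drop overlaps
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < taken_end & cand$end[i] > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  sites <- cand[keep, , drop = FALSE] |> dplyr::arrange(.data$start)

  if (!is.null(upe_backend)) {
    flank_seq <- substring(tx, pmax(1L, sites$start + 1L - params$flank_up),
                        pmin(L, sites$end + params$flank_down))
    sites$upe <- upe_backend(flank_seq)
    if (filter_upe) sites <- dplyr::filter(sites, .data$upe <= params$upe_max)
  } else {
    sites$upe <- NA_real_
  }
  dplyr::select(sites, "start", "end", "expectation", "mode", "upe", "pairing")
}

#' Predict target sites for a set of miRNAs across a transcriptome
#'
#' @param mirnas named character vector of miRNA sequences, or a tibble with
#'   `id` and `sequence` columns.
#' @param transcriptome a [reference_set()] of transcripts.
#' @inheritParams scan_transcript
#' @return tibble with `mirna_id`, `transcript_id` and the [scan_transcript()]
#'   columns.
#' @export
predict_targets <- function(mirnas, transcriptome, params = scoring_params(),
                            upe_backend = NULL,
                            filter_upe = !is.null(upe_backend)) {
  if (is.data.frame(mirnas)) mirnas <- setNames(mirnas$sequence, mirnas$id)
  stopifnot(inherits(transcriptome, "reference_set"))
  purrr::imap_dfr(mirnas, function(mseq, mid) {
    purrr::map_dfr(seq_len(nrow(transcriptome)), function(j) {
      if (nchar(transcriptome$sequence[j]) < params$hsp_size) return(NULL)
      sites <- scan_transcript(mseq, transcriptome$sequence[j], params,
                               upe_backend, filter_upe)
      if (nrow(sites) == 0) return(NULL)
      dplyr::mutate(sites, mirna_id = mid,
                    transcript_id = transcriptome$id[j], .before = 1)
    })
  })
}

#' Link miRNA differential expression to target transcript presence
#'
#' Emits the interaction logic used to nominate repression-consistent
#' miRNA-mRNA pairs: a miRNA over-expressed in genotype A whose target is
#' detected only in genotype B is flagged `"repression-consistent"`; if the
#' target is detected in both genotypes the pair is flagged `"partial"`
#' (repression cannot be attributed exclusively to the miRNA); otherwise
#' `"inconsistent"`. miRNAs without a differential-expression call produce no
#' rows.
#'
#' @param targets tibble with `mirna_id` and `transcript_id` (e.g.
#'   [predict_targets()] output).
#' @param mirna_de tibble with `mirna_id` and `up_in` (genotype the miRNA is
#'   over-expressed in; `NA` or missing rows mean not differentially
#'   expressed).
#' @param transcript_presence tibble with `transcript_id`, `genotype`,
#'   `detected` (logical).
#' @return tibble with `mirna_id`, `transcript_id`, `mirna_up_in`,
#'   `target_detected_in`, `status`.
#' @export
link_expression <- function(targets, mirna_de, transcript_presence) {
  de <- dplyr::filter(mirna_de, !is.na(.data$up_in))
  out <- targets |>
    dplyr::distinct(.data$mirna_id, .data$transcript_id) |>
    dplyr::inner_join(de, by = "mirna_id")
  if (nrow(out) == 0) {
    return(tibble(mirna_id = character(), transcript_id = character(),
                  mirna_up_in = character(), target_detected_in = character(),
                  status = character()))
  }
  pres <- transcript_presence |>
    dplyr::filter(.data$detected) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(detected_in = list(unique(.data$genotype)), .groups = "drop")
  out |>
    dplyr::left_join(pres, by = "transcript_id") |>
    dplyr::mutate(
      detected_in = purrr::map(.data$detected_in, ~ .x %||% character()),
      target_detected_in = purrr::map_chr(
        .data$detected_in,
        ~ if (length(.x)) paste(sort(.x), collapse = "+") else "none"
      ),
      status = purrr::map2_chr(.data$up_in, .data$detected_in, function(up, det) {
        if (length(det) == 0) return("inconsistent")
        if (up %in% det) {
          if (length(det) > 1) "partial" else "inconsistent"
        } else {
          if (length(det) >= 1) "repression-consistent" else "inconsistent"
        }
      }),
      mirna_up_in = .data$up_in
    ) |>
    dplyr::select("mirna_id", "transcript_id", "mirna_up_in",
                  "target_detected_in", "status")
}
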