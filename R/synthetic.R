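#' Configuration for the synthetic small-RNA study
#'
#' Builds the parameter object that fully determines a synthetic four-library
#' experiment (two genotypes x two biological replicates). The defaults emulate
#' the marginal statistics of real spikelet small-RNA libraries at desk scale:
#' bimodal insert lengths peaking at 21 and 24 nt, ~0.5% organellar reads,
#' ~4.5% ncRNA reads, ~0.4% conserved-miRNA reads, a degradation-tiled
#' transcript fraction, planted novel-miRNA loci, and a singleton-heavy random
#' background so that roughly a fifth of reads fall below the minimum tag
#' count. Genotype-specific fold changes are planted on named tag classes.
#'
#' @param seed integer seed; together with the other fields it fully
#'   determines every downstream output (FASTA, FASTQ and truth tables are
#'   byte-identical across reruns).
#' @param n_reads_per_library reads simulated per library (> 0).
#' @param length_modes insert-length modes of the random background, within
#'   17-33 nt.
#' @param length_mode_weights mixture weights for `length_modes` (sum to 1).
#' @param adapter 3' adapter sequence ligated to every insert (>= 8 nt). The
#'   default is the standard Illumina small-RNA 3' adapter.
#' @param frac_organellar,frac_ncrna,frac_conserved_mirna,frac_degradation,frac_novel_mirna,frac_random
#'   expected read fractions of the six tag classes; must sum to 1 (1e-9
#'   tolerance).
#' @param n_mirna_families number of conserved miRNA families planted (>= 1).
#' @param n_transcripts transcriptome size.
#' @param n_degradation_transcripts transcripts tiled with degradation windows.
#' @param n_novel_loci planted novel-miRNA loci (each an exact 21-nt substring
#'   of one transcript).
#' @param n_planted_targets transcripts carrying a perfect complementary site
#'   for one of the planted mature miRNAs.
#' @param n_spike_tags abundant background tags available for planting
#'   differential expression.
#' @param planted_de tibble with columns `id`, `genotype`, `log2fc`: the
#'   abundance of the named tag class is multiplied by `2^log2fc` in libraries
#'   of that genotype. Defaults plant `|log2fc| = 3` on two novel loci and the
#'   ten spike tags, balanced across genotypes.
#' @param mismatch_profile named probabilities over 0-3 mismatches for
#'   conserved-miRNA sequence variants.
#' @param read_length instrument read length; 50 nt so that every insert
#'   (<= 33 nt) carries adapter sequence and the trimmer is always exercised.
#' @param library_design tibble with columns `library`, `genotype`,
#'   `replicate`; the default mirrors a 2 genotype x 2 replicate spikelet
#'   design (`O2P1`, `O2P2` sexual; `T3P1`, `T3P2` apomictic).
#' @return an object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_reads_per_library = 1000)
#' cfg$frac_random
sim_config <- function(seed = 1,
                       n_reads_per_library = 20000,
                       length_modes = c(21L, 24L),
                       length_mode_weights = c(0.55, 0.45),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       frac_organellar = 0.005,
                       frac_ncrna = 0.045,
                       frac_conserved_mirna = 0.004,
                       frac_degradation = 0.20,
                       frac_novel_mirna = 0.006,
                       frac_random = 0.74,
                       n_mirna_families = 5,
                       n_transcripts = 60,
                       n_degradation_transcripts = 6,
                       n_novel_loci = 4,
                       n_planted_targets = 3,
                       n_spike_tags = 10,
                       planted_de = NULL,
                       mismatch_profile = c("0" = 0.55, "1" = 0.25, "2" = 0.15, "3" = 0.05),
                       read_length = 50,
                       library_design = NULL) {
  fracs <- c(
    organellar = frac_organellar, ncrna = frac_ncrna,
    conserved = frac_conserved_mirna, degradation = frac_degradation,
    novel = frac_novel_mirna, random = frac_random
  )
  if (any(fracs < 0)) abort("Class fractions must be non-negative.")
  if (abs(sum(fracs) - 1) > 1e-9) {
    abort(sprintf("Class fractions must sum to 1 (got %.12f).", sum(fracs)))
  }
  if (any(length_modes < 17L | length_modes > 33L)) {
    abort("Length modes must lie within the 17-33 nt window.")
  }
  if (length(length_mode_weights) != length(length_modes) ||
      abs(sum(length_mode_weights) - 1) > 1e-9) {
    abort("`length_mode_weights` must match `length_modes` and sum to 1.")
  }
  adapter <- as_dna(adapter)
  if (nchar(adapter) < 8) abort("`adapter` must be at least 8 nt.")
  .check_scalar(seed, "number", is.numeric)
  .check_scalar(n_mirna_families, "positive integer", function(x) x >= 1)
  if (abs(sum(mismatch_profile) - 1) > 1e-9 ||
      !identical(sort(names(mismatch_profile)), c("0", "1", "2", "3"))) {
    abort("`mismatch_profile` must be named '0'..'3' and sum to 1.")
  }
  if (is.null(library_design)) {
    library_design <- tibble(
      library = c("O2P1", "O2P2", "T3P1", "T3P2"),
      genotype = c("sexual", "sexual", "apomictic", "apomictic"),
      replicate = c(1L, 2L, 1L, 2L)
    )
  }
  if (is.null(planted_de)) {
    planted_de <- tibble(
      id = c("novel-1", "novel-2", paste0("spike-", seq_len(n_spike_tags))),
      genotype = c("sexual", "sexual",
                   rep(c("sexual", "apomictic"), length.out = n_spike_tags)),
      log2fc = 3
    )
  }
  structure(list(
    seed = as.integer(seed),
    n_reads_per_library = n_reads_per_library,
    length_modes = as.integer(length_modes),
    length_mode_weights = length_mode_weights,
    adapter = adapter,
    fractions = fracs,
    n_mirna_families = as.integer(n_mirna_families),
    n_transcripts = as.integer(n_transcripts),
    n_degradation_transcripts = as.integer(n_degradation_transcripts),
    n_novel_loci = as.integer(n_novel_loci),
    n_planted_targets = as.integer(n_planted_targets),
    n_spike_tags = as.integer(n_spike_tags),
    planted_de = planted_de,
    mismatch_profile = mismatch_profile[c("0", "1", "2", "3")],
    read_length = as.integer(read_length),
    library_design = library_design
  ), class = "sim_config")
}

# deterministic random DNA strings
.rand_seq <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# substitute `m` random positions of `x` with a different base
.mutate_seq <- function(x, m) {
  if (m == 0L) return(x)
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), m)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# family numbers and species prefixes used for plausible database identifiers
.FAMILY_NUMBERS <- c(156L, 2275L, 396L, 827L, 169L, 894L, 8175L, 5072L, 5049L, 821L)
.SPECIES_PREFIXES <- c("ata", "osa", "zma", "bdi", "gma")

#' Generate the synthetic reference sets
#'
#' Builds the five reference collections a real analysis would download
#' (organellar genomes, ncRNA families, mature and hairpin miRNA databases,
#' reference transcriptome) together with a reference-level truth table: which
#' transcript carries each planted novel-miRNA locus, which transcripts are
#' degradation-designated, and where perfect target sites for the planted
#' mature miRNAs were embedded.
#'
#' All sequences are random under the configuration seed; each planted novel
#' locus is an exact 21-nt substring of its transcript and each mature miRNA
#' belongs to a named family with a matching hairpin entry (5' flank + mature +
#' loop + reverse complement + 3' flank).
#'
#' @param config a [sim_config()].
#' @return a list with reference sets `mitochondria`, `chloroplast`, `ncrna`,
#'   `mature`, `hairpin`, `transcriptome` and a `truth` list of tibbles
#'   (`families`, `novel_loci`, `degradation`, `target_sites`). Intervals are
#'   0-based half-open in transcript coordinates.
#' @export
#' @examples
#' refs <- sim_references(sim_config(seed = 1, n_transcripts = 20,
#'                                   n_degradation_transcripts = 2))
#' refs$truth$novel_loci
sim_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  mito <- reference_set(c(mito_genome = .rand_seq(1, 1800)),
                        "mitochondria", "organellar")
  chloro <- reference_set(c(chloro_genome = .rand_seq(1, 2200)),
                          "chloroplast", "organellar")

  nc_classes <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"), length.out = 20)
  nc_seqs <- .rand_seq(20, sample(80:250, 20, replace = TRUE))
  names(nc_seqs) <- sprintf("%s_%02d", nc_classes, seq_along(nc_seqs))
  ncrna <- reference_set(nc_seqs, "ncRNA families", "ncrna")

  n_fam <- config$n_mirna_families
  fam_num <- rep_len(.FAMILY_NUMBERS, n_fam)
  members <- purrr::map_dfr(seq_len(n_fam), function(i) {
    n_mem <- if (i %% 2 == 1) 2L else 1L
    tibble(
      db_id = sprintf("%s-miR%d%s-5p",
                      .SPECIES_PREFIXES[(i - 1) %% length(.SPECIES_PREFIXES) + 1],
                      fam_num[i], letters[seq_len(n_mem)]),
      family = sprintf("miR%d", fam_num[i]),
      sequence = .rand_seq(n_mem, sample(20:22, n_mem, replace = TRUE))
    )
  })
  mature <- reference_set(setNames(members$sequence, members$db_id),
                          "mature miRNAs", "mirna-mature")
  hp_seqs <- vapply(members$sequence, function(m) {
    paste0(.rand_seq(1, 15), m, .rand_seq(1, 8), revcomp(m), .rand_seq(1, 10))
  }, character(1))
  names(hp_seqs) <- sub("-(5p|3p)$", "", sub("miR", "MIR", members$db_id))
  hairpin <- reference_set(hp_seqs, "miRNA hairpins", "mirna-hairpin")

  tx_len <- sample(350:700, config$n_transcripts, replace = TRUE)
  tx <- .rand_seq(config$n_transcripts, tx_len)
  names(tx) <- sprintf("isotig%05d", seq_len(config$n_transcripts))

  need <- config$n_novel_loci + config$n_degradation_transcripts +
    config$n_planted_targets
  if (need > config$n_transcripts) {
    abort("Not enough transcripts for the requested planted features.")
  }
  special <- sample(names(tx), need)
  novel_tx <- special[seq_len(config$n_novel_loci)]
  degr_tx <- special[config$n_novel_loci + seq_len(config$n_degradation_transcripts)]
  target_tx <- special[config$n_novel_loci + config$n_degradation_transcripts +
                         seq_len(config$n_planted_targets)]

  novel_loci <- purrr::map_dfr(seq_along(novel_tx), function(i) {
    id <- novel_tx[i]
    L <- nchar(tx[[id]])
    start <- sample(0:(L - 21L), 1)
    tibble(
      locus_id = paste0("novel-", i), transcript_id = id,
      start = start, end = start + 21L,
      sequence = substr(tx[[id]], start + 1L, start + 21L)
    )
  })

  n_target <- min(config$n_planted_targets, nrow(members))
  target_sites <- purrr::map_dfr(seq_len(n_target), function(i) {
    id <- target_tx[i]
    site <- revcomp(members$sequence[i])
    L <- nchar(tx[[id]])
    w <- nchar(site)
    # keep flanks available for accessibility windows
    start <- sample(20:(L - w - 20L), 1)
    substr(tx[[id]], start + 1L, start + w) <<- site
    tibble(mirna_id = members$db_id[i], transcript_id = id,
           start = start, end = start + w)
  })

  transcriptome <- reference_set(tx, "reference transcriptome", "transcriptome")

  list(
    mitochondria = mito, chloroplast = chloro, ncrna = ncrna,
    mature = mature, hairpin = hairpin, transcriptome = transcriptome,
    truth = list(
      families = members,
      novel_loci = novel_loci,
      degradation = tibble(transcript_id = degr_tx),
      target_sites = target_sites
    )
  )
}

# Build the tag pool: every distinct emission unit with its class, origin and
# per-genotype expected weight. Weights are unnormalized; per library they are
# renormalized and fed to a multinomial draw.
.build_tag_pool <- function(config, refs) {
  fr <- config$fractions
  pool <- list()

  sample_substring <- function(seqs, len_range = 19:26) {
    id <- sample(names(seqs), 1)
    s <- seqs[[id]]
    w <- sample(len_range, 1)
    start <- sample(1:(nchar(s) - w + 1), 1)
    list(id = id, seq = substr(s, start, start + w - 1))
  }

  if (fr[["organellar"]] > 0) {
    org_seqs <- c(
      setNames(refs$mitochondria$sequence, refs$mitochondria$id),
      setNames(refs$chloroplast$sequence, refs$chloroplast$id)
    )
    n_org <- 8L
    org <- purrr::map_dfr(seq_len(n_org), function(i) {
      x <- sample_substring(org_seqs)
      s <- if (runif(1) < 0.5) revcomp(x$seq) else x$seq
      tibble(sequence = s, class = "organellar", origin_id = x$id)
    })
    org$weight <- rexp(n_org)
    org$weight <- org$weight / sum(org$weight) * fr[["organellar"]]
    pool$organellar <- org
  }

  if (fr[["ncrna"]] > 0) {
    nc_seqs <- setNames(refs$ncrna$sequence, refs$ncrna$id)
    n_nc <- 60L
    nc <- purrr::map_dfr(seq_len(n_nc), function(i) {
      x <- sample_substring(nc_seqs)
      tibble(sequence = x$seq, class = "ncrna", origin_id = x$id)
    })
    nc$weight <- rexp(n_nc)
    nc$weight <- nc$weight / sum(nc$weight) * fr[["ncrna"]]
    pool$ncrna <- nc
  }

  if (fr[["conserved"]] > 0) {
    members <- refs$truth$families
    per_member <- fr[["conserved"]] / nrow(members)
    cons <- purrr::map_dfr(seq_len(nrow(members)), function(i) {
      mm <- 0:3
      tibble(
        sequence = vapply(mm, function(m) .mutate_seq(members$sequence[i], m),
                          character(1)),
        class = "conserved",
        origin_id = members$db_id[i],
        n_mismatch = mm,
        weight = per_member * unname(config$mismatch_profile)
      )
    })
    pool$conserved <- cons
  }

  if (fr[["degradation"]] > 0) {
    degr_tx <- refs$truth$degradation$transcript_id
    tx <- setNames(refs$transcriptome$sequence, refs$transcriptome$id)
    per_tx <- fr[["degradation"]] / length(degr_tx)
    degr <- purrr::map_dfr(degr_tx, function(id) {
      s <- tx[[id]]
      n_win <- 120L
      w <- sample(17:30, n_win, replace = TRUE)
      start <- vapply(w, function(wi) sample(1:(nchar(s) - wi + 1), 1), integer(1))
      out <- tibble(
        sequence = substring(s, start, start + w - 1),
        class = "degradation", origin_id = id,
        weight = rexp(n_win)
      )
      out$weight <- out$weight / sum(out$weight) * per_tx
      out
    })
    pool$degradation <- degr
  }

  if (fr[["novel"]] > 0) {
    loci <- refs$truth$novel_loci
    pool$novel <- tibble(
      sequence = loci$sequence, class = "novel", origin_id = loci$locus_id,
      weight = fr[["novel"]] / nrow(loci)
    )
  }

  if (fr[["random"]] > 0) {
    rare_share <- 0.27          # singleton-depth background -> min-count discards
    spike_share <- 0.027        # abundant tags available for DE planting
    common_share <- 1 - rare_share - spike_share

    draw_len <- function(n) {
      len <- sample(config$length_modes, n, replace = TRUE,
                    prob = config$length_mode_weights)
      jitter <- runif(n) < 0.25
      len[jitter] <- len[jitter] + sample(c(-2L, -1L, 1L, 2L),
                                          sum(jitter), replace = TRUE)
      pmin(pmax(len, 17L), 33L)
    }

    n_rare <- 4000L
    rare <- tibble(
      sequence = .rand_seq(n_rare, draw_len(n_rare)),
      class = "random", origin_id = "background-rare",
      weight = fr[["random"]] * rare_share / n_rare
    )
    n_common <- 400L
    common <- tibble(
      sequence = .rand_seq(n_common, draw_len(n_common)),
      class = "random", origin_id = "background-common",
      weight = rlnorm(n_common)
    )
    common$weight <- common$weight / sum(common$weight) *
      fr[["random"]] * common_share
    n_spike <- config$n_spike_tags
    spike <- tibble(
      sequence = .rand_seq(n_spike, draw_len(n_spike)),
      class = "random", origin_id = paste0("spike-", seq_len(n_spike)),
      weight = fr[["random"]] * spike_share / max(n_spike, 1L)
    )
    pool$random <- dplyr::bind_rows(rare, common, spike)
  }

  pool <- dplyr::bind_rows(pool)
  if (!"n_mismatch" %in% names(pool)) pool$n_mismatch <- NA_integer_
  pool$n_mismatch[pool$class != "conserved"] <- NA_integer_

  # drop accidental cross-class sequence collisions (astronomically rare)
  pool <- pool[!duplicated(pool$sequence), ]

  # apply planted genotype fold changes
  genos <- unique(config$library_design$genotype)
  for (g in genos) pool[[paste0("mult_", g)]] <- 1
  pd <- config$planted_de
  if (!is.null(pd) && nrow(pd) > 0) {
    for (i in seq_len(nrow(pd))) {
      hit <- pool$origin_id == pd$id[i]
      if (!any(hit)) {
        warn(sprintf("planted_de id '%s' matches no tag class; ignored.", pd$id[i]))
        next
      }
      col <- paste0("mult_", pd$genotype[i])
      if (!col %in% names(pool)) {
        abort(sprintf("planted_de genotype '%s' not in the library design.",
                      pd$genotype[i]))
      }
      pool[[col]][hit] <- pool[[col]][hit] * 2^pd$log2fc[i]
    }
  }
  pool
}

#' Simulate the four raw FASTQ libraries with per-read truth
#'
#' Draws, per library, a multinomial sample over the class-weighted tag pool
#' (with planted fold changes applied to that library's genotype), then emits
#' raw reads as insert + 3' adapter (+ constant filler) truncated to the
#' instrument read length, with valid Phred+33 qualities. Every read has
#' exactly one truth record.
#'
#' @param config a [sim_config()].
#' @param refs output of [sim_references()] for the same config.
#' @return a list:
#' \describe{
#'   \item{reads}{tibble `read_id`, `sequence`, `quality`, `library`,
#'     `genotype`, `replicate` — the raw reads.}
#'   \item{truth}{tibble `read_id`, `class`, `origin_id`, `library`,
#'     `genotype`, `replicate` — one row per read.}
#'   \item{tag_pool}{the emission-unit table: `sequence`, `class`,
#'     `origin_id`, `n_mismatch`, `weight` and per-genotype multipliers.}
#'   \item{de_truth}{tibble of planted differentially expressed tags
#'     (`sequence`, `origin_id`, `genotype_up`, `log2fc`).}
#' }
#' @export
sim_libraries <- function(config, refs) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reads_per_library < 1) {
    abort("`n_reads_per_library` must be at least 1 (empty library requested).")
  }
  set.seed(config$seed + 1L)
  pool <- .build_tag_pool(config, refs)

  filler <- "CGTATGCCGTCTTCTGCTTGAAAAAAAAAA"
  design <- config$library_design
  reads_list <- vector("list", nrow(design))
  truth_list <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    lib <- design$library[i]
    w <- pool$weight * pool[[paste0("mult_", design$genotype[i])]]
    counts <- as.vector(rmultinom(1, config$n_reads_per_library, w))
    idx <- rep.int(seq_len(nrow(pool)), counts)
    insert <- pool$sequence[idx]
    raw <- substr(paste0(insert, config$adapter, filler), 1L, config$read_length)
    ids <- sprintf("%s_%07d", lib, seq_along(raw))
    reads_list[[i]] <- tibble(
      read_id = ids, sequence = raw,
      quality = strrep("I", nchar(raw)),
      library = lib, genotype = design$genotype[i], replicate = design$replicate[i]
    )
    truth_list[[i]] <- tibble(
      read_id = ids, class = pool$class[idx], origin_id = pool$origin_id[idx],
      library = lib, genotype = design$genotype[i], replicate = design$replicate[i]
    )
  }

  pd <- config$planted_de
  de_truth <- if (is.null(pd) || nrow(pd) == 0) {
    tibble(sequence = character(), origin_id = character(),
           genotype_up = character(), log2fc = numeric())
  } else {
    dplyr::inner_join(
      dplyr::select(pool, "sequence", "origin_id"),
      dplyr::rename(pd, origin_id = "id", genotype_up = "genotype"),
      by = "origin_id"
    )
  }

  list(
    reads = dplyr::bind_rows(reads_list),
    truth = dplyr::bind_rows(truth_list),
    tag_pool = pool,
    de_truth = de_truth
  )
}

#' Write a simulated experiment to disk
#'
#' Writes the reference sets as FASTA, the four libraries as FASTQ, and the
#' per-read truth table as TSV, so the pipeline can be exercised from files
#' exactly as it would be on real data.
#'
#' @param refs output of [sim_references()].
#' @param libs output of [sim_libraries()].
#' @param outdir output directory (created if missing).
#' @param gzip compress the FASTQ files.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(refs, libs, outdir, gzip = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("mitochondria", "chloroplast", "ncrna", "mature", "hairpin",
               "transcriptome")) {
    write_fasta(refs[[nm]], file.path(outdir, paste0(nm, ".fa")))
  }
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  for (lib in unique(libs$reads$library)) {
    write_fastq(dplyr::filter(libs$reads, .data$library == lib),
                file.path(outdir, paste0(lib, ext)))
  }
  readr::write_tsv(libs$truth, file.path(outdir, "truth_reads.tsv"))
  invisible(outdir)
}
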