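#' Pipeline configuration
#'
#' Collects the inputs and every stage threshold of the end-to-end analysis.
#' Reference inputs and reads may be given as file paths (FASTA / FASTQ) or
#' as in-memory objects ([reference_set()]s / a read tibble). The defaults
#' are the conventional values of the small-RNA literature: minimum tag
#' count 3, 17-33 nt length window, subtraction at 0 mismatches, conserved
#' homology at <= 2 mismatches and >= 90% coverage, degradation breadth 0.8,
#' target expectation <= 2.5 with UPE <= 20, and DE calls at adjusted
#' p < 0.01 with |log2FC| > 2.
#'
#' @param reads read tibble (`read_id`, `sequence`, `quality`, `library`) or
#'   `NULL` when `fastq` paths are given.
#' @param fastq named character vector of FASTQ paths (names = library ids).
#' @param design tibble with `library`, `genotype` (and optionally
#'   `replicate`).
#' @param mitochondria,chloroplast,ncrna,mature,hairpin,transcriptome
#'   reference inputs: [reference_set()]s or FASTA paths.
#' @param adapter 3' adapter sequence.
#' @param quality_cutoff,min_len,max_len,min_count preprocessing thresholds.
#' @param max_mismatch_subtract mismatches allowed in contamination
#'   subtraction.
#' @param max_mismatch_conserved,min_coverage conserved-homology thresholds.
#' @param breadth_threshold,max_loci,max_locus_width,merge_gap
#'   degradation-filter thresholds.
#' @param max_expectation,upe_max target-scoring thresholds.
#' @param p_threshold,fc_threshold differential-expression call thresholds.
#' @param prefix species prefix for assigned miRNA names.
#' @param outdir report output directory (`NULL`: no files written).
#' @param seed integer seed recorded in reports.
#' @param scan_targets run the (comparatively expensive) target scan stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads = NULL, fastq = NULL, design,
                            mitochondria, chloroplast, ncrna, mature,
                            hairpin = NULL, transcriptome,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            quality_cutoff = 20, min_len = 17, max_len = 33,
                            min_count = 3, max_mismatch_subtract = 0,
                            max_mismatch_conserved = 2, min_coverage = 0.90,
                            breadth_threshold = 0.8, max_loci = 2,
                            max_locus_width = 30, merge_gap = 5,
                            max_expectation = 2.5, upe_max = 20,
                            p_threshold = 0.01, fc_threshold = 2,
                            prefix = "ecu", outdir = NULL, seed = 1,
                            scan_targets = TRUE) {
  if (is.null(reads) && is.null(fastq)) {
    abort("Provide either `reads` or `fastq` paths.")
  }
  if (!is.null(fastq)) {
    missing_files <- fastq[!file.exists(fastq)]
    if (length(missing_files)) {
      abort(paste0("FASTQ file(s) not found: ",
                   paste(missing_files, collapse = ", ")))
    }
  }
  refs <- list(mitochondria = mitochondria, chloroplast = chloroplast,
               ncrna = ncrna, mature = mature, hairpin = hairpin,
               transcriptome = transcriptome)
  ref_class <- c(mitochondria = "organellar", chloroplast = "organellar",
                 ncrna = "ncrna", mature = "mirna-mature",
                 hairpin = "mirna-hairpin", transcriptome = "transcriptome")
  for (nm in names(refs)) {
    r <- refs[[nm]]
    if (is.null(r)) {
      if (nm == "hairpin") next
      abort(sprintf("Reference set '%s' is required.", nm))
    }
    if (is.character(r)) {
      if (!file.exists(r)) abort(sprintf("Reference file not found: %s", r))
      refs[[nm]] <- read_fasta(r, name = nm, class = ref_class[[nm]])
    } else if (!inherits(r, "reference_set")) {
      abort(sprintf("'%s' must be a reference_set or a FASTA path.", nm))
    }
  }
  structure(c(
    list(reads = reads, fastq = fastq, design = as_tibble(design)),
    refs,
    list(adapter = adapter, quality_cutoff = quality_cutoff,
         min_len = min_len, max_len = max_len, min_count = min_count,
         max_mismatch_subtract = max_mismatch_subtract,
         max_mismatch_conserved = max_mismatch_conserved,
         min_coverage = min_coverage, breadth_threshold = breadth_threshold,
         max_loci = max_loci, max_locus_width = max_locus_width,
         merge_gap = merge_gap, max_expectation = max_expectation,
         upe_max = upe_max, p_threshold = p_threshold,
         fc_threshold = fc_threshold, prefix = prefix, outdir = outdir,
         seed = seed, scan_targets = scan_targets)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' File paths in the YAML are resolved relative to the YAML file's directory.
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (`fastq` as a named map of library id to path).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  if (!is.null(y$fastq)) y$fastq <- setNames(rel(unlist(y$fastq)), names(y$fastq))
  for (nm in c("mitochondria", "chloroplast", "ncrna", "mature", "hairpin",
               "transcriptome")) {
    if (!is.null(y[[nm]]) && is.character(y[[nm]])) y[[nm]] <- rel(y[[nm]])
  }
  y$design <- dplyr::bind_rows(y$design)
  do.call(pipeline_config, y)
}

.report_header <- function(config) {
  keys <- c("min_count", "min_len", "max_len", "max_mismatch_subtract",
            "max_mismatch_conserved", "min_coverage", "breadth_threshold",
            "max_expectation", "upe_max", "p_threshold", "fc_threshold",
            "seed")
  sprintf("# apomir %s | %s", packageVersion("apomir"),
          paste(sprintf("%s=%s", keys, unlist(config[keys])), collapse = " "))
}

.write_report <- function(df, path, header) {
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the full small-RNA analysis pipeline
#'
#' Orchestrates all stages: read cleanup and tag collapsing with the minimum
#' count filter, contamination subtraction (mitochondria, chloroplast,
#' ncRNA), conserved-miRNA classification and family summary with consensus
#' naming, degradation-aware novel candidate discovery, optional target
#' scanning for the inferred miRNAs, and differential expression between the
#' two genotypes. When `config$outdir` is set, six TSV reports (library
#' description, depuration, conserved statistics, family summary, novel
#' candidates, target sites, differential expression) plus a manifest are
#' written, each headed by a comment line recording the tool version and
#' thresholds; a rerun with the same config and seed reproduces them
#' byte-identically. If a stage fails, reports completed so far are preserved
#' and listed in the manifest before the error propagates.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list with the stage results: `trimmed`,
#'   `library_description`, `tags`, `depured`, `depuration`,
#'   `conserved_hits`, `families`, `conserved_stats`, `consensus`, `novel`,
#'   `targets`, `de`, and `reports` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  reports <- character()
  header <- .report_header(config)
  writing <- !is.null(config$outdir)
  if (writing) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    on.exit(writeLines(
      c(header, basename(reports)),
      file.path(config$outdir, "MANIFEST.txt")
    ), add = TRUE)
  }
  emit <- function(df, file) {
    if (!writing) return(invisible(NULL))
    p <- .write_report(df, file.path(config$outdir, file), header)
    reports <<- c(reports, p)
  }

  reads <- config$reads
  if (is.null(reads)) {
    reads <- purrr::imap_dfr(config$fastq, function(p, lib) read_fastq(p, lib))
  }
  message("* trimming ", nrow(reads), " raw reads")
  trimmed <- trim_reads(reads, config$adapter,
                        quality_cutoff = config$quality_cutoff,
                        min_len = config$min_len, max_len = config$max_len)
  libdesc <- library_description(trimmed, min_count = config$min_count)
  emit(libdesc, "library_description.tsv")

  tags <- collapse_tags(clean_reads(trimmed))
  kept <- filter_min_count(tags, config$min_count)

  message("* depuration of ", length(unique(kept$sequence)), " unique tags")
  depured <- depure(kept, config$mitochondria, config$chloroplast,
                    config$ncrna, max_mismatch = config$max_mismatch_subtract)
  dep_report <- depuration_report(depured)
  emit(dep_report$stages, "depuration_stages.tsv")
  emit(dep_report$depured, "depuration.tsv")

  message("* conserved miRNA classification")
  hits <- classify_conserved(depured, config$mature, config$hairpin,
                             max_mismatch = config$max_mismatch_conserved,
                             min_coverage = config$min_coverage)
  families <- summarize_families(hits, depured)
  stats <- conserved_stats(families)
  consensus <- consensus_name(hits, depured, prefix = config$prefix)
  emit(stats, "conserved_stats.tsv")
  emit(families, "family_summary.tsv")

  message("* novel miRNA discovery")
  non_conserved <- depured[!depured$sequence %in% hits$sequence, , drop = FALSE]
  novel <- discover_novel(non_conserved, config$transcriptome,
                          breadth_threshold = config$breadth_threshold,
                          max_loci = config$max_loci,
                          max_locus_width = config$max_locus_width,
                          merge_gap = config$merge_gap)
  novel <- name_novel(novel, config$mature, prefix = config$prefix)
  emit(novel, "novel_candidates.tsv")

  targets <- NULL
  if (isTRUE(config$scan_targets)) {
    message("* target scanning")
    mirnas <- c(
      setNames(as_dna(consensus$consensus), consensus$name),
      setNames(novel$sequence, novel$name)
    )
    mirnas <- mirnas[nchar(mirnas) >= 17 & nchar(mirnas) <= 26]
    mirnas <- mirnas[!duplicated(names(mirnas))]
    params <- scoring_params(max_expectation = config$max_expectation,
                             upe_max = config$upe_max)
    targets <- predict_targets(mirnas, config$transcriptome, params,
                               upe_backend = upe_stub, filter_upe = TRUE)
    emit(targets, "target_sites.tsv")
  }

  message("* differential expression")
  # Test on the full clean counts of every depured tag, not the per-library
  # filtered rows: a tag kept in one library may sit just under the minimum
  # count in another, and zeroing those counts would fabricate
  # genotype-exclusive patterns. Library sizes stay the depured totals.
  de_input <- dplyr::semi_join(tags, depured, by = "sequence")
  depured_sizes <- depured |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(size = sum(.data$count), .groups = "drop")
  lib_order <- unique(de_input$library)
  de <- de_test(de_input, config$design,
                lib_sizes = depured_sizes$size[match(lib_order,
                                                     depured_sizes$library)],
                p_threshold = config$p_threshold,
                fc_threshold = config$fc_threshold)
  emit(tidy(de), "differential_expression.tsv")

  invisible(list(
    trimmed = trimmed, library_description = libdesc, tags = kept,
    depured = depured, depuration = dep_report, conserved_hits = hits,
    families = families, conserved_stats = stats, consensus = consensus,
    novel = novel, targets = targets, de = de, reports = reports
  ))
}
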