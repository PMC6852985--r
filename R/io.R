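#' Construct a reference sequence set
#'
#' A reference set bundles a named collection of sequences with the metadata
#' the subtraction and annotation stages need: a set name, a class describing
#' what the sequences are, and a strand policy controlling whether tags are
#' matched against both strands or the forward strand only. By default
#' organellar DNA references are searched on both strands while RNA-derived
#' references (ncRNA families, mature/hairpin miRNAs, transcriptome) are
#' forward-only.
#'
#' @param sequences named character vector of sequences (names are ids), or a
#'   data frame with `id` and `sequence` columns.
#' @param name human-readable set name (e.g. `"chloroplast"`).
#' @param class one of `"organellar"`, `"ncrna"`, `"mirna-mature"`,
#'   `"mirna-hairpin"`, `"transcriptome"`.
#' @param strand_policy `"both"` or `"forward"`; defaults by class.
#' @return an object of class `reference_set`: a tibble with columns `id` and
#'   `sequence` and attributes `name`, `ref_class`, `strand_policy`.
#' @export
#' @examples
#' reference_set(c(tRNA1 = "ACGTACGTACGTACGTACGTA"), "tRNAs", "ncrna")
reference_set <- function(sequences, name, class, strand_policy = NULL) {
  class <- match.arg(class, c(
    "organellar", "ncrna", "mirna-mature", "mirna-hairpin", "transcriptome"
  ))
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("Reference sequences must have unique ids (names).")
  }
  seqs <- as_dna(sequences)
  if (any(!nzchar(seqs))) abort("Reference sequences must be non-empty.")
  if (is.null(strand_policy)) {
    strand_policy <- if (class == "organellar") "both" else "forward"
  }
  strand_policy <- match.arg(strand_policy, c("both", "forward"))
  out <- tibble(id = names(seqs), sequence = unname(seqs))
  structure(out,
    class = c("reference_set", class(out)),
    name = name, ref_class = class, strand_policy = strand_policy
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set '%s'> class: %s | strand: %s | %d sequence(s), %d nt total\n",
    attr(x, "name"), attr(x, "ref_class"), attr(x, "strand_policy"),
    nrow(x), sum(nchar(x$sequence))
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Read a FASTA file into a reference set
#'
#' @param path FASTA file (gzip transparently supported).
#' @inheritParams reference_set
#' @return a [reference_set()].
#' @export
read_fasta <- function(path, name = basename(path), class = "transcriptome",
                       strand_policy = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  reference_set(setNames(as.character(ss), ids), name, class, strand_policy)
}

#' Write sequences to a FASTA file
#'
#' @param x a [reference_set()] or named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a FASTQ file into a tidy read table
#'
#' Reads are returned as a tibble so the preprocessing verbs chain with the
#' pipe. Quality strings are kept verbatim (Phred+33).
#'
#' @param path FASTQ file (gzip transparently supported).
#' @param library_id library label to attach to every read; defaults to the
#'   file name without extensions.
#' @return tibble with columns `read_id`, `sequence`, `quality`, `library`.
#' @export
read_fastq <- function(path, library_id = NULL) {
  if (is.null(library_id)) {
    library_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  # Biostrings warns that the quality metadata columns are dropped when the
  # sequences are materialized; we extract the qualities separately anyway
  suppressWarnings({
    ss <- Biostrings::readQualityScaledDNAStringSet(path,
                                                    quality.scoring = "phred")
    out <- tibble(
      read_id = unname(sub("\\s.*$", "", names(ss))),
      sequence = unname(as.character(ss)),
      quality = unname(as.character(Biostrings::quality(ss))),
      library = library_id
    )
  })
  out
}

#' Write a tidy read table to FASTQ
#'
#' @param reads tibble with `read_id`, `sequence`, `quality` columns.
#' @param path output file path (`.gz` suffix enables compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("Sequence and quality lengths differ; refusing to write FASTQ.")
  }
  lines <- as.vector(rbind(
    paste0("@", reads$read_id), reads$sequence, "+", reads$quality
  ))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
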