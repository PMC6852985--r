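#' Canonicalize a nucleotide sequence to the DNA alphabet
#'
#' The package treats U and T as the same symbol; all internal computation is
#' done on uppercase DNA strings. RNA input (miRNA sequences, qPCR assay
#' sequences) is converted transparently.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over `{A,C,G,T,N}`.
#' @export
#' @examples
#' as_dna("uugacagaagauagagagcac")
as_dna <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

#' Reverse complement of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

# complement lookup used by the duplex scorer (vectorised over single bases)
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# internal: check that a scalar is a single non-missing value of given predicate
.check_scalar <- function(x, what, pred, name = deparse(substitute(x))) {
  if (length(x) != 1L || is.na(x) || !pred(x)) {
    abort(sprintf("`%s` must be a single %s.", name, what))
  }
  invisible(x)
}

.check_fraction <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a fraction in [0, 1].", name))
  }
  invisible(x)
}

# internal: extract the sequence column from a tags tibble or pass through a
# character vector of sequences
.tag_sequences <- function(tags) {
  if (is.character(tags)) return(unique(as_dna(tags)))
  if (is.data.frame(tags)) {
    if (!"sequence" %in% names(tags)) {
      abort("`tags` data frame must have a `sequence` column.")
    }
    return(unique(as_dna(tags$sequence)))
  }
  abort("`tags` must be a character vector or a data frame with a `sequence` column.")
}

#' Derive a miRNA family name from a database identifier
#'
#' Family names follow the field convention `miR<number>`: the numeric token
#' after the "miR"/"MIR"/"mir" tag of a database identifier such as
#' `ata-miR2275a-3p` or `ppt-MIR894` is extracted, so both examples group under
#' `miR2275` and `miR894`. Identifiers without a parsable token are assigned
#' family `"unknown"` with a warning.
#'
#' @param db_id character vector of miRNA database identifiers.
#' @return character vector of family names.
#' @export
#' @examples
#' mirna_family(c("ata-miR2275a-3p", "osa-miR2275d", "ppt-MIR894"))
mirna_family <- function(db_id) {
  m <- stringr::str_match(db_id, stringr::regex("mir-?_?([0-9]+)", ignore_case = TRUE))
  fam <- ifelse(is.na(m[, 2]), NA_character_, paste0("miR", m[, 2]))
  if (anyNA(fam)) {
    warn(sprintf(
      "Could not parse a miRNA family from %d identifier(s); assigned 'unknown'.",
      sum(is.na(fam))
    ))
    fam[is.na(fam)] <- "unknown"
  }
  fam
}
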