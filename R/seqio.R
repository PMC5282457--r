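#' Read sequences from a FASTA or FASTQ file
#'
#' Reads a sequence file into a tibble with one row per record.  Sequences
#' are normalized to upper case; `N` is accepted.  Qualities are returned
#' verbatim (Phred+33 is assumed but not interpreted).
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (default; guessed from the file extension),
#'   `"fasta"` or `"fastq"`.
#' @return A tibble with columns `id`, `sequence` and, for FASTQ input,
#'   `quality`.  An empty file yields a zero-row tibble.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2", "GGCC"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  if (format == "auto") {
    format <- guess_seq_format(path)
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    out <- tibble(
      id = names(set),
      sequence = unname(toupper(as.character(set)))
    )
  } else {
    set <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- unname(as.character(S4Vectors::mcols(set)$qualities))
    out <- tibble(
      id = names(set),
      sequence = unname(toupper(as.character(set))),
      quality = qual
    )
    bad <- which(nchar(out$sequence) != nchar(out$quality))
    if (length(bad) > 0) {
      abort(paste0(
        "malformed FASTQ record ", bad[1],
        ": sequence and quality lengths differ"
      ))
    }
  }
  bad <- which(grepl("[^ACGTUN]", out$sequence))
  if (length(bad) > 0) {
    abort(paste0("malformed record ", bad[1], ": invalid characters in sequence"))
  }
  bad <- which(grepl("T", out$sequence) & grepl("U", out$sequence))
  if (length(bad) > 0) {
    abort(paste0("malformed record ", bad[1], ": sequence mixes T and U"))
  }
  out
}

#' Write sequences to a FASTA or FASTQ file
#'
#' @param x A data frame with columns `id`, `sequence` and, for FASTQ
#'   output, `quality`.
#' @param path Output file path.
#' @param format `"auto"` (from extension), `"fasta"` or `"fastq"`.
#'   FASTQ output requires a `quality` column.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- guess_seq_format(path)
  }
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$id
  if (format == "fastq") {
    if (!"quality" %in% names(x)) {
      abort("FASTQ output requires a `quality` column")
    }
    Biostrings::writeXStringSet(
      set, path,
      format = "fastq",
      qualities = Biostrings::BStringSet(x$quality)
    )
  } else {
    Biostrings::writeXStringSet(set, path, format = "fasta")
  }
  invisible(path)
}

guess_seq_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("fq", "fastq")) {
    "fastq"
  } else if (ext %in% c("fa", "fasta", "fna", "txt")) {
    "fasta"
  } else {
    abort(paste0("unknown sequence format for file: ", path))
  }
}

# alphabet check shared by the sequence transforms; U is rejected for DNA
check_dna <- function(x, what = "sequence") {
  if (!is.character(x)) abort(paste0(what, " must be a character vector"))
  x <- toupper(x)
  if (any(grepl("U", x))) {
    abort(paste0(what, " contains U; expected DNA (use RNA-aware functions)"))
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(paste0(what, " contains characters outside {A,C,G,T,N}"))
  }
  x
}

#' Reverse complement of DNA sequences
#'
#' Watson–Crick reverse complement; `N` complements to `N`.  Vectorized;
#' applying it twice returns the input.
#'
#' @param x Character vector of DNA sequences (upper or lower case;
#'   `U` is an error).
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("TCGGGCGAGTCGTCTG")
#' @export
reverse_complement <- function(x) {
  x <- check_dna(x)
  out <- character(length(x))
  nonempty <- nchar(x) > 0
  if (any(nonempty)) {
    out[nonempty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nonempty]))
    )
  }
  out
}

#' Transcribe DNA to RNA
#'
#' Replaces `T` with `U`; all other bases are unchanged.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of RNA sequences.
#' @examples
#' dna_to_rna("ACGT")
#' @export
dna_to_rna <- function(x) {
  x <- check_dna(x)
  chartr("T", "U", x)
}
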