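#' Describe an aptamer library design
#'
#' A library design records the constant flanking sequences shared by every
#' library member, the admissible variable-region (VR) length range, and the
#' minimum raw read length.  The defaults are the design used throughout the
#' package's examples: a 40-nt random region (N40) flanked by a 16-nt left
#' and a 17-nt right constant region, sequenced reads of at least 70 nt, and
#' a VR accepted at 38–42 nt.
#'
#' @param left_constant DNA sequence of the 5' constant flank.
#' @param right_constant DNA sequence of the 3' constant flank.
#' @param vr_min,vr_max Integer bounds (nt) on the accepted variable-region
#'   length.
#' @param min_read_length Integer; reads shorter than this are rejected
#'   before any flank search.
#' @param search_reverse_complement If `TRUE` (default), a read whose
#'   forward orientation lacks the flanks is re-searched as its reverse
#'   complement.
#' @return An object of class `library_design`.
#' @examples
#' library_design()
#' @export
library_design <- function(left_constant = "TCGGGCGAGTCGTCTG",
                           right_constant = "CCGCATCGTCCTCCCTA",
                           vr_min = 38L,
                           vr_max = 42L,
                           min_read_length = 70L,
                           search_reverse_complement = TRUE) {
  left_constant <- toupper(left_constant)
  right_constant <- toupper(right_constant)
  for (s in c(left_constant, right_constant)) {
    if (nchar(s) == 0 || grepl("[^ACGT]", s)) {
      abort("constant regions must be non-empty DNA over {A,C,G,T} (no N)")
    }
  }
  vr_min <- as.integer(vr_min)
  vr_max <- as.integer(vr_max)
  min_read_length <- as.integer(min_read_length)
  if (!(vr_min > 0 && vr_min <= vr_max)) {
    abort("need 0 < vr_min <= vr_max")
  }
  if (min_read_length < 0) abort("min_read_length must be >= 0")
  structure(
    list(
      left_constant = left_constant,
      right_constant = right_constant,
      vr_min = vr_min,
      vr_max = vr_max,
      min_read_length = min_read_length,
      search_reverse_complement = isTRUE(search_reverse_complement)
    ),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>\n")
  cat("  5' constant: ", x$left_constant, " (", nchar(x$left_constant), " nt)\n", sep = "")
  cat("  3' constant: ", x$right_constant, " (", nchar(x$right_constant), " nt)\n", sep = "")
  cat("  VR length:   ", x$vr_min, "-", x$vr_max, " nt\n", sep = "")
  cat("  min read:    ", x$min_read_length, " nt\n", sep = "")
  cat("  search reverse complement: ", x$search_reverse_complement, "\n", sep = "")
  invisible(x)
}
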