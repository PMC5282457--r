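#' Global alignment of two sequences
#'
#' Needleman–Wunsch global alignment under a simple linear scoring scheme
#' (match 1, mismatch 0, gap -1 by default).  Among all optimal-score
#' alignments, the one with the most identical (matched) columns is
#' returned — this makes the derived percent identity independent of the
#' argument order.  Remaining traceback ties are broken deterministically:
#' diagonal (match/mismatch) over up (gap in the second sequence) over left
#' (gap in the first), so a given input always yields the same alignment.
#'
#' @param a,b Sequences to align (non-empty strings, or one may be empty).
#' @param match,mismatch,gap Scores; `match` must exceed `mismatch`.
#' @return An object of class `selex_alignment`: a list with `aligned_a`,
#'   `aligned_b` (gap character `-`) and `score`.
#' @examples
#' global_align("ACGT", "ACGA")
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (match <= mismatch) abort("match score must exceed mismatch score")
  a <- toupper(a)
  b <- toupper(b)
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac)
  m <- length(bc)
  # S: best score; M: most matched columns among alignments achieving S
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    is_match <- ac[i] == bc
    sub <- ifelse(is_match, match, mismatch)
    for (j in seq_len(m)) {
      cs <- c(S[i, j] + sub[j], S[i, j + 1] + gap, S[i + 1, j] + gap)
      cm <- c(M[i, j] + is_match[j], M[i, j + 1], M[i + 1, j])
      best <- max(cs)
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- max(cm[cs == best])
    }
  }
  # traceback along (score, matches)-optimal moves: diagonal, then up, then left
  i <- n
  j <- m
  ra <- character(0)
  rb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      hit <- ac[i] == bc[j]
      diag_ok <- S[i + 1, j + 1] == S[i, j] + (if (hit) match else mismatch) &&
        M[i + 1, j + 1] == M[i, j] + hit
    } else {
      diag_ok <- FALSE
    }
    if (diag_ok) {
      ra <- c(ac[i], ra)
      rb <- c(bc[j], rb)
      i <- i - 1
      j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap &&
               M[i + 1, j + 1] == M[i, j + 1]) {
      ra <- c(ac[i], ra)
      rb <- c("-", rb)
      i <- i - 1
    } else {
      ra <- c("-", ra)
      rb <- c(bc[j], rb)
      j <- j - 1
    }
  }
  structure(
    list(aligned_a = paste(ra, collapse = ""),
         aligned_b = paste(rb, collapse = ""),
         score = S[n + 1, m + 1]),
    class = "selex_alignment"
  )
}

#' @export
print.selex_alignment <- function(x, ...) {
  am <- strsplit(x$aligned_a, "")[[1]]
  bm <- strsplit(x$aligned_b, "")[[1]]
  bar <- ifelse(am == bm & am != "-", "|", " ")
  cat(x$aligned_a, "\n", paste(bar, collapse = ""), "\n", x$aligned_b,
      "\nscore: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Percent identity between two sequences under global alignment
#'
#' Aligns with [global_align()] and reports the percentage of identical
#' aligned columns.  The denominator is either the full alignment length
#' (default) or the shorter sequence's length.
#'
#' @inheritParams global_align
#' @param denominator `"alignment"` (alignment length, default) or
#'   `"shorter"` (length of the shorter input).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACGT", "ACGA")
#' @export
percent_identity <- function(a, b, match = 1, mismatch = 0, gap = -1,
                             denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  aln <- global_align(a, b, match = match, mismatch = mismatch, gap = gap)
  am <- strsplit(aln$aligned_a, "")[[1]]
  bm <- strsplit(aln$aligned_b, "")[[1]]
  ident <- sum(am == bm & am != "-")
  den <- switch(denominator,
                alignment = length(am),
                shorter = min(nchar(a), nchar(b)))
  if (den == 0) return(0)
  100 * ident / den
}
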