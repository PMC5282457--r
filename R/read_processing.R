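#' Demultiplex reads by a leading round barcode
#'
#' Each read is assigned to the unique barcode found at its start within
#' `max_barcode_mismatch` mismatches; the barcode is removed from assigned
#' reads.  Barcodes must be pairwise separated by more than
#' `2 * max_barcode_mismatch` mismatches, otherwise an assignment could be
#' ambiguous by construction and setup fails.
#'
#' @param reads A data frame with columns `id` and `sequence`.
#' @param barcodes Named character vector: names are round labels, values
#'   are the barcode sequences (all the same length).
#' @param max_barcode_mismatch Maximum mismatches tolerated between a read
#'   prefix and a barcode (default 0).
#' @return A tibble like `reads` with a `round` column (`NA` for unassigned
#'   reads, whose sequences are left untouched); assigned reads have the
#'   barcode stripped.
#' @export
demultiplex <- function(reads, barcodes, max_barcode_mismatch = 0L) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    abort("`barcodes` must be a named character vector (names = round labels)")
  }
  barcodes <- toupper(barcodes)
  if (anyDuplicated(barcodes)) abort("duplicate barcode sequences")
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1) abort("barcodes must all have the same length")
  if (length(barcodes) > 1) {
    d <- hamming_matrix(barcodes, barcodes)
    d[upper.tri(d, diag = TRUE)] <- NA
    if (any(d <= 2 * max_barcode_mismatch, na.rm = TRUE)) {
      abort("two barcodes are within 2 * max_barcode_mismatch of each other")
    }
  }
  prefix <- toupper(substr(reads$sequence, 1L, blen))
  hit <- rep(NA_integer_, nrow(reads))
  full <- which(nchar(prefix) == blen)
  if (length(full) > 0) {
    d <- hamming_matrix(prefix[full], barcodes) # reads x barcodes
    hit[full] <- apply(d <= max_barcode_mismatch, 1L, function(ok) {
      if (sum(ok) == 1L) which(ok) else NA_integer_
    })
  }
  out <- as_tibble(reads)
  out$round <- names(barcodes)[hit]
  assigned <- !is.na(hit)
  out$sequence[assigned] <- substr(out$sequence[assigned], blen + 1L,
                                   nchar(out$sequence[assigned]))
  out
}

# pairwise Hamming distance between two character vectors whose elements all
# share one length; returns a length(a) x length(b) integer matrix
hamming_matrix <- function(a, b) {
  stopifnot(length(unique(nchar(c(a, b)))) == 1L)
  am <- matrix(unlist(strsplit(a, "")), nrow = length(a), byrow = TRUE)
  out <- matrix(0L, nrow = length(a), ncol = length(b))
  for (j in seq_along(b)) {
    bj <- strsplit(b[j], "")[[1]]
    out[, j] <- as.integer(rowSums(am != matrix(bj, nrow = length(a),
                                                ncol = length(bj), byrow = TRUE)))
  }
  out
}

# all occurrences of `pattern` in each sequence within max_mm mismatches,
# as a list of integer start vectors ordered best-first (fewest mismatches,
# then leftmost); out-of-bounds hits are dropped
flank_hits <- function(sequences, pattern, max_mm) {
  subj <- Biostrings::DNAStringSet(sequences)
  m <- Biostrings::vmatchPattern(pattern, subj, max.mismatch = max_mm, fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  if (max_mm == 0) {
    return(starts) # exact hits, already leftmost-first
  }
  plen <- nchar(pattern)
  pat_chars <- strsplit(pattern, "")[[1]]
  slens <- nchar(sequences)
  lapply(seq_along(sequences), function(i) {
    s <- starts[[i]]
    if (is.null(s) || length(s) == 0) return(NULL)
    s <- s[s >= 1 & s + plen - 1L <= slens[i]]
    if (length(s) == 0) return(NULL)
    mm <- vapply(s, function(st) {
      sum(strsplit(substr(sequences[i], st, st + plen - 1L), "")[[1]] != pat_chars)
    }, integer(1))
    s[order(mm, s)]
  })
}

# flank location for one orientation; returns a tibble with one row per read
locate_one_orientation <- function(sequences, design, max_mm) {
  left <- flank_hits(sequences, design$left_constant, max_mm)
  right <- flank_hits(sequences, design$right_constant, max_mm)
  n <- length(sequences)
  llen <- nchar(design$left_constant)
  rlen <- nchar(design$right_constant)
  status <- rep("ok", n)
  left_start <- rep(NA_integer_, n)
  right_start <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    lh <- left[[i]]
    if (is.null(lh) || length(lh) == 0) {
      status[i] <- "missing_left"
      next
    }
    ls <- lh[1]
    rh <- right[[i]]
    rh <- rh[rh > ls + llen - 1L]
    if (length(rh) == 0) {
      status[i] <- "missing_right"
      next
    }
    left_start[i] <- ls
    right_start[i] <- rh[1]
  }
  tibble(
    status = status,
    left_start = left_start,
    left_end = left_start + llen - 1L,
    right_start = right_start,
    right_end = right_start + rlen - 1L
  )
}

#' Locate the constant flanks within reads
#'
#' Finds the best occurrence (fewest mismatches, then leftmost) of the left
#' constant region and, strictly to its right, of the right constant region.
#' If the forward search fails and the design enables it, the reverse
#' complement of the read is searched and the orientation recorded;
#' coordinates then refer to the reverse-complemented sequence.
#'
#' Coordinates are 1-based and inclusive (the R/Bioconductor convention).
#'
#' @param sequences Character vector of read sequences.
#' @param design A [library_design()].
#' @param max_flank_mismatch Mismatches tolerated per flank (default 0,
#'   exact match).
#' @return A tibble with one row per read: `status` (`"ok"`,
#'   `"missing_left"` or `"missing_right"`), `orientation` (`"forward"` or
#'   `"reverse_complemented"`), the flank spans `left_start`, `left_end`,
#'   `right_start`, `right_end`, and the extracted `vr` between the flanks.
#' @examples
#' d <- library_design()
#' read <- paste0(d$left_constant, strrep("A", 40), d$right_constant)
#' locate_flanks(read, d)
#' @export
locate_flanks <- function(sequences, design, max_flank_mismatch = 0L) {
  stopifnot(inherits(design, "library_design"))
  sequences <- toupper(sequences)
  fwd <- locate_one_orientation(sequences, design, max_flank_mismatch)
  fwd$orientation <- "forward"
  need_rc <- which(fwd$status != "ok")
  if (design$search_reverse_complement && length(need_rc) > 0) {
    rc_seq <- reverse_complement(sequences[need_rc])
    rc <- locate_one_orientation(rc_seq, design, max_flank_mismatch)
    rescued <- which(rc$status == "ok")
    if (length(rescued) > 0) {
      idx <- need_rc[rescued]
      fwd[idx, c("status", "left_start", "left_end", "right_start", "right_end")] <-
        rc[rescued, c("status", "left_start", "left_end", "right_start", "right_end")]
      fwd$orientation[idx] <- "reverse_complemented"
      sequences[idx] <- rc_seq[rescued]
    }
  }
  fwd$orientation[fwd$status != "ok"] <- NA_character_
  fwd$vr <- ifelse(
    fwd$status == "ok",
    substr(sequences, fwd$left_end + 1L, fwd$right_start - 1L),
    NA_character_
  )
  fwd$sequence <- sequences # oriented sequence (reverse-complemented if rescued)
  fwd[, c("sequence", "status", "orientation",
          "left_start", "left_end", "right_start", "right_end", "vr")]
}

#' Filter reads and extract their variable regions
#'
#' Applies the read-acceptance rules in a fixed order: a read is rejected as
#' `too_short` if shorter than the design's minimum read length (before any
#' flank search), then as `missing_left` / `missing_right` if a constant
#' flank cannot be located, then as `vr_length_out_of_range` if the
#' extracted variable region falls outside the design's length bounds.
#' The first failing rule wins, so every input read is counted exactly once
#' in the report.
#'
#' @param reads A data frame with columns `id` and `sequence`; a `round`
#'   column, if present, is carried through.
#' @param design A [library_design()].
#' @param max_flank_mismatch Mismatches tolerated per flank (default 0).
#' @return An object of class `selex_filter` with elements `reads` (tibble
#'   of accepted reads: `id`, optional `round`, `sequence` in accepted
#'   orientation, `orientation`, flank spans, `vr`) and `report` (tibble of
#'   `category`, `count`, one row per rejection reason plus `passed`).
#'   `tidy()` returns the accepted reads; `glance()` the report as one row.
#' @examples
#' d <- library_design()
#' reads <- tibble::tibble(
#'   id = c("a", "b"),
#'   sequence = c(paste0(d$left_constant, strrep("A", 40), d$right_constant),
#'                strrep("G", 69))
#' )
#' filter_and_extract(reads, d)
#' @export
filter_and_extract <- function(reads, design, max_flank_mismatch = 0L) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)),
            inherits(design, "library_design"))
  reads <- as_tibble(reads)
  reads$sequence <- toupper(reads$sequence)
  n <- nrow(reads)
  status <- rep(NA_character_, n)

  too_short <- nchar(reads$sequence) < design$min_read_length
  status[too_short] <- "too_short"

  todo <- which(!too_short)
  loc <- NULL
  if (length(todo) > 0) {
    loc <- locate_flanks(reads$sequence[todo], design, max_flank_mismatch)
    status[todo] <- ifelse(loc$status == "ok", NA_character_, loc$status)
    vr_len <- nchar(loc$vr)
    bad_len <- loc$status == "ok" &
      (vr_len < design$vr_min | vr_len > design$vr_max)
    status[todo[bad_len]] <- "vr_length_out_of_range"
  }
  passed_idx <- which(is.na(status))
  status[passed_idx] <- "passed"

  categories <- c("too_short", "missing_left", "missing_right",
                  "vr_length_out_of_range", "multiple_hits", "passed")
  report <- tibble(
    category = categories,
    count = vapply(categories, function(k) sum(status == k), integer(1))
  )

  accepted <- reads[passed_idx, , drop = FALSE]
  if (length(todo) > 0 && length(passed_idx) > 0) {
    keep <- match(passed_idx, todo)
    accepted$sequence <- loc$sequence[keep]
    accepted$orientation <- loc$orientation[keep]
    accepted$left_start <- loc$left_start[keep]
    accepted$left_end <- loc$left_end[keep]
    accepted$right_start <- loc$right_start[keep]
    accepted$right_end <- loc$right_end[keep]
    accepted$vr <- loc$vr[keep]
  } else {
    accepted$orientation <- character(0)
    accepted$left_start <- integer(0)
    accepted$left_end <- integer(0)
    accepted$right_start <- integer(0)
    accepted$right_end <- integer(0)
    accepted$vr <- character(0)
  }

  structure(
    list(
      reads = accepted,
      report = report,
      total = n,
      params = list(max_flank_mismatch = max_flank_mismatch, design = design)
    ),
    class = "selex_filter"
  )
}

#' @export
print.selex_filter <- function(x, ...) {
  cat("<selex_filter> ", x$total, " reads, ",
      x$report$count[x$report$category == "passed"], " passed\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @rdname filter_and_extract
#' @param x A `selex_filter` object.
#' @param ... Unused.
#' @method tidy selex_filter
#' @export
tidy.selex_filter <- function(x, ...) {
  x$reads
}

#' @rdname filter_and_extract
#' @method glance selex_filter
#' @export
glance.selex_filter <- function(x, ...) {
  wide <- as.list(setNames(x$report$count, x$report$category))
  as_tibble(c(list(total = x$total), wide))
}

#' Tabulate accepted variable regions into a per-round count pool
#'
#' Deduplicates variable regions and counts them per round, producing the
#' long count table ("pool") that clustering and enrichment work on.
#'
#' @param x A `selex_filter` object or a data frame with a `vr` column and
#'   optionally a `round` column.
#' @param round Round label used when no `round` column is present
#'   (default `"R1"`).
#' @return A tibble with columns `sequence`, `round` (factor, levels in
#'   order of appearance) and `count`.
#' @export
tally_pool <- function(x, round = "R1") {
  if (inherits(x, "selex_filter")) x <- x$reads
  stopifnot(is.data.frame(x), "vr" %in% names(x))
  if (!"round" %in% names(x)) x$round <- round
  lv <- if (is.factor(x$round)) levels(x$round) else unique(as.character(x$round))
  x %>%
    mutate(round = factor(as.character(.data$round), levels = lv)) %>%
    count(sequence = .data$vr, .data$round, name = "count") %>%
    arrange(.data$round, desc(.data$count), .data$sequence)
}

#' Read a unique-sequence count table
#'
#' Reads a tab-separated table with one row per unique sequence and one
#' count column per round (the format of published SELEX supplementary
#' count tables).  Columns whose names contain "percent" or "%" are
#' ignored; remaining numeric columns are taken as per-round counts.
#' Lines starting with `#` are treated as comments.
#'
#' @param path Path to the tab-separated file.
#' @param sequence_col Name of the sequence column; defaults to the first
#'   character column.
#' @return A long pool tibble (`sequence`, `round`, `count`), as produced
#'   by [tally_pool()].
#' @examples
#' path <- system.file("extdata", "example_pool.tsv", package = "selexr")
#' read_pool_table(path)
#' @export
read_pool_table <- function(path, sequence_col = NULL) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.null(sequence_col)) {
    chr <- names(df)[vapply(df, is.character, logical(1))]
    if (length(chr) == 0) abort("no character (sequence) column found")
    sequence_col <- chr[1]
  }
  count_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  count_cols <- count_cols[!grepl("percent|%", count_cols, ignore.case = TRUE)]
  if (length(count_cols) == 0) abort("no per-round count columns found")
  df %>%
    as_tibble() %>%
    select(sequence = dplyr::all_of(sequence_col), dplyr::all_of(count_cols)) %>%
    mutate(sequence = toupper(.data$sequence)) %>%
    tidyr::pivot_longer(-"sequence", names_to = "round", values_to = "count") %>%
    mutate(round = factor(.data$round, levels = count_cols),
           count = as.integer(round(.data$count))) %>%
    filter(.data$count > 0) %>%
    arrange(.data$round, desc(.data$count), .data$sequence)
}

#' Write a pool as a wide per-round count table
#'
#' @param pool A long pool tibble (`sequence`, `round`, `count`).
#' @param path Output path for the tab-separated table.
#' @param comment Optional character vector of header comment lines
#'   (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_pool_table <- function(pool, path, comment = NULL) {
  wide <- pool_widen(pool)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# long pool -> wide table (sequence, one count column per round), totals desc
pool_widen <- function(pool) {
  pool %>%
    tidyr::pivot_wider(names_from = "round", values_from = "count",
                       values_fill = 0L) %>%
    mutate(total = rowSums(dplyr::across(-"sequence"))) %>%
    arrange(desc(.data$total), .data$sequence) %>%
    select(-"total")
}
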