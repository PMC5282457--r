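# Independent oracles used to cross-check the implementation.  These are
# deliberately written as literal, loop-based transcriptions of the rules
# (and plain dynamic programs), sharing no code with the package internals.

# edit distance by plain DP; equal lengths use positional mismatch counting
oracle_distance <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  if (length(A) == length(B)) {
    return(sum(A != B))
  }
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- numeric(length(B) + 1)
    cur[1] <- i
    for (j in seq_along(B)) {
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(B) + 1]
}

# edit distance by exhaustive recursion (for very short strings only)
oracle_distance_recursive <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  a1 <- substr(a, 1, 1)
  b1 <- substr(b, 1, 1)
  rest_a <- substr(a, 2, nchar(a))
  rest_b <- substr(b, 2, nchar(b))
  min(
    oracle_distance_recursive(rest_a, rest_b) + (a1 != b1),
    oracle_distance_recursive(rest_a, b) + 1,
    oracle_distance_recursive(a, rest_b) + 1
  )
}

# literal transcription of the clustering rules: order by total count
# (descending, lexicographic tie-break); a sequence is a centroid iff it is
# not within `radius` mismatches of any previously defined centroid; the
# rest join their nearest centroid; equal-distance ties are ambiguous
oracle_cluster <- function(uniques, radius) {
  o <- order(-uniques$total_count, uniques$sequence)
  sq <- uniques$sequence[o]
  cents <- character(0)
  for (s in sq) {
    d <- vapply(cents, function(cc) oracle_distance(s, cc), numeric(1))
    if (all(d > radius)) cents <- c(cents, s)
  }
  member_of <- list()
  member_dist <- list()
  ambiguous <- list()
  for (s in setdiff(sq, cents)) {
    d <- vapply(cents, function(cc) oracle_distance(s, cc), numeric(1))
    nearest <- which(d == min(d))
    if (length(nearest) > 1) {
      ambiguous[[s]] <- as.integer(nearest)
    } else {
      member_of[[s]] <- as.integer(nearest)
      member_dist[[s]] <- min(d)
    }
  }
  list(centroids = cents, member_of = member_of, member_dist = member_dist,
       ambiguous = ambiguous)
}

# maximal global-alignment score by exhaustive recursion (short strings)
oracle_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (nchar(a) == 0) return(gap * nchar(b))
  if (nchar(b) == 0) return(gap * nchar(a))
  a1 <- substr(a, 1, 1)
  b1 <- substr(b, 1, 1)
  rest_a <- substr(a, 2, nchar(a))
  rest_b <- substr(b, 2, nchar(b))
  max(
    oracle_align_score(rest_a, rest_b, match, mismatch, gap) +
      if (a1 == b1) match else mismatch,
    oracle_align_score(rest_a, b, match, mismatch, gap) + gap,
    oracle_align_score(a, rest_b, match, mismatch, gap) + gap
  )
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# mutate a sequence with k random substitutions
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(ch), min(k, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a random pool rich in near-duplicates so centroid/member/ambiguous cases
# all occur: new uniques are either fresh or mutated copies of earlier ones
random_test_pool <- function(max_uniques = 50, rounds = 2) {
  n <- sample.int(max_uniques, 1)
  seqs <- character(0)
  while (length(seqs) < n) {
    if (length(seqs) == 0 || stats::runif(1) < 0.4) {
      cand <- random_dna(1, sample(8:10, 1))
    } else {
      cand <- mutate_seq(sample(seqs, 1), sample.int(6, 1))
    }
    seqs <- unique(c(seqs, cand))
  }
  labels <- paste0("R", seq_len(rounds))
  out <- expand.grid(sequence = seqs, round = labels,
                     stringsAsFactors = FALSE)
  out$count <- sample.int(20, nrow(out), replace = TRUE)
  # make some sequences absent from some rounds
  drop <- stats::runif(nrow(out)) < 0.2
  out <- out[!drop, , drop = FALSE]
  if (nrow(out) == 0) out <- data.frame(sequence = seqs[1], round = "R1",
                                        count = 1L)
  tibble::as_tibble(out)
}

# compare a selex_clusters result against the oracle transcription
expect_matches_oracle <- function(clusters, oracle) {
  asn <- clusters$assignments
  expect_identical(clusters$centroids$sequence, oracle$centroids)
  impl_members <- asn[asn$role == "member", ]
  expect_setequal(impl_members$sequence,
                  as.character(names(oracle$member_of)))
  for (i in seq_len(nrow(impl_members))) {
    s <- impl_members$sequence[i]
    expect_identical(impl_members$cluster[i], oracle$member_of[[s]])
    expect_identical(as.numeric(impl_members$distance[i]),
                     as.numeric(oracle$member_dist[[s]]))
  }
  impl_amb <- asn[asn$role == "ambiguous", ]
  expect_setequal(impl_amb$sequence, as.character(names(oracle$ambiguous)))
  for (i in seq_len(nrow(impl_amb))) {
    s <- impl_amb$sequence[i]
    expect_identical(sort(impl_amb$tied[[i]]), sort(oracle$ambiguous[[s]]))
  }
}
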