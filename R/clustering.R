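#' Mismatch distance between sequences
#'
#' For pairs of equal length this is the Hamming distance — the number of
#' mismatched positions, which is what "mismatches" means for a fixed-length
#' variable region.  For pairs of unequal length (the length filter admits a
#' small range) the Levenshtein edit distance is used instead, since
#' positional mismatch counting is undefined there.
#'
#' @param a,b Character vectors of sequences, recycled to a common length;
#'   distances are computed pairwise.
#' @return Integer vector of distances.
#' @examples
#' sequence_distance("AAAA", "AAAT")
#' sequence_distance("ACGTA", "ACGT")
#' @export
sequence_distance <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  eq <- nchar(a) == nchar(b)
  if (any(eq)) {
    out[eq] <- mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)),
                      a[eq], b[eq], USE.NAMES = FALSE)
  }
  if (any(!eq)) {
    out[!eq] <- mapply(function(x, y) adist(x, y), a[!eq], b[!eq],
                       USE.NAMES = FALSE)
  }
  out
}

# all-pairs Hamming distance via one-hot encoding and BLAS; seqs share a length
hamming_full <- function(seqs) {
  n <- length(seqs)
  ch <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  D <- matrix(nchar(seqs[1]), n, n)
  for (base in unique(as.vector(ch))) {
    m <- (ch == base) * 1
    D <- D - tcrossprod(m)
  }
  storage.mode(D) <- "integer"
  D
}

# all-pairs distance matrix: Hamming within equal-length groups, Levenshtein
# across groups (utils::adist)
seq_dist_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) {
    return(hamming_full(seqs))
  }
  D <- adist(seqs, seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (length(idx) > 1) {
      D[idx, idx] <- hamming_full(seqs[idx])
    }
  }
  storage.mode(D) <- "integer"
  D
}

# pool (long) -> uniques in centroid-candidate order: total count descending,
# ties broken lexicographically by sequence
pool_uniques <- function(pool) {
  stopifnot(is.data.frame(pool), all(c("sequence", "count") %in% names(pool)))
  pool %>%
    group_by(.data$sequence) %>%
    summarise(total_count = sum(.data$count), .groups = "drop") %>%
    arrange(desc(.data$total_count), .data$sequence)
}

#' Pick cluster centroids greedily by total abundance
#'
#' Unique sequences are visited in order of decreasing total read count
#' across all rounds (ties broken lexicographically); a sequence becomes a
#' new centroid exactly when its mismatch distance to every
#' previously chosen centroid exceeds `radius`.  "Within `radius`
#' mismatches" is read inclusively: distance <= `radius` blocks a centroid.
#'
#' @param pool A long pool tibble (`sequence`, `round`, `count`), e.g. from
#'   [tally_pool()] or [read_pool_table()].
#' @param radius Mismatch radius (default 4).
#' @return A tibble of centroids in the order chosen: `cluster`,
#'   `sequence`, `total_count`.
#' @export
pick_centroids <- function(pool, radius = 4L) {
  uq <- pool_uniques(pool)
  if (nrow(uq) == 0) {
    return(tibble(cluster = integer(), sequence = character(),
                  total_count = integer()))
  }
  D <- seq_dist_matrix(uq$sequence)
  cent <- integer(0)
  for (i in seq_len(nrow(uq))) {
    if (length(cent) == 0 || all(D[i, cent] > radius)) {
      cent <- c(cent, i)
    }
  }
  tibble(cluster = seq_along(cent),
         sequence = uq$sequence[cent],
         total_count = uq$total_count[cent])
}

#' Assign unique sequences to their nearest centroid
#'
#' Every non-centroid sequence joins the cluster of its unique nearest
#' centroid.  A sequence equidistant from two or more nearest centroids is
#' "ambiguous" and belongs to no cluster; if `max_assignment_distance` is
#' finite, sequences farther than it from every centroid are likewise set
#' aside, flagged `"too_far"`.
#'
#' @inheritParams pick_centroids
#' @param centroids Centroid tibble from [pick_centroids()] on the same
#'   pool.
#' @param max_assignment_distance Optional cap on member distance
#'   (default `Inf`, no cap).
#' @return An object of class `selex_clusters`; see [cluster_pool()].
#' @export
assign_members <- function(pool, centroids, radius = 4L,
                           max_assignment_distance = Inf) {
  uq <- pool_uniques(pool)
  k <- nrow(centroids)
  asn <- uq
  asn$role <- "centroid"
  asn$cluster <- NA_integer_
  asn$distance <- NA_integer_
  asn$tied <- vector("list", nrow(uq))
  asn$flag <- NA_character_

  cent_idx <- match(centroids$sequence, uq$sequence)
  asn$cluster[cent_idx] <- centroids$cluster
  asn$distance[cent_idx] <- 0L

  rest <- setdiff(seq_len(nrow(uq)), cent_idx)
  if (length(rest) > 0 && k > 0) {
    # distances from every non-centroid to every centroid
    lens_r <- nchar(uq$sequence[rest])
    lens_c <- nchar(centroids$sequence)
    if (length(unique(c(lens_r, lens_c))) == 1L) {
      Drc <- matrix(0L, length(rest), k)
      n_all <- length(rest) + k
      seqs <- c(uq$sequence[rest], centroids$sequence)
      ch <- matrix(unlist(strsplit(seqs, "")), nrow = n_all, byrow = TRUE)
      Dfull <- matrix(lens_c[1], length(rest), k)
      for (base in unique(as.vector(ch))) {
        m <- (ch == base) * 1
        Dfull <- Dfull - m[seq_along(rest), , drop = FALSE] %*%
          t(m[length(rest) + seq_len(k), , drop = FALSE])
      }
      Drc <- Dfull
      storage.mode(Drc) <- "integer"
    } else {
      Drc <- matrix(0L, length(rest), k)
      for (j in seq_len(k)) {
        Drc[, j] <- sequence_distance(uq$sequence[rest], centroids$sequence[j])
      }
    }
    for (r in seq_along(rest)) {
      i <- rest[r]
      d <- Drc[r, ]
      m <- min(d)
      tied <- which(d == m)
      if (length(tied) > 1) {
        asn$role[i] <- "ambiguous"
        asn$distance[i] <- m
        asn$tied[[i]] <- as.integer(tied)
        asn$flag[i] <- "tie"
      } else if (m > max_assignment_distance) {
        asn$role[i] <- "ambiguous"
        asn$distance[i] <- m
        asn$tied[[i]] <- as.integer(tied)
        asn$flag[i] <- "too_far"
      } else {
        asn$role[i] <- "member"
        asn$cluster[i] <- tied
        asn$distance[i] <- m
      }
    }
  }

  structure(
    list(
      assignments = asn,
      centroids = centroids,
      pool = pool,
      params = list(radius = radius,
                    max_assignment_distance = max_assignment_distance)
    ),
    class = "selex_clusters"
  )
}

#' Cluster a pooled unique-sequence table by mismatch radius
#'
#' Composes [pick_centroids()] and [assign_members()]: greedy
#' abundance-ordered centroid selection on the multi-round pooled counts,
#' then nearest-centroid assignment with equidistant ties set aside as
#' ambiguous.  Deterministic for a fixed pool regardless of row order.
#'
#' @inheritParams assign_members
#' @return An object of class `selex_clusters` with elements
#'   `assignments` (tibble: `sequence`, `total_count`, `role` in
#'   centroid/member/ambiguous, `cluster`, `distance`, `tied` list-column of
#'   tied cluster ids, `flag`), `centroids`, the input `pool` and `params`.
#'   `tidy()` returns the assignment tibble, `glance()` a one-row summary.
#' @examples
#' pool <- tibble::tibble(
#'   sequence = c("AAAAAAAA", "AAAAAAAT", "GGGGGGGG"),
#'   round = "R1",
#'   count = c(10L, 3L, 5L)
#' )
#' cluster_pool(pool, radius = 4)
#' @export
cluster_pool <- function(pool, radius = 4L, max_assignment_distance = Inf) {
  if (radius < 0) abort("radius must be >= 0")
  centroids <- pick_centroids(pool, radius = radius)
  assign_members(pool, centroids, radius = radius,
                 max_assignment_distance = max_assignment_distance)
}

#' @export
print.selex_clusters <- function(x, ...) {
  g <- glance(x)
  cat("<selex_clusters> ", g$n_unique, " unique sequences in ",
      g$n_clusters, " clusters (radius ", x$params$radius, "), ",
      g$n_ambiguous, " ambiguous\n", sep = "")
  print(head(x$centroids, 5))
  invisible(x)
}

#' @rdname cluster_pool
#' @param x A `selex_clusters` object.
#' @param ... Unused.
#' @method tidy selex_clusters
#' @export
tidy.selex_clusters <- function(x, ...) {
  x$assignments
}

#' @rdname cluster_pool
#' @method glance selex_clusters
#' @export
glance.selex_clusters <- function(x, ...) {
  tibble(
    n_unique = nrow(x$assignments),
    n_clusters = nrow(x$centroids),
    n_members = sum(x$assignments$role == "member"),
    n_ambiguous = sum(x$assignments$role == "ambiguous"),
    radius = x$params$radius
  )
}

#' Write a cluster table
#'
#' One row per unique sequence: cluster id, role, distance to centroid and
#' per-round counts, tab-separated.
#'
#' @param clusters A `selex_clusters` object.
#' @param path Output path.
#' @param comment Optional header comment lines (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path, comment = NULL) {
  wide <- pool_widen(clusters$pool)
  tab <- clusters$assignments %>%
    mutate(tied = vapply(.data$tied, function(t) {
      if (is.null(t)) "" else paste(t, collapse = ",")
    }, character(1))) %>%
    left_join(wide, by = "sequence") %>%
    arrange(.data$role != "centroid", .data$cluster, desc(.data$total_count))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# radius: ", clusters$params$radius), con)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
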