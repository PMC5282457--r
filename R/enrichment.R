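#' Per-round pool enrichment percentage
#'
#' Diversity collapse of a selection round is summarized as
#' `(1 - unique_sequences / total_reads) * 100`: 0 when every read is
#' distinct, approaching 100 as the pool converges on few sequences.
#'
#' @param pool A long pool tibble (`sequence`, `round`, `count`).
#' @return A tibble of class `selex_enrichment` with columns `round`,
#'   `total_reads`, `unique_count`, `enrichment_percent`.
#' @examples
#' pool <- tibble::tibble(sequence = c("AC", "GT"), round = "R1",
#'                        count = c(99L, 1L))
#' round_enrichment(pool)
#' @export
round_enrichment <- function(pool) {
  stopifnot(is.data.frame(pool),
            all(c("sequence", "round", "count") %in% names(pool)))
  out <- pool %>%
    group_by(.data$round) %>%
    summarise(
      total_reads = sum(.data$count),
      unique_count = sum(.data$count > 0),
      .groups = "drop"
    )
  if (any(out$total_reads == 0)) {
    abort("enrichment undefined for a round with zero total reads")
  }
  out <- out %>%
    mutate(enrichment_percent = (1 - .data$unique_count / .data$total_reads) * 100)
  class(out) <- c("selex_enrichment", class(out))
  out
}

#' Per-cluster abundance trajectories across rounds
#'
#' For each cluster and round, the cluster-inclusive abundance is
#' `100 * (centroid + member counts in the round) / (round total)`; the
#' centroid-exact variant (`centroid_percent`, the centroid sequence's own
#' counts only) is reported alongside.  Pseudo-rows `ambiguous` (equidistant
#' ties) and, when an assignment cap is in use, `unclustered` complete the
#' partition, so per round the cluster-inclusive percentages sum to 100.
#'
#' @param clusters A `selex_clusters` object from [cluster_pool()].
#' @return A tibble of class `selex_trajectory`: `label` (`"C1"`, `"C2"`,
#'   ... in centroid order, plus `"ambiguous"` / `"unclustered"`),
#'   `cluster`, `centroid`, `round`, `abundance_percent`,
#'   `centroid_percent`.  Rounds with zero total reads yield `NA`
#'   percentages.
#' @export
abundance_trajectory <- function(clusters) {
  stopifnot(inherits(clusters, "selex_clusters"))
  pool <- clusters$pool
  asn <- clusters$assignments
  rounds <- if (is.factor(pool$round)) levels(pool$round) else unique(as.character(pool$round))
  totals <- pool %>%
    mutate(round = factor(as.character(.data$round), levels = rounds)) %>%
    group_by(.data$round, .drop = FALSE) %>%
    summarise(round_total = sum(.data$count), .groups = "drop")

  grp <- asn %>%
    select("sequence", "role", "cluster", "flag") %>%
    mutate(label = dplyr::case_when(
      role %in% c("centroid", "member") ~ paste0("C", cluster),
      flag == "too_far" ~ "unclustered",
      TRUE ~ "ambiguous"
    ))

  counts <- pool %>%
    mutate(round = factor(as.character(.data$round), levels = rounds)) %>%
    left_join(grp, by = "sequence")

  labels <- c(paste0("C", clusters$centroids$cluster), "ambiguous", "unclustered")
  labels <- labels[labels %in% c(unique(grp$label), "ambiguous")]

  cluster_counts <- counts %>%
    group_by(label = factor(.data$label, levels = labels),
             .data$round, .drop = FALSE) %>%
    summarise(count = sum(.data$count), .groups = "drop")

  centroid_counts <- counts %>%
    filter(.data$role == "centroid") %>%
    group_by(label = factor(.data$label, levels = labels),
             .data$round, .drop = FALSE) %>%
    summarise(centroid_count = sum(.data$count), .groups = "drop")

  out <- cluster_counts %>%
    left_join(centroid_counts, by = c("label", "round")) %>%
    left_join(totals, by = "round") %>%
    mutate(
      abundance_percent = ifelse(.data$round_total > 0,
                                 100 * .data$count / .data$round_total, NA_real_),
      centroid_percent = ifelse(
        .data$label %in% c("ambiguous", "unclustered"), NA_real_,
        ifelse(.data$round_total > 0,
               100 * .data$centroid_count / .data$round_total, NA_real_)
      ),
      label = as.character(.data$label),
      cluster = suppressWarnings(as.integer(sub("^C", "", .data$label)))
    ) %>%
    left_join(
      clusters$centroids %>% select(cluster = "cluster", centroid = "sequence"),
      by = "cluster"
    ) %>%
    select("label", "cluster", "centroid", "round",
           "abundance_percent", "centroid_percent") %>%
    arrange(!is.na(.data$cluster), .data$cluster, .data$round) %>%
    arrange(is.na(.data$cluster), .data$cluster, .data$round)
  class(out) <- c("selex_trajectory", class(out))
  out
}

#' Per-position mismatch profile of a cluster
#'
#' Counts, at every centroid position, how many member sequences differ
#' from the centroid there.  Members whose length differs from the
#' centroid's are excluded (indel placement would be alignment-dependent);
#' their number is recorded in the `n_excluded` attribute.
#'
#' @param clusters A `selex_clusters` object.
#' @param cluster Cluster id (default 1, the top cluster).
#' @return A tibble with columns `position` (1-based) and `mismatches`,
#'   one row per centroid position; attribute `n_excluded` gives the count
#'   of unequal-length members left out.
#' @export
mutation_profile <- function(clusters, cluster = 1L) {
  stopifnot(inherits(clusters, "selex_clusters"))
  cent <- clusters$centroids$sequence[clusters$centroids$cluster == cluster]
  if (length(cent) != 1) abort(paste0("no cluster with id ", cluster))
  members <- clusters$assignments %>%
    filter(.data$role == "member", .data$cluster == !!cluster)
  same_len <- members$sequence[nchar(members$sequence) == nchar(cent)]
  n_excluded <- nrow(members) - length(same_len)
  L <- nchar(cent)
  mism <- integer(L)
  if (length(same_len) > 0) {
    cm <- strsplit(cent, "")[[1]]
    mm <- matrix(unlist(strsplit(same_len, "")), ncol = L, byrow = TRUE)
    mism <- as.integer(colSums(mm != matrix(cm, nrow = length(same_len),
                                            ncol = L, byrow = TRUE)))
  }
  out <- tibble(position = seq_len(L), mismatches = mism)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "centroid") <- cent
  out
}

#' Split a cluster's mismatches by a motif span
#'
#' Given the conserved-motif interval within the centroid, sums the
#' per-position mismatch profile inside and outside the span.  The motif is
#' conserved in the cluster exactly when the in-motif mismatch count is 0.
#'
#' @inheritParams mutation_profile
#' @param motif Integer vector `c(start, end)`, a 1-based inclusive
#'   interval within the centroid variable region.
#' @return A one-row tibble: `in_motif`, `out_motif`, `conserved`.
#' @export
motif_conservation <- function(clusters, motif, cluster = 1L) {
  prof <- mutation_profile(clusters, cluster = cluster)
  L <- nrow(prof)
  if (length(motif) != 2 || motif[1] < 1 || motif[2] > L || motif[1] > motif[2]) {
    abort("motif span must be c(start, end) with 1 <= start <= end <= centroid length")
  }
  inside <- prof$position >= motif[1] & prof$position <= motif[2]
  tibble(
    in_motif = sum(prof$mismatches[inside]),
    out_motif = sum(prof$mismatches[!inside]),
    conserved = sum(prof$mismatches[inside]) == 0L
  )
}

#' Plot enrichment per round
#'
#' @param object A `selex_enrichment` tibble from [round_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selex_enrichment
#' @export
autoplot.selex_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$round,
                                       y = .data$enrichment_percent,
                                       group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "selection round", y = "% enrichment",
                  title = "Pool enrichment per selection round")
}

#' Plot per-cluster abundance trajectories
#'
#' @param object A `selex_trajectory` tibble from [abundance_trajectory()].
#' @param top Number of top clusters to show (by mean abundance across
#'   rounds); pseudo-rows (ambiguous/unclustered) are always dropped.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selex_trajectory
#' @export
autoplot.selex_trajectory <- function(object, top = 5, ...) {
  real <- object %>% filter(!is.na(.data$cluster))
  keep <- real %>%
    group_by(.data$label) %>%
    summarise(m = mean(.data$abundance_percent, na.rm = TRUE), .groups = "drop") %>%
    arrange(desc(.data$m)) %>%
    head(top)
  real %>%
    filter(.data$label %in% keep$label) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$round, y = .data$abundance_percent,
                                 colour = .data$label, group = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "selection round", y = "% of round reads",
                  colour = "cluster",
                  title = "Cluster abundance across selection rounds")
}

#' Plot a cluster mutation profile
#'
#' @param profile A tibble from [mutation_profile()].
#' @param motif Optional `c(start, end)` motif span to shade.
#' @return A ggplot object.
#' @export
plot_mutation_profile <- function(profile, motif = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position,
                                             y = .data$mismatches)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position in variable region",
                  y = "members mismatching centroid",
                  title = "Per-position variation within cluster")
  if (!is.null(motif)) {
    p <- p + ggplot2::annotate("rect", xmin = motif[1] - 0.5,
                               xmax = motif[2] + 0.5,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
  }
  p
}

#' Write a trajectory table in wide per-round layout
#'
#' Rows are clusters (plus ambiguous/unclustered), columns are rounds,
#' values are cluster-inclusive abundance percentages printed to one
#' decimal place.
#'
#' @param trajectory A `selex_trajectory` tibble.
#' @param path Output path.
#' @param digits Decimal places for the percentages (default 1).
#' @param comment Optional header comment lines (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(trajectory, path, digits = 1, comment = NULL) {
  wide <- trajectory %>%
    mutate(abundance_percent = round(.data$abundance_percent, digits)) %>%
    select("label", "centroid", "round", "abundance_percent") %>%
    tidyr::pivot_wider(names_from = "round", values_from = "abundance_percent")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
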