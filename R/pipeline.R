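#' Run the SELEX analysis pipeline end to end
#'
#' Composes the analysis stages: optional demultiplexing by round barcode,
#' read filtering and variable-region extraction, deduplication into a
#' per-round count pool, mismatch-radius clustering of the pooled uniques,
#' and per-round enrichment plus per-cluster abundance trajectories.  The
#' entry point may equally be a pre-tabulated unique-sequence count table
#' (the published supplementary-table format), in which case the read-level
#' stages are skipped.
#'
#' @param x One of: a `selex_simulation` from [run_selection()]; a data
#'   frame of reads (`id`, `sequence`, optional `round`); or a long pool
#'   tibble (`sequence`, `round`, `count`) such as [read_pool_table()]
#'   returns.
#' @param design A [library_design()].
#' @param radius Cluster mismatch radius (default 4).
#' @param max_flank_mismatch Mismatches tolerated per constant flank
#'   (default 0).
#' @param max_assignment_distance Optional cap on member assignment
#'   distance (default `Inf`).
#' @param barcodes Optional named barcode vector for [demultiplex()] when
#'   reads carry no `round` column.
#' @param max_barcode_mismatch Barcode mismatch tolerance (default 0).
#' @return An object of class `selex_run`: a list with `filter` (a
#'   `selex_filter`, or `NULL` for table input), `pool`, `clusters`,
#'   `enrichment`, `trajectory` and a stage-count `log` tibble.  `tidy()`
#'   returns the trajectory, `glance()` a one-row summary.
#' @examples
#' cfg <- selex_sim_config(n_library = 20, depth_per_round = 200, rounds = 2,
#'                         sticky_s = 50, seed = 7)
#' run <- run_selex_pipeline(run_selection(cfg))
#' glance(run)
#' @export
run_selex_pipeline <- function(x,
                               design = library_design(),
                               radius = 4L,
                               max_flank_mismatch = 0L,
                               max_assignment_distance = Inf,
                               barcodes = NULL,
                               max_barcode_mismatch = 0L) {
  if (inherits(x, "selex_simulation")) x <- x$reads
  stopifnot(is.data.frame(x))
  is_pool <- all(c("sequence", "round", "count") %in% names(x)) &&
    !"id" %in% names(x)

  log <- list()
  filt <- NULL
  if (is_pool) {
    pool <- as_tibble(x)
    if (!is.factor(pool$round)) {
      pool$round <- factor(pool$round, levels = unique(as.character(pool$round)))
    }
    log$input_sequences <- nrow(pool)
  } else {
    reads <- as_tibble(x)
    log$input_reads <- nrow(reads)
    if (!is.null(barcodes) && !"round" %in% names(reads)) {
      reads <- demultiplex(reads, barcodes, max_barcode_mismatch)
      log$unassigned_barcode <- sum(is.na(reads$round))
      reads <- reads %>% filter(!is.na(.data$round))
    }
    filt <- filter_and_extract(reads, design, max_flank_mismatch)
    passed <- filt$report$count[filt$report$category == "passed"]
    rejected <- sum(filt$report$count) - passed
    stopifnot(passed + rejected == filt$total) # conservation
    log$passed <- passed
    log$rejected <- rejected
    if (passed == 0) {
      warn("no reads passed the filters; downstream tables are empty")
    }
    pool <- tally_pool(filt)
  }

  clusters <- cluster_pool(pool, radius = radius,
                           max_assignment_distance = max_assignment_distance)
  n_uniques <- nrow(clusters$assignments)
  stopifnot(sum(clusters$assignments$role %in%
                  c("centroid", "member", "ambiguous")) == n_uniques)
  log$unique_sequences <- n_uniques
  log$clusters <- nrow(clusters$centroids)
  log$ambiguous <- sum(clusters$assignments$role == "ambiguous")

  enrichment <- if (nrow(pool) > 0) round_enrichment(pool) else
    structure(tibble(round = factor(), total_reads = integer(),
                     unique_count = integer(), enrichment_percent = double()),
              class = c("selex_enrichment", "tbl_df", "tbl", "data.frame"))
  trajectory <- abundance_trajectory(clusters)

  structure(
    list(
      filter = filt,
      pool = pool,
      clusters = clusters,
      enrichment = enrichment,
      trajectory = trajectory,
      log = tibble(stage = names(log), count = unlist(log, use.names = FALSE)),
      params = list(radius = radius,
                    max_flank_mismatch = max_flank_mismatch,
                    max_assignment_distance = max_assignment_distance)
    ),
    class = "selex_run"
  )
}

#' @export
print.selex_run <- function(x, ...) {
  cat("<selex_run>\n")
  print(x$log)
  invisible(x)
}

#' @rdname run_selex_pipeline
#' @param ... Unused.
#' @method tidy selex_run
#' @export
tidy.selex_run <- function(x, ...) {
  x$trajectory
}

#' @rdname run_selex_pipeline
#' @method glance selex_run
#' @export
glance.selex_run <- function(x, ...) {
  g <- glance(x$clusters)
  top1 <- x$trajectory %>%
    filter(.data$cluster == 1L) %>%
    arrange(.data$round) %>%
    head(1)
  g$top_cluster_round1_percent <-
    if (nrow(top1) > 0) top1$abundance_percent else NA_real_
  first_enrich <- if (nrow(x$enrichment) > 0) {
    x$enrichment$enrichment_percent[1]
  } else {
    NA_real_
  }
  g$enrichment_round1_percent <- first_enrich
  g
}

#' Write all pipeline tables to a directory
#'
#' Writes the filter report, the wide per-round pool table, the cluster
#' table, the per-round enrichment table and the wide trajectory table as
#' tab-separated files with parameter header comments.  Output is
#' deterministic: re-running an identical pipeline writes byte-identical
#' files.
#'
#' @param run A `selex_run` object.
#' @param outdir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_selex_run <- function(run, outdir) {
  stopifnot(inherits(run, "selex_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    paste0("radius: ", run$params$radius),
    paste0("max_flank_mismatch: ", run$params$max_flank_mismatch),
    paste0("max_assignment_distance: ", run$params$max_assignment_distance)
  )
  files <- character(0)

  if (!is.null(run$filter)) {
    p <- file.path(outdir, "filter_report.tsv")
    con <- file(p, "w")
    writeLines(paste0("# ", hdr), con)
    write.table(run$filter$report, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    files <- c(files, p)
  }

  p <- file.path(outdir, "pool.tsv")
  write_pool_table(run$pool, p, comment = hdr)
  files <- c(files, p)

  p <- file.path(outdir, "clusters.tsv")
  write_cluster_table(run$clusters, p, comment = hdr)
  files <- c(files, p)

  p <- file.path(outdir, "enrichment.tsv")
  con <- file(p, "w")
  writeLines(paste0("# ", hdr), con)
  write.table(as.data.frame(run$enrichment), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  files <- c(files, p)

  p <- file.path(outdir, "trajectory.tsv")
  write_trajectory_table(run$trajectory, p, comment = hdr)
  files <- c(files, p)

  invisible(files)
}
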