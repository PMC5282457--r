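test_that("round enrichment is (1 - unique/total) * 100", {
  all_distinct <- tibble::tibble(sequence = random_dna(10, 8), round = "R1",
                                 count = 1L)
  expect_equal(round_enrichment(all_distinct)$enrichment_percent, 0)

  one_seq <- tibble::tibble(sequence = "ACGTACGT", round = "R1", count = 100L)
  expect_equal(round_enrichment(one_seq)$enrichment_percent, 99)

  set.seed(14)
  # 120 unique sequences carrying 1000 reads in total
  pool <- tibble::tibble(sequence = random_dna(120, 10), round = "R1",
                         count = c(881L, rep(1L, 119)))
  expect_equal(round_enrichment(pool)$enrichment_percent, 88)
})

test_that("enrichment grows as duplicate reads are added and ignores labels", {
  pool <- tibble::tibble(sequence = c("AAAA", "CCCC"), round = "R1",
                         count = c(5L, 5L))
  e1 <- round_enrichment(pool)$enrichment_percent
  more <- pool
  more$count <- more$count + 10L
  expect_gt(round_enrichment(more)$enrichment_percent, e1)
  relabeled <- pool
  relabeled$sequence <- c("GGGG", "TTTT")
  expect_equal(round_enrichment(relabeled)$enrichment_percent, e1)
})

test_that("enrichment of an empty round is an error", {
  pool <- tibble::tibble(sequence = "AAAA",
                         round = factor("R1", levels = c("R1", "R2")),
                         count = 0L)
  expect_error(round_enrichment(pool), "zero total")
})

test_that("abundance percentages partition each round", {
  set.seed(15)
  for (i in 1:5) {
    pool <- random_test_pool(max_uniques = 30, rounds = 3)
    cl <- cluster_pool(pool, radius = 4)
    traj <- abundance_trajectory(cl)
    sums <- tapply(traj$abundance_percent, traj$round, sum, na.rm = TRUE)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  }
})

test_that("a single cluster holding every read sits at 100 percent", {
  set.seed(16)
  cent <- random_dna(1, 40)
  pool <- tibble::tibble(
    sequence = c(cent, mutate_seq(cent, 1), mutate_seq(cent, 2)),
    round = rep("R1", 3),
    count = c(50L, 3L, 2L)
  ) |> dplyr::distinct(sequence, .keep_all = TRUE)
  traj <- abundance_trajectory(cluster_pool(pool))
  expect_equal(traj$abundance_percent[traj$label == "C1"], 100)
})

test_that("cluster-inclusive and centroid-exact percentages are both reported", {
  cent <- strrep("A", 40)
  member <- paste0(strrep("A", 39), "T")
  pool <- tibble::tibble(sequence = c(cent, member), round = "R1",
                         count = c(80L, 20L))
  traj <- abundance_trajectory(cluster_pool(pool))
  c1 <- traj[traj$label == "C1", ]
  expect_equal(c1$abundance_percent, 100)
  expect_equal(c1$centroid_percent, 80)
})

test_that("rounds absent from the pool give missing percentages", {
  pool <- tibble::tibble(sequence = "AAAA",
                         round = factor("R1", levels = c("R1", "R2")),
                         count = 10L)
  traj <- abundance_trajectory(cluster_pool(pool))
  expect_true(is.na(traj$abundance_percent[traj$label == "C1" &
                                             traj$round == "R2"]))
  expect_equal(traj$abundance_percent[traj$label == "C1" &
                                        traj$round == "R1"], 100)
})

test_that("mutation profiles count per-position member mismatches", {
  cent <- strrep("A", 10)
  pool <- tibble::tibble(
    sequence = c(cent, cent_sub3 <- paste0("AA", "T", strrep("A", 7))),
    round = "R1", count = c(10L, 1L)
  )
  prof <- mutation_profile(cluster_pool(pool))
  expect_equal(prof$mismatches, c(0, 0, 1, rep(0, 7)))

  # members identical in aggregate: all-zero profile needs no members differing
  pool0 <- tibble::tibble(sequence = cent, round = "R1", count = 5L)
  expect_equal(mutation_profile(cluster_pool(pool0))$mismatches, rep(0L, 10))
})

test_that("random planted substitutions match a brute-force positional tally", {
  set.seed(17)
  cent <- random_dna(1, 40)
  members <- unique(vapply(1:12, function(i) mutate_seq(cent, sample(1:3, 1)),
                           character(1)))
  members <- setdiff(members, cent)
  pool <- tibble::tibble(sequence = c(cent, members), round = "R1",
                         count = c(100L, rep(1L, length(members))))
  prof <- mutation_profile(cluster_pool(pool))
  cm <- strsplit(cent, "")[[1]]
  manual <- rep(0L, 40)
  for (m in members) {
    mm <- strsplit(m, "")[[1]]
    manual <- manual + as.integer(mm != cm)
  }
  expect_equal(prof$mismatches, manual)
})

test_that("unequal-length members are excluded from profiles but reported", {
  cent <- strrep("A", 10)
  indel <- strrep("A", 9) # distance 1 (Levenshtein), joins the cluster
  pool <- tibble::tibble(sequence = c(cent, indel), round = "R1",
                         count = c(10L, 1L))
  cl <- cluster_pool(pool)
  prof <- mutation_profile(cl)
  expect_equal(attr(prof, "n_excluded"), 1L)
  expect_equal(prof$mismatches, rep(0L, 10))
})

test_that("motif conservation splits mismatches by span", {
  set.seed(18)
  cent <- random_dna(1, 40)
  # plant substitutions only outside the motif span 10..30
  outside <- c(1:9, 31:40)
  members <- vapply(1:6, function(i) {
    ch <- strsplit(cent, "")[[1]]
    p <- sample(outside, 1)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  members <- setdiff(unique(members), cent)
  pool <- tibble::tibble(sequence = c(cent, members), round = "R1",
                         count = c(50L, rep(1L, length(members))))
  cl <- cluster_pool(pool)
  mc <- motif_conservation(cl, motif = c(10, 30))
  expect_equal(mc$in_motif, 0L)
  expect_gt(mc$out_motif, 0L)
  expect_true(mc$conserved)

  # a single in-motif substitution breaks conservation
  ch <- strsplit(cent, "")[[1]]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  pool2 <- tibble::tibble(sequence = c(cent, paste(ch, collapse = "")),
                          round = "R1", count = c(50L, 1L))
  mc2 <- motif_conservation(cluster_pool(pool2), motif = c(10, 30))
  expect_equal(mc2$in_motif, 1L)
  expect_equal(mc2$out_motif, 0L)
  expect_false(mc2$conserved)

  # no members at all: (0, 0)
  mc0 <- motif_conservation(cluster_pool(
    tibble::tibble(sequence = cent, round = "R1", count = 5L)
  ), motif = c(10, 30))
  expect_equal(c(mc0$in_motif, mc0$out_motif), c(0L, 0L))

  expect_error(motif_conservation(cl, motif = c(0, 30)), "span")
  expect_error(motif_conservation(cl, motif = c(10, 41)), "span")
})

test_that("plot methods return ggplot objects", {
  set.seed(19)
  pool <- random_test_pool(max_uniques = 15, rounds = 3)
  cl <- cluster_pool(pool)
  expect_s3_class(ggplot2::autoplot(round_enrichment(pool)), "ggplot")
  expect_s3_class(ggplot2::autoplot(abundance_trajectory(cl)), "ggplot")
  expect_s3_class(plot_mutation_profile(mutation_profile(cl), motif = c(2, 4)),
                  "ggplot")
})
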