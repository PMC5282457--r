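make_pool <- function(seqs, counts) {
  tibble::tibble(sequence = seqs, round = "R1", count = as.integer(counts))
}

test_that("sequence distance is Hamming for equal, Levenshtein for unequal lengths", {
  expect_equal(sequence_distance("ACGT", "ACGT"), 0L)
  expect_equal(sequence_distance("AAAA", "AAAT"), 1L)
  expect_equal(sequence_distance("ACGTA", "ACGT"), 1L)
  # vectorized and symmetric
  expect_equal(sequence_distance(c("AAAA", "ACGTA"), c("AAAT", "ACGT")),
               c(1L, 1L))
  set.seed(7)
  a <- random_dna(20, sample(3:9, 20, replace = TRUE))
  b <- random_dna(20, sample(3:9, 20, replace = TRUE))
  expect_equal(sequence_distance(a, b), sequence_distance(b, a))
  expect_equal(sequence_distance(a, b),
               mapply(oracle_distance, a, b, USE.NAMES = FALSE))
})

test_that("edit distance agrees with exhaustive recursion on short strings", {
  set.seed(8)
  a <- random_dna(15, sample(1:5, 15, replace = TRUE))
  b <- random_dna(15, sample(1:5, 15, replace = TRUE))
  expect_equal(sequence_distance(a, b),
               mapply(oracle_distance_recursive, a, b, USE.NAMES = FALSE))
})

test_that("greedy centroid picking follows the abundance-and-radius rule", {
  # a single unique sequence is the sole centroid
  one <- pick_centroids(make_pool("ACGTACGT", 5))
  expect_equal(one$sequence, "ACGTACGT")

  # B within radius of A never becomes a centroid
  a <- strrep("A", 10)
  b <- paste0(strrep("A", 8), "TT") # distance 2
  two <- pick_centroids(make_pool(c(a, b), c(10, 3)), radius = 4)
  expect_equal(two$sequence, a)

  # at distance 6 > 4 both are centroids, in count order
  b6 <- paste0(strrep("A", 4), strrep("T", 6)) # distance 6 from a
  both <- pick_centroids(make_pool(c(a, b6), c(10, 8)), radius = 4)
  expect_equal(both$sequence, c(a, b6))
})

test_that("count ties in centroid order break lexicographically", {
  s1 <- "CCCCCCCCCC"
  s2 <- "GGGGGGGGGG"
  res <- pick_centroids(make_pool(c(s2, s1), c(5, 5)), radius = 4)
  expect_equal(res$sequence, c(s1, s2))
})

test_that("members join their nearest centroid; ties are ambiguous", {
  a <- strrep("A", 10)
  b <- paste0(strrep("A", 4), strrep("T", 6)) # d(a,b) = 6
  mid <- paste0(strrep("A", 7), strrep("T", 3)) # d=3 to both
  near_a <- paste0(strrep("A", 9), "T") # d=1 to a, 5 to b
  pool <- make_pool(c(a, b, mid, near_a), c(20, 15, 2, 1))
  cl <- cluster_pool(pool, radius = 4)
  asn <- tidy(cl)
  expect_equal(asn$role[asn$sequence == mid], "ambiguous")
  expect_equal(sort(asn$tied[asn$sequence == mid][[1]]), c(1L, 2L))
  expect_equal(asn$role[asn$sequence == near_a], "member")
  expect_equal(asn$cluster[asn$sequence == near_a], 1L)
  expect_equal(asn$distance[asn$sequence == near_a], 1L)
})

test_that("clusters with no non-centroid sequences have empty member lists", {
  a <- strrep("A", 10)
  g <- strrep("G", 10)
  cl <- cluster_pool(make_pool(c(a, g), c(5, 4)))
  expect_equal(glance(cl)$n_clusters, 2L)
  expect_equal(glance(cl)$n_members, 0L)
  expect_equal(glance(cl)$n_ambiguous, 0L)
})

test_that("a planted family clusters together; distant families split", {
  set.seed(9)
  cent <- random_dna(1, 40)
  sats <- vapply(1:5, function(i) mutate_seq(cent, sample(1:2, 1)), character(1))
  pool <- make_pool(c(cent, unique(sats)),
                    c(100, seq_len(length(unique(sats))) + 1))
  cl <- cluster_pool(pool, radius = 4)
  expect_equal(glance(cl)$n_clusters, 1L)
  expect_equal(glance(cl)$n_members, length(unique(sats)))

  # second family at large distance forms its own cluster
  far <- chartr("ACGT", "GTAC", cent) # distance 40
  pool2 <- rbind(pool, make_pool(c(far, mutate_seq(far, 2)), c(50, 3)))
  cl2 <- cluster_pool(pool2, radius = 4)
  expect_equal(glance(cl2)$n_clusters, 2L)
  expect_equal(glance(cl2)$n_ambiguous, 0L)
})

test_that("an assignment-distance cap sets distant sequences aside", {
  a <- strrep("A", 12)
  near3 <- paste0(strrep("A", 9), "CCC") # distance 3: not a centroid
  cl <- cluster_pool(make_pool(c(a, near3), c(10, 1)), radius = 4,
                     max_assignment_distance = 2)
  asn <- tidy(cl)
  expect_equal(asn$role[asn$sequence == near3], "ambiguous")
  expect_equal(asn$flag[asn$sequence == near3], "too_far")
  # without the cap the same sequence is an ordinary member
  no_cap <- tidy(cluster_pool(make_pool(c(a, near3), c(10, 1)), radius = 4))
  expect_equal(no_cap$role[no_cap$sequence == near3], "member")
})

test_that("every unique sequence appears exactly once in the partition", {
  set.seed(10)
  for (i in 1:10) {
    pool <- random_test_pool(max_uniques = 40)
    cl <- cluster_pool(pool, radius = 4)
    asn <- tidy(cl)
    expect_setequal(asn$sequence, unique(pool$sequence))
    expect_equal(nrow(asn), length(unique(pool$sequence)))
    expect_true(all(asn$role %in% c("centroid", "member", "ambiguous")))
    # centroids pairwise more than radius apart
    if (nrow(cl$centroids) > 1) {
      pairs <- utils::combn(nrow(cl$centroids), 2)
      d <- sequence_distance(cl$centroids$sequence[pairs[1, ]],
                             cl$centroids$sequence[pairs[2, ]])
      expect_true(all(d > 4))
    }
    # recorded member distances are true distances
    mem <- asn[asn$role == "member", ]
    if (nrow(mem) > 0) {
      expect_equal(mem$distance,
                   sequence_distance(mem$sequence,
                                     cl$centroids$sequence[mem$cluster]))
    }
  }
})

test_that("input row order never changes the clustering", {
  set.seed(12)
  for (i in 1:5) {
    pool <- random_test_pool(max_uniques = 30)
    cl1 <- cluster_pool(pool, radius = 4)
    cl2 <- cluster_pool(pool[sample.int(nrow(pool)), ], radius = 4)
    expect_equal(cl1$centroids, cl2$centroids)
    expect_equal(cl1$assignments, cl2$assignments)
  }
})

test_that("greedy clustering matches the brute-force rule transcription", {
  set.seed(13)
  for (i in 1:25) {
    pool <- random_test_pool(max_uniques = 50)
    cl <- cluster_pool(pool, radius = 4)
    uq <- dplyr::summarise(dplyr::group_by(pool, sequence),
                           total_count = sum(count), .groups = "drop")
    expect_matches_oracle(cl, oracle_cluster(uq, radius = 4))
  }
})
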