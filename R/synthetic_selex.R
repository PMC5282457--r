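#' Configure a synthetic SELEX selection
#'
#' Bundles the parameters of the forward selection-round simulator.  The
#' defaults describe the regime the package's analyses are built for: a
#' library of 1000 distinct founder variable regions of 40 nt with uniform
#' starting fractions, three "sticky" founders whose multiplicative
#' selection coefficients let the top one take over most of the pool within
#' a single round, seven selection rounds sequenced at 10,000 reads each,
#' and a low per-base substitution error.
#'
#' Selection is modeled per round as `f' = s * f / sum(s * f)`: one
#' coefficient per founder folding cell binding, internalization, nuclease
#' survival and amplification into a single factor.
#'
#' @param n_library Number of distinct founder variable regions.
#' @param vr_lengths Integer vector of admissible VR lengths (default 40).
#' @param vr_length_probs Sampling probabilities for `vr_lengths`
#'   (default uniform).
#' @param design A [library_design()] providing the constant flanks.
#' @param sticky_s Selection coefficients of the planted sticky founders
#'   (one per sticky founder); all other founders get
#'   `default_coefficient`.
#' @param sticky_vr Optional character vector of planted sticky VRs; by
#'   default the first founders generated take the sticky role.  Planted
#'   VRs must be pairwise more than `2 * sticky_min_separation / 2`
#'   mismatches apart (see `sticky_min_separation`).
#' @param sticky_min_separation Minimum pairwise distance enforced between
#'   sticky VRs so planted truth stays recoverable by clustering; default 9
#'   (more than twice the default cluster radius of 4).
#' @param default_coefficient Selection coefficient of non-sticky founders
#'   (default 1).
#' @param rounds Number of selection rounds (default 7).
#' @param depth_per_round Reads sequenced per round (default 10,000).
#' @param per_base_error_rate Per-base substitution error probability in
#'   `[0, 1)` (default 1e-4).
#' @param mutation_spares_motif Optional `c(start, end)` interval in VR
#'   coordinates; sequencing errors are never placed inside it (emulating a
#'   conserved motif).
#' @param seed Integer seed driving all randomness (default 1).
#' @return An object of class `selex_sim_config`.
#' @export
selex_sim_config <- function(n_library = 1000L,
                             vr_lengths = 40L,
                             vr_length_probs = NULL,
                             design = library_design(),
                             sticky_s = c(9700, 1250, 500),
                             sticky_vr = NULL,
                             sticky_min_separation = 9L,
                             default_coefficient = 1,
                             rounds = 7L,
                             depth_per_round = 10000L,
                             per_base_error_rate = 1e-4,
                             mutation_spares_motif = NULL,
                             seed = 1L) {
  stopifnot(inherits(design, "library_design"))
  n_library <- as.integer(n_library)
  if (n_library < 1) abort("n_library must be >= 1")
  if (is.null(vr_length_probs)) {
    vr_length_probs <- rep(1 / length(vr_lengths), length(vr_lengths))
  }
  if (length(vr_length_probs) != length(vr_lengths) ||
      any(vr_length_probs < 0) || sum(vr_length_probs) <= 0) {
    abort("vr_length_probs must be non-negative weights matching vr_lengths")
  }
  if (any(sticky_s < 0) || default_coefficient < 0) {
    abort("selection coefficients must be >= 0")
  }
  if (length(sticky_s) > n_library) {
    abort("more sticky founders than library members")
  }
  if (!is.null(sticky_vr)) {
    if (length(sticky_vr) != length(sticky_s)) {
      abort("sticky_vr must match sticky_s in length")
    }
    sticky_vr <- check_dna(sticky_vr, "sticky_vr")
    if (length(sticky_vr) > 1) {
      pairs <- utils::combn(length(sticky_vr), 2)
      d <- sequence_distance(sticky_vr[pairs[1, ]], sticky_vr[pairs[2, ]])
      if (any(d < sticky_min_separation)) {
        abort("planted sticky VRs are too close for clustering to separate them")
      }
    }
  }
  if (per_base_error_rate < 0 || per_base_error_rate >= 1) {
    abort("per_base_error_rate must be in [0, 1)")
  }
  if (!is.null(mutation_spares_motif)) {
    m <- mutation_spares_motif
    if (length(m) != 2 || m[1] < 1 || m[1] > m[2] || m[2] > min(vr_lengths)) {
      abort("mutation_spares_motif must be c(start, end) within the VR")
    }
  }
  structure(
    list(
      n_library = n_library,
      vr_lengths = as.integer(vr_lengths),
      vr_length_probs = vr_length_probs / sum(vr_length_probs),
      design = design,
      sticky_s = sticky_s,
      sticky_vr = sticky_vr,
      sticky_min_separation = as.integer(sticky_min_separation),
      default_coefficient = default_coefficient,
      rounds = as.integer(rounds),
      depth_per_round = as.integer(depth_per_round),
      per_base_error_rate = per_base_error_rate,
      mutation_spares_motif = mutation_spares_motif,
      seed = as.integer(seed)
    ),
    class = "selex_sim_config"
  )
}

random_vrs <- function(n, lengths, probs) {
  len <- lengths[sample.int(length(lengths), n, replace = TRUE, prob = probs)]
  vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# library generation using the current RNG state
generate_library_impl <- function(config) {
  space <- sum(4^config$vr_lengths[config$vr_length_probs > 0])
  if (config$n_library > space) {
    abort("n_library exceeds the number of distinct variable regions")
  }
  vrs <- character(0)
  tries <- 0
  while (length(vrs) < config$n_library) {
    tries <- tries + 1
    if (tries > 100) abort("could not generate enough distinct variable regions")
    need <- config$n_library - length(vrs)
    vrs <- unique(c(vrs, random_vrs(need, config$vr_lengths,
                                    config$vr_length_probs)))
  }
  k <- length(config$sticky_s)
  if (!is.null(config$sticky_vr)) {
    vrs <- unique(c(config$sticky_vr, setdiff(vrs, config$sticky_vr)))
    while (length(vrs) < config$n_library) {
      vrs <- unique(c(vrs, random_vrs(config$n_library - length(vrs),
                                      config$vr_lengths, config$vr_length_probs)))
    }
    vrs <- vrs[seq_len(config$n_library)]
  } else if (k > 1) {
    # keep auto-planted sticky founders well separated so truth is recoverable
    repeat {
      d <- seq_dist_matrix(vrs[seq_len(k)])
      d[upper.tri(d, diag = TRUE)] <- NA
      bad <- which(d < config$sticky_min_separation, arr.ind = TRUE)
      if (nrow(bad) == 0) break
      vrs[bad[1, 1]] <- random_vrs(1, config$vr_lengths, config$vr_length_probs)
      vrs <- unique(vrs)
      while (length(vrs) < config$n_library) {
        vrs <- unique(c(vrs, random_vrs(config$n_library - length(vrs),
                                        config$vr_lengths, config$vr_length_probs)))
      }
    }
  }
  s <- rep(config$default_coefficient, config$n_library)
  if (k > 0) s[seq_len(k)] <- config$sticky_s
  tibble(
    founder_id = sprintf("f%04d", seq_len(config$n_library)),
    vr = vrs,
    s = s,
    fraction = 1 / config$n_library,
    sticky = seq_len(config$n_library) <= k
  )
}

#' Generate a founder library with uniform starting fractions
#'
#' Draws `n_library` distinct random variable regions with equimolar base
#' composition, assigns the configured selection coefficients (the first
#' founders take the sticky role unless `sticky_vr` plants specific
#' sequences), and gives every founder the same initial fraction.
#' Reproducible: the same config (including seed) yields the same library.
#'
#' @param config A [selex_sim_config()].
#' @return A tibble: `founder_id`, `vr`, `s` (selection coefficient),
#'   `fraction`, `sticky`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "selex_sim_config"))
  withr_seed(config$seed)
  generate_library_impl(config)
}

# set.seed without leaking the caller's RNG expectations; simulation
# functions document that they reset the RNG from the config seed
withr_seed <- function(seed) {
  set.seed(seed)
}

#' Deterministic one-round selection update
#'
#' Multiplicative selection: the next expected fraction of founder `i` is
#' `s_i * f_i / sum_j(s_j * f_j)`.  Equal coefficients leave the fractions
#' unchanged; a zero coefficient removes a founder immediately.
#'
#' @param fractions Numeric vector of current fractions (summing to 1).
#' @param coefficients Non-negative selection coefficients, same length.
#' @return Updated fractions summing to 1.
#' @examples
#' advance_round(c(0.01, 0.99), c(10, 1))
#' @export
advance_round <- function(fractions, coefficients) {
  stopifnot(length(fractions) == length(coefficients))
  if (any(fractions < 0) || any(coefficients < 0)) {
    abort("fractions and coefficients must be >= 0")
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must sum to 1")
  }
  num <- coefficients * fractions
  tot <- sum(num)
  if (tot <= 0) abort("selection drove every founder to zero")
  num / tot
}

#' Sample a sequenced round from founder fractions
#'
#' Draws `depth_per_round` reads multinomially from the founder fractions,
#' assembles each read as left constant + VR + right constant, and applies
#' per-base substitution errors (uniform over the three alternative bases).
#' If the config spares a motif span, no error is ever placed inside that
#' span of the variable region.
#'
#' @param founders A tibble with columns `vr` and `fraction` (e.g. from
#'   [generate_library()], possibly with updated fractions).
#' @param config A [selex_sim_config()].
#' @param round_label Label for the round (default `"R1"`).
#' @param seed Optional seed; by default the current RNG state is used so
#'   that [run_selection()] controls reproducibility globally.
#' @return A tibble of reads: `id`, `sequence`, `round`; the attribute
#'   `founder_counts` records the sampled count per founder.
#' @export
sample_reads <- function(founders, config, round_label = "R1", seed = NULL) {
  stopifnot(inherits(config, "selex_sim_config"),
            all(c("vr", "fraction") %in% names(founders)))
  if (!is.null(seed)) withr_seed(seed)
  depth <- config$depth_per_round
  counts <- as.integer(rmultinom(1, depth, founders$fraction))
  idx <- rep(seq_len(nrow(founders)), counts)
  idx <- sample(idx) # shuffle read order
  left <- config$design$left_constant
  right <- config$design$right_constant
  seqs <- paste0(left, founders$vr[idx], right)

  rate <- config$per_base_error_rate
  if (rate > 0) {
    widths <- nchar(seqs)
    n_err <- rbinom(length(seqs), widths, rate)
    for (r in which(n_err > 0)) {
      allowed <- seq_len(widths[r])
      if (!is.null(config$mutation_spares_motif)) {
        span <- nchar(left) + config$mutation_spares_motif
        allowed <- allowed[allowed < span[1] | allowed > span[2]]
      }
      if (length(allowed) == 0) next
      pos <- sample(allowed, min(n_err[r], length(allowed)))
      chars <- strsplit(seqs[r], "")[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      }
      seqs[r] <- paste(chars, collapse = "")
    }
  }

  out <- tibble(
    id = sprintf("%s_read_%05d", round_label, seq_along(seqs)),
    sequence = seqs,
    round = round_label
  )
  fc <- founders
  fc$count <- counts
  attr(out, "founder_counts") <- fc
  out
}

#' Run a full synthetic selection
#'
#' Generates the founder library, then for each round applies the
#' deterministic selection update followed by finite-depth sequencing with
#' error ([advance_round()] then [sample_reads()]).  The truth table
#' records every founder's true (expected) fraction in every round, so
#' pipeline estimates can be checked against planted truth.
#'
#' @param config A [selex_sim_config()].
#' @return An object of class `selex_simulation`: a list with `reads`
#'   (tibble `id`, `sequence`, `round` across all rounds), `truth` (tibble
#'   `round`, `founder_id`, `vr`, `s`, `sticky`, `true_fraction`),
#'   `founders` (the starting library) and `config`.  `tidy()` returns the
#'   truth table; `glance()` a one-row summary.
#' @examples
#' cfg <- selex_sim_config(n_library = 20, depth_per_round = 200, rounds = 2,
#'                         sticky_s = 10, seed = 7)
#' sim <- run_selection(cfg)
#' glance(sim)
#' @export
run_selection <- function(config) {
  stopifnot(inherits(config, "selex_sim_config"))
  withr_seed(config$seed)
  founders <- generate_library_impl(config)
  f <- founders$fraction
  reads <- vector("list", config$rounds)
  truth <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    label <- paste0("R", r)
    f <- advance_round(f, founders$s)
    cur <- founders
    cur$fraction <- f
    reads[[r]] <- sample_reads(cur, config, round_label = label)
    truth[[r]] <- tibble(
      round = label,
      founder_id = founders$founder_id,
      vr = founders$vr,
      s = founders$s,
      sticky = founders$sticky,
      true_fraction = f
    )
  }
  all_reads <- bind_rows(reads)
  labels <- paste0("R", seq_len(config$rounds))
  all_reads$round <- factor(all_reads$round, levels = labels)
  truth <- bind_rows(truth)
  truth$round <- factor(truth$round, levels = labels)
  structure(
    list(reads = all_reads, truth = truth, founders = founders,
         config = config),
    class = "selex_simulation"
  )
}

#' @export
print.selex_simulation <- function(x, ...) {
  g <- glance(x)
  cat("<selex_simulation> ", g$rounds, " rounds x ", g$depth_per_round,
      " reads, ", g$n_library, " founders (", g$n_sticky, " sticky)\n",
      sep = "")
  invisible(x)
}

#' @rdname run_selection
#' @param x A `selex_simulation` object.
#' @param ... Unused.
#' @method tidy selex_simulation
#' @export
tidy.selex_simulation <- function(x, ...) {
  x$truth
}

#' @rdname run_selection
#' @method glance selex_simulation
#' @export
glance.selex_simulation <- function(x, ...) {
  tibble(
    rounds = x$config$rounds,
    depth_per_round = x$config$depth_per_round,
    n_library = x$config$n_library,
    n_sticky = length(x$config$sticky_s),
    per_base_error_rate = x$config$per_base_error_rate,
    seed = x$config$seed
  )
}

#' Write a simulated selection to per-round sequence files
#'
#' Writes one FASTA (or constant-quality FASTQ) file per round plus a
#' tab-separated truth table of true founder fractions.
#'
#' @param sim A `selex_simulation` object.
#' @param outdir Output directory (created if needed).
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return A character vector of the files written, invisibly.
#' @export
write_selection <- function(sim, outdir, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "selex_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (label in levels(sim$reads$round)) {
    rr <- sim$reads[sim$reads$round == label, ]
    path <- file.path(outdir, paste0(label, ".", format))
    df <- tibble(id = rr$id, sequence = rr$sequence)
    if (format == "fastq") df$quality <- strrep("I", nchar(df$sequence))
    write_sequences(df, path, format = format)
    files <- c(files, path)
  }
  tpath <- file.path(outdir, "truth.tsv")
  write.table(sim$truth, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, tpath))
}
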