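test_that("edit distance matches the DP oracle and metric axioms", {
  expect_identical(levenshtein("GATTACA", "GATTACA"), 0L)
  # the two printed spellings of the first conserved motif differ by one
  # deletion once DNA-normalized
  expect_identical(levenshtein("ACGCGUUUAC", "CGCGUUUAC"), 1L)
  expect_identical(levenshtein("AAAA", "TTTT"), 4L)
  expect_identical(levenshtein("AAAA", "TTTT"), dp_levenshtein("AAAA", "TTTT"))

  set.seed(11)
  a <- rand_dna(40, sample(8:14, 40, replace = TRUE))
  b <- rand_dna(40, sample(8:14, 40, replace = TRUE))
  cc <- rand_dna(40, sample(8:14, 40, replace = TRUE))
  d_ab <- levenshtein(a, b)
  expect_identical(d_ab, mapply(dp_levenshtein, a, b, USE.NAMES = FALSE))
  expect_identical(d_ab, levenshtein(b, a))                 # symmetry
  expect_true(all(levenshtein(a, cc) <= d_ab + levenshtein(b, cc)))  # triangle
})

test_that("candidate selection applies the frequency threshold inclusively", {
  libs <- list(
    round_library_from_counts(stats::setNames(c(1L, 99999L), c("AAAT", "CCCC")),
                              round_index = 1),
    round_library_from_counts(stats::setNames(c(2000L, 98000L), c("GGGG", "CCCC")),
                              round_index = 2))
  cands <- select_candidates(libs, threshold = 1e-5)
  # 1 read in a 100000-read round is exactly 0.001% -> retained
  expect_true("AAAT" %in% cands$sequence)
  expect_true(all(c("CCCC", "GGGG") %in% cands$sequence))
  # below threshold everywhere -> excluded
  libs2 <- c(libs, list(round_library_from_counts(
    stats::setNames(c(9L, 999991L), c("TTTT", "CCCC")), round_index = 3)))
  cands2 <- select_candidates(libs2, threshold = 1e-5)
  expect_false("TTTT" %in% cands2$sequence)
  # total_count sums across rounds
  expect_identical(cands$total_count[cands$sequence == "CCCC"], 197999L)
  expect_error(select_candidates(list(round_library_from_counts(integer(0)))),
               "empty")
})

test_that("greedy clustering groups by representative distance", {
  A <- strrep("ACGTACG", 5)                       # 35-mer
  B <- A; substr(B, 3, 5) <- "TTT"                # 3 edits from A
  C <- rand_dna(1, 35)
  stopifnot(dp_levenshtein(A, C) > 7, dp_levenshtein(B, C) > 7)
  cands <- data.frame(sequence = c(A, B, C), total_count = c(100L, 50L, 80L))
  fams <- cluster_families(cands, max_dist = 7)
  expect_identical(nrow(fams$families), 2L)
  expect_identical(fams$families$representative[1], A)      # F0: count 150
  expect_setequal(fams$members$sequence[fams$members$family_id == "F0"],
                  c(A, B))
  expect_identical(fams$members$family_id[fams$members$sequence == C], "F1")

  single <- cluster_families(data.frame(sequence = A, total_count = 5L))
  expect_identical(nrow(single$families), 1L)
  expect_identical(single$families$n_members, 1L)

  # equal counts, distance 1: merged, representative is the smaller string
  x <- strrep("A", 35)
  y <- paste0(strrep("A", 34), "C")
  tie <- cluster_families(data.frame(sequence = c(y, x),
                                     total_count = c(10L, 10L)))
  expect_identical(nrow(tie$families), 1L)
  expect_identical(tie$families$representative, x)
})

test_that("clustering partitions candidates within the radius bound", {
  set.seed(23)
  seeds <- rand_dna(8, 35)
  variants <- unlist(lapply(seeds, function(s) {
    vapply(1:6, function(i) {
      v <- s
      pos <- sample(35, sample(1:3, 1))
      for (p in pos) substr(v, p, p) <- sample(c("A","C","G","T"), 1)
      v
    }, "")
  }))
  seqs <- unique(c(seeds, variants, rand_dna(40, 35)))
  cands <- data.frame(sequence = seqs,
                      total_count = sample(1:500, length(seqs)))
  fams <- cluster_families(cands, max_dist = 7)

  # partition: every candidate in exactly one family
  expect_identical(sort(fams$members$sequence), sort(seqs))
  expect_identical(sum(fams$families$n_members), length(seqs))

  # radius bound: member within max_dist of its representative
  rep_of <- fams$families$representative[
    match(fams$members$family_id, fams$families$family_id)]
  expect_true(all(levenshtein(fams$members$sequence, rep_of) <= 7))

  # representatives of different families are mutually separated
  reps <- fams$families$representative
  d <- levenshtein_matrix(reps)
  expect_true(all(d[upper.tri(d)] > 7))

  # determinism against the independent oracle
  oracle <- naive_greedy_cluster(cands$sequence, cands$total_count, 7)
  ours <- fams$families$representative[
    match(fams$members$family_id, fams$families$family_id)]
  expect_identical(ours[match(oracle$sequence, fams$members$sequence)],
                   oracle$rep)
})

test_that("family trajectories sum member frequencies per round", {
  A <- strrep("A", 35); A2 <- paste0(strrep("A", 34), "G")
  G <- strrep("G", 35)
  libs <- list(
    round_library_from_counts(stats::setNames(c(10L, 5L, 985L), c(A, A2, G)),
                              round_index = 1),
    round_library_from_counts(stats::setNames(c(400L, 600L), c(A, G)),
                              round_index = 2))
  fams <- cluster_families(data.frame(sequence = c(A, A2, G),
                                      total_count = c(410L, 5L, 1585L)))
  traj <- family_trajectories(fams, libs)
  gid <- fams$members$family_id[fams$members$sequence == G]
  aid <- fams$members$family_id[fams$members$sequence == A]
  expect_equal(traj[aid, 1], 0.015)        # (10 + 5) / 1000
  expect_equal(traj[aid, 2], 0.4)          # member absent contributes 0
  expect_equal(unname(colSums(traj)), c(1, 1))  # all sequences covered

  expect_identical(unname(diversity_per_round(traj)), c(2, 2))
  traj0 <- traj; traj0[gid, 1] <- 0
  expect_identical(unname(diversity_per_round(traj0)), c(1, 2))
  expect_identical(unname(diversity_per_round(traj0 * 0)), c(0, 0))
  expect_identical(unname(diversity_per_round(traj, presence_threshold = 0.1)),
                   c(1, 2))
})

test_that("family FASTA export writes one record per member", {
  fams <- cluster_families(data.frame(
    sequence = c(strrep("A", 35), paste0(strrep("A", 33), "GG"),
                 strrep("C", 35)),
    total_count = c(9L, 3L, 5L)))
  dir <- tempfile()
  write_family_fasta(fams, dir)
  f0 <- Biostrings::readDNAStringSet(file.path(dir, "F0.fasta"))
  expect_identical(length(f0), 2L)
  expect_true(file.exists(file.path(dir, "F1.fasta")))
})
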