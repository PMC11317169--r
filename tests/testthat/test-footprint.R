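toy_panel <- function() {
  aptamer_panel(c(a = "ACGTACGTACGTACG",
                  b = "TTTTGGGGCCCCAAA",
                  g = "GACTGACTGACTGAC"))
}

test_that("panel validation enforces separation and unique names", {
  expect_error(aptamer_panel(c(x = "ACGTACGTACGTACG",
                               y = "ACGTACGAACGTACG",
                               z = "TTTTGGGGCCCCAAA")),
               "within the assignment radius")
  # the same close pair is legal at a smaller assignment radius
  expect_s3_class(aptamer_panel(c(x = "ACGTACGTACGTACG",
                                  y = "ACGTAGGAACGTACG",
                                  z = "TTTTGGGGCCCCAAA"), max_dist = 1),
                  "aptamer_panel")
  expect_error(aptamer_panel(c("ACGTACGTACGTACG", "TTTTGGGGCCCCAAA")),
               "names")
  pan <- default_panel()
  expect_identical(pan$n, 15L)
  expect_identical(pan$members$name[pan$n], "Scr")
  d <- levenshtein_matrix(pan$members$sequence)
  expect_true(all(d[upper.tri(d)] > 3))
})

test_that("panel FASTA round-trips", {
  pan <- default_panel()
  path <- tempfile(fileext = ".fasta")
  x <- Biostrings::DNAStringSet(pan$members$sequence)
  names(x) <- pan$members$name
  Biostrings::writeXStringSet(x, path)
  pan2 <- read_panel_fasta(path)
  expect_identical(pan2$members, pan$members)
})

test_that("reads assign to the unique nearest panel member", {
  pan <- toy_panel()
  refs <- pan$members$sequence
  mut1 <- refs[2]; substr(mut1, 4, 4) <- "A"         # 1 edit from b
  far <- strrep("CA", 8)                             # far from everything
  stopifnot(min(adist(far, refs)) > 3)
  ac <- assign_reads(c(refs[1], refs[1], mut1, far), pan,
                     condition = "x", replicate = 2)
  expect_identical(unname(ac$counts), c(2L, 1L, 0L))
  expect_identical(ac$n_unassigned, 1L)
  expect_identical(ac$n_total, 4L)
  expect_identical(ac$condition, "x")

  # equidistant read: distance 2 to two members -> unassigned
  pan2 <- aptamer_panel(c(p = "AAAAAAAATTTTTTTT", q = "AAAAAAAAGGGGGGGG"),
                        max_dist = 3)
  tie <- "AAAAAAAATTGGTTGG"
  d <- as.integer(adist(tie, pan2$members$sequence))
  stopifnot(length(unique(d)) == 1)
  act <- assign_reads(tie, pan2, max_dist = max(d))
  expect_identical(sum(act$counts), 0L)
  expect_identical(act$n_unassigned, 1L)
})

test_that("the RN cascade reproduces the printed-formula arithmetic", {
  casc <- rn_cascade(fx = c(0.25, 0.60, 0.15), f0 = c(0.5, 0.3, 0.2))
  expect_equal(casc$r_raw, c(0.5, 2.0, 0.75))
  expect_equal(casc$r_norm, c(2, 8, 3) / 13, tolerance = 1e-12)
  expect_equal(casc$rn, c(-7, 11, -4) / 13, tolerance = 1e-12)
  expect_equal(sum(casc$rn), 0, tolerance = 1e-12)

  expect_equal(enrichment_raw(c(0.2, 0.8), c(0.2, 0.8)), c(1, 1))
  expect_equal(enrichment_raw(c(0, 1), c(0.5, 0.5)), c(0, 2))
  expect_error(enrichment_raw(c(0.5, 0.5), c(1, 0)), "zero")

  expect_equal(normalize_enrichment(c(2, 2, 2, 2)), rep(0.25, 4))
  expect_equal(normalize_enrichment(c(0, 5, 0)), c(0, 1, 0))
  expect_error(normalize_enrichment(c(0, 0)), "zero")

  # uniform composition: no member moved, all RN = 0
  expect_equal(enrichment_rn(rep(1 / 15, 15)), rep(0, 15))
  # single surviving member reaches the n-1 / -1 bounds
  expect_equal(enrichment_rn(c(1, 0, 0, 0)), c(3, -1, -1, -1))
})

test_that("RN sums to zero and stays in bounds for random compositions", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    f0 <- rgamma(n, 1); f0 <- f0 / sum(f0)
    fx <- rgamma(n, 1); fx <- fx / sum(fx)
    rn <- rn_cascade(fx, f0)$rn
    expect_lt(abs(sum(rn)), 1e-9)
    expect_true(all(rn >= -1 - 1e-12 & rn <= n - 1 + 1e-12))
  }
})

test_that("footprint tables pair conditions with the starting mixture", {
  pan <- toy_panel()
  mk <- function(cnt, cond, rep) assay_counts(
    stats::setNames(cnt, pan$members$name), pan, cond, rep)
  assays <- list(mk(c(500, 300, 200), "0", 1),
                 mk(c(250, 600, 150), "x", 1),
                 mk(c(500, 300, 200), "x", 2))
  fp <- footprint_table(assays)
  x1 <- fp$long[fp$long$condition == "x" & fp$long$replicate == 1, ]
  expect_equal(x1$rn, c(-7, 11, -4) / 13, tolerance = 1e-12)
  x2 <- fp$long[fp$long$condition == "x" & fp$long$replicate == 2, ]
  expect_equal(x2$rn, rep(0, 3))            # unchanged composition

  # per-assay invariants from the table itself
  by_assay <- split(fp$long, interaction(fp$long$condition,
                                         fp$long$replicate, drop = TRUE))
  for (a in by_assay) {
    expect_equal(sum(a$r_norm), 1, tolerance = 1e-12)
    expect_lt(abs(sum(a$rn)), 1e-9)
    expect_true(all(a$rn >= -1))
  }

  expect_error(footprint_table(assays[2:3]), "condition-0")
  bad <- assays
  bad[[2]] <- assay_counts(c(a = 1L, b = 1L), aptamer_panel(
    c(a = "ACGTACGTACGTACG", b = "TTTTGGGGCCCCAAA")), "x", 1)
  expect_error(footprint_table(bad), "inconsistent")
})

test_that("median footprint follows the sample-median convention", {
  pan <- toy_panel()
  mk <- function(cnt, cond, rep) assay_counts(
    stats::setNames(cnt, pan$members$name), pan, cond, rep)
  base <- c(1000, 1000, 1000)
  assays <- list(mk(base, "0", 1), mk(base, "0", 2), mk(base, "0", 3),
                 mk(c(1100, 950, 950), "x", 1),
                 mk(c(1200, 900, 900), "x", 2),
                 mk(c(1900, 550, 550), "x", 3))
  fp <- footprint_table(assays)
  med <- median_footprint(fp)
  rep_rn <- sapply(1:3, function(r)
    fp$long$rn[fp$long$replicate == r & fp$long$member == "a"])
  expect_equal(med["a", "x"], sort(rep_rn)[2])     # odd count: middle value
  fp2 <- footprint_table(assays[c(1, 2, 4, 5)])
  med2 <- median_footprint(fp2)
  two <- fp2$long$rn[fp2$long$member == "a"]
  expect_equal(med2["a", "x"], mean(two))          # even count: middle mean
  # single replicate: the footprint is that replicate
  fp1 <- footprint_table(assays[c(1, 4)])
  expect_equal(median_footprint(fp1)["a", "x"],
               fp1$long$rn[fp1$long$member == "a"])
})

test_that("pseudocount rescues complete depletion when requested", {
  pan <- toy_panel()
  mk <- function(cnt, cond, rep) assay_counts(
    stats::setNames(cnt, pan$members$name), pan, cond, rep)
  assays <- list(mk(c(400, 300, 300), "0", 1), mk(c(0, 700, 300), "x", 1))
  fp <- footprint_table(assays)
  expect_equal(fp$long$rn[fp$long$member == "a"], -1)   # depletion -> -1
  fp_pc <- footprint_table(assays, pseudocount = 0.5)
  rn_a <- fp_pc$long$rn[fp_pc$long$member == "a"]
  expect_gt(rn_a, -1)
  expect_lt(rn_a, -0.9)
  expect_lt(abs(sum(fp_pc$long$rn)), 1e-9)
})

test_that("footprint TSV export writes the long table and median matrix", {
  pan <- toy_panel()
  mk <- function(cnt, cond, rep) assay_counts(
    stats::setNames(cnt, pan$members$name), pan, cond, rep)
  fp <- footprint_table(list(mk(c(500, 300, 200), "0", 1),
                             mk(c(250, 600, 150), "x", 1)))
  dir <- tempfile()
  write_footprint_tsv(fp, dir)
  long <- read.delim(file.path(dir, "rn_long.tsv"))
  expect_identical(nrow(long), 3L)
  med <- read.delim(file.path(dir, "footprint_median.tsv"))
  expect_identical(med$member, pan$members$name)
})
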