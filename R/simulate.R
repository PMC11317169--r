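#' Define a synthetic SELEX scenario
#'
#' Parameters of the generative model used to emulate a selection series:
#' a random-region library in which a few founder sequences ("planted
#' families") carry a multiplicative per-round fitness advantage over a
#' neutral background. Each round applies one selection step (replicator
#' update `f' = w f / sum(w f)`), multinomial resampling to the sequencing
#' depth, per-base substitution mutations and optional per-read single-base
#' indels (which move inserts off the nominal length and exercise the
#' 33--37 retention window); emitted reads additionally carry iid
#' substitution sequencing errors and the fixed primer-binding sites.
#'
#' Defaults mirror the study conditions at desk scale: 15 rounds,
#' 1e5 reads per round (scaled down from millions), 10 planted founder
#' families at initial frequency 1e-3 each with fitness evenly spaced
#' 1.1--1.8 over a neutral background.
#'
#' @param n_rounds Number of selection rounds (default 15).
#' @param reads_per_round Sequencing depth per round (default 1e5).
#' @param founders Character vector of founder region sequences; generated
#'   as well-separated random `region_length`-mers when NULL.
#' @param n_families Number of founders to generate when `founders` is
#'   NULL (default 10).
#' @param fitness Per-founder multiplicative fitness (default evenly
#'   spaced 1.1 to 1.8).
#' @param initial_fractions Per-founder starting frequency (default 1e-3
#'   each); the remainder is neutral background.
#' @param background_fitness Fitness of background sequences (default 1).
#' @param region_length Founder/background region length (default 35).
#' @param mutation_rate Per-base substitution rate per round (default
#'   1e-3).
#' @param indel_rate Per-read probability of a single-base insertion or
#'   deletion per round (default 1e-3).
#' @param error_rate Per-base sequencing substitution rate (default 5e-4).
#' @param primer5,primer3 Fixed flanking sequences affixed to emitted
#'   reads.
#' @param selex_id Series label (default "S1").
#' @param seed RNG seed; the simulation is byte-deterministic given the
#'   scenario.
#' @return A `selex_scenario` list.
#' @export
selex_scenario <- function(n_rounds = 15L, reads_per_round = 1e5L,
                           founders = NULL, n_families = 10L,
                           fitness = NULL, initial_fractions = NULL,
                           background_fitness = 1,
                           region_length = 35L,
                           mutation_rate = 1e-3, indel_rate = 1e-3,
                           error_rate = 5e-4,
                           primer5 = default_primer5(),
                           primer3 = default_primer3(),
                           selex_id = "S1", seed = 1L) {
  if (is.null(founders)) {
    set.seed(seed)
    repeat {
      founders <- random_dna(n_families, region_length)
      d <- adist(founders)
      if (n_families < 2L || min(d[upper.tri(d)]) > 14L) break
    }
  }
  k <- length(founders)
  if (is.null(fitness))
    fitness <- if (k == 1L) 1.5 else seq(1.1, 1.8, length.out = k)
  if (is.null(initial_fractions)) initial_fractions <- rep(1e-3, k)
  stopifnot(length(fitness) == k, length(initial_fractions) == k,
            all(fitness >= 0), all(initial_fractions > 0),
            sum(initial_fractions) <= 1,
            mutation_rate >= 0, indel_rate >= 0, error_rate >= 0)
  if (all(fitness == 0)) stop("degenerate scenario: all fitness values are zero")
  structure(list(n_rounds = as.integer(n_rounds),
                 reads_per_round = as.integer(reads_per_round),
                 founders = normalize_seq(founders),
                 fitness = fitness,
                 initial_fractions = initial_fractions,
                 background_fraction = 1 - sum(initial_fractions),
                 background_fitness = background_fitness,
                 region_length = as.integer(region_length),
                 mutation_rate = mutation_rate, indel_rate = indel_rate,
                 error_rate = error_rate,
                 primer5 = normalize_seq(primer5),
                 primer3 = normalize_seq(primer3),
                 selex_id = selex_id, seed = as.integer(seed)),
            class = "selex_scenario")
}

#' Deterministic expected family trajectories of a scenario
#'
#' The infinite-reads limit of the selection recurrence: per round,
#' `f' = w f / (sum(w f) + w_bg * f_bg)`, ignoring drift and mutation
#' (mutants remain inside their family, so family mass is unaffected).
#'
#' @param scenario A [selex_scenario()].
#' @return Matrix families x rounds of expected frequencies (columns
#'   `r1..r<n_rounds>`); attribute `"background"` holds the expected
#'   background mass per round.
#' @export
expected_family_fractions <- function(scenario) {
  k <- length(scenario$founders)
  f <- scenario$initial_fractions
  b <- scenario$background_fraction
  out <- matrix(NA_real_, nrow = k, ncol = scenario$n_rounds,
                dimnames = list(paste0("founder", seq_len(k)),
                                paste0("r", seq_len(scenario$n_rounds))))
  bg <- numeric(scenario$n_rounds)
  for (t in seq_len(scenario$n_rounds)) {
    z <- sum(scenario$fitness * f) + scenario$background_fitness * b
    f <- scenario$fitness * f / z
    b <- scenario$background_fitness * b / z
    out[, t] <- f
    bg[t] <- b
  }
  attr(out, "background") <- bg
  out
}

# Apply single-base indels to reads: each read independently suffers an
# insertion or deletion (equiprobable) at a uniform position with
# probability `rate`.
apply_indels <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  hit <- which(runif(length(seqs)) < rate)
  for (i in hit) {
    L <- nchar(seqs[i])
    if (runif(1L) < 0.5 && L > 1L) {            # deletion
      p <- sample.int(L, 1L)
      seqs[i] <- paste0(substr(seqs[i], 1L, p - 1L),
                        substr(seqs[i], p + 1L, L))
    } else {                                    # insertion
      p <- sample.int(L + 1L, 1L)
      seqs[i] <- paste0(substr(seqs[i], 1L, p - 1L),
                        sample(c("A", "C", "G", "T"), 1L),
                        substr(seqs[i], p, L))
    }
  }
  seqs
}

write_fastq <- function(seqs, ids, path) {
  qual <- strrep("?", nchar(seqs))              # constant Q30 placeholder
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

#' Simulate a SELEX round series as FASTQ files with planted truth
#'
#' Runs the generative model of [selex_scenario()] and writes one FASTQ
#' per round. Identical scenarios (including seed) produce byte-identical
#' output.
#'
#' @param scenario A [selex_scenario()].
#' @param out_dir Output directory for FASTQ files (created if needed).
#' @return List with `fastq` (paths, one per round), `truth` (list:
#'   `expected` and `realized` family x round frequency matrices,
#'   `founders` data.frame with `family`, `sequence`, `fitness`,
#'   `initial_fraction`), and `scenario`.
#' @export
simulate_selex <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "selex_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(scenario$seed)
  k <- length(scenario$founders)
  reads <- scenario$reads_per_round

  # current pool: concrete sequences with family labels (0 = background),
  # plus an anonymous background mass that materializes on first sampling
  pool_seq <- scenario$founders
  pool_fam <- seq_len(k)
  pool_frac <- scenario$initial_fractions
  anon_mass <- scenario$background_fraction

  realized <- matrix(0, nrow = k, ncol = scenario$n_rounds,
                     dimnames = list(paste0("founder", seq_len(k)),
                                     paste0("r", seq_len(scenario$n_rounds))))
  paths <- character(scenario$n_rounds)

  for (t in seq_len(scenario$n_rounds)) {
    w <- ifelse(pool_fam == 0L, scenario$background_fitness,
                scenario$fitness[pmax(pool_fam, 1L)])
    sel <- c(pool_frac * w, anon_mass * scenario$background_fitness)
    sel <- sel / sum(sel)
    cnt <- as.integer(rmultinom(1L, reads, sel))
    n_anon <- cnt[length(cnt)]
    cnt <- cnt[-length(cnt)]

    round_seqs <- c(rep(pool_seq, cnt),
                    random_dna(n_anon, scenario$region_length))
    round_fams <- c(rep(pool_fam, cnt), rep(0L, n_anon))

    # amplification mutations enter the pool (and the emitted reads)
    round_seqs <- mutate_bases(round_seqs, scenario$mutation_rate)
    round_seqs <- apply_indels(round_seqs, scenario$indel_rate)

    fam_cnt <- tabulate(round_fams, nbins = k)
    realized[, t] <- fam_cnt / reads

    # sequencing errors only on the emitted copy
    emitted <- mutate_bases(round_seqs, scenario$error_rate)
    full <- paste0(scenario$primer5, emitted, scenario$primer3)
    ids <- paste0(scenario$selex_id, "_r", t, "_", seq_along(full))
    paths[t] <- file.path(out_dir,
                          paste0(scenario$selex_id, "_round",
                                 formatC(t, width = 2, flag = "0"),
                                 ".fastq"))
    write_fastq(full, ids, paths[t])

    # aggregate the post-mutation sample into the next-round pool
    key <- paste0(round_fams, ":", round_seqs)
    tab <- table(key)
    ord <- order(names(tab))                    # deterministic pool order
    keys <- names(tab)[ord]
    sep <- regexpr(":", keys, fixed = TRUE)
    pool_fam <- as.integer(substr(keys, 1L, sep - 1L))
    pool_seq <- substr(keys, sep + 1L, nchar(keys))
    pool_frac <- as.numeric(tab)[ord] / reads
    anon_mass <- 0
  }

  truth <- list(expected = expected_family_fractions(scenario),
                realized = realized,
                founders = data.frame(family = paste0("founder", seq_len(k)),
                                      sequence = scenario$founders,
                                      fitness = scenario$fitness,
                                      initial_fraction = scenario$initial_fractions,
                                      stringsAsFactors = FALSE))
  list(fastq = paths, truth = truth, scenario = scenario)
}

#' Define a synthetic assay scenario
#'
#' Ground-truth model of a mixture-binding assay: the starting mixture has
#' composition `f0` over the panel (equimolar by default); the bound
#' fraction recovered under condition `x` has composition `q_x`. Observed
#' counts are multinomial draws at the sequencing depth, per replicate.
#' The implied true normalized enrichment ratio is
#' `RN_a = n ((q_a/f0_a) / sum_b (q_b/f0_b)) - 1`.
#'
#' @param q Named list: condition label -> probability vector over the
#'   panel (bound-fraction composition). Zeros allowed (complete
#'   depletion, RN -> -1).
#' @param panel An [aptamer_panel()] (default [default_panel()]).
#' @param f0 Starting-mixture composition (default equimolar); must be
#'   strictly positive.
#' @param reads_per_assay Sequencing depth per assay (default 1e5).
#' @param replicates Technical replicates per condition (default 3).
#' @param error_rate Per-base sequencing substitution rate for FASTQ
#'   output (default 1e-3).
#' @param seed RNG seed.
#' @return An `assay_scenario` list with a `truth_rn` members x conditions
#'   matrix.
#' @export
assay_scenario <- function(q, panel = default_panel(), f0 = NULL,
                           reads_per_assay = 1e5L, replicates = 3L,
                           error_rate = 1e-3, seed = 1L) {
  stopifnot(inherits(panel, "aptamer_panel"), is.list(q), length(q) >= 1L,
            !is.null(names(q)))
  if (is.null(f0)) f0 <- rep(1 / panel$n, panel$n)
  stopifnot(length(f0) == panel$n, all(f0 > 0),
            abs(sum(f0) - 1) < 1e-8)
  q <- lapply(q, function(v) {
    stopifnot(length(v) == panel$n, all(v >= 0), abs(sum(v) - 1) < 1e-8)
    v
  })
  truth <- vapply(q, function(v) {
    r <- v / f0
    panel$n * (r / sum(r)) - 1
  }, numeric(panel$n))
  rownames(truth) <- panel$members$name
  structure(list(panel = panel, f0 = f0, q = q,
                 reads_per_assay = as.integer(reads_per_assay),
                 replicates = as.integer(replicates),
                 error_rate = error_rate, seed = as.integer(seed),
                 truth_rn = truth),
            class = "assay_scenario")
}

#' Simulate assay read-outs with planted truth
#'
#' Draws multinomial counts for each (condition, replicate) — including
#' the condition-0 starting mixture — at the scenario depth. With
#' `output = "counts"` returns `assay_counts` objects directly; with
#' `output = "fastq"` writes one FASTQ per assay (reads are panel
#' reference sequences carrying iid substitution sequencing errors, in
#' shuffled order).
#'
#' @param scenario An [assay_scenario()].
#' @param output `"counts"` or `"fastq"`.
#' @param out_dir Output directory (required for `"fastq"`).
#' @return List with `assays` (list of `assay_counts`, counts mode) or
#'   `manifest` (data.frame `file`, `condition`, `replicate`, fastq mode),
#'   plus `truth_rn` and `scenario`.
#' @export
simulate_assay <- function(scenario, output = c("counts", "fastq"),
                           out_dir = NULL) {
  stopifnot(inherits(scenario, "assay_scenario"))
  output <- match.arg(output)
  if (output == "fastq") {
    if (is.null(out_dir)) stop("out_dir required for fastq output")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  set.seed(scenario$seed)
  panel <- scenario$panel
  comps <- c(list("0" = scenario$f0), scenario$q)
  assays <- list()
  manifest <- NULL
  for (cd in names(comps)) {
    for (r in seq_len(scenario$replicates)) {
      cnt <- as.integer(rmultinom(1L, scenario$reads_per_assay, comps[[cd]]))
      names(cnt) <- panel$members$name
      if (output == "counts") {
        assays[[length(assays) + 1L]] <-
          assay_counts(cnt, panel, condition = cd, replicate = r)
      } else {
        seqs <- rep(panel$members$sequence, cnt)
        seqs <- mutate_bases(seqs, scenario$error_rate)
        seqs <- seqs[sample.int(length(seqs))]
        path <- file.path(out_dir, paste0("assay_", cd, "_rep", r, ".fastq"))
        write_fastq(seqs, paste0(cd, "_rep", r, "_", seq_along(seqs)), path)
        manifest <- rbind(manifest,
                          data.frame(file = path, condition = cd,
                                     replicate = r,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- list(truth_rn = scenario$truth_rn, scenario = scenario)
  if (output == "counts") out$assays <- assays else out$manifest <- manifest
  out
}

#' Run the footprint pipeline on a simulated-assay manifest
#'
#' Convenience wrapper: reads each FASTQ of a [simulate_assay()] manifest,
#' assigns reads to the panel, and builds the footprint table.
#'
#' @param manifest Data.frame with `file`, `condition`, `replicate`.
#' @param panel An [aptamer_panel()].
#' @param max_dist Assignment radius, default 3.
#' @param pseudocount Passed to [footprint_table()].
#' @return A `footprint_table`.
#' @export
footprint_from_manifest <- function(manifest, panel, max_dist = 3L,
                                    pseudocount = 0) {
  assays <- lapply(seq_len(nrow(manifest)), function(i) {
    assign_reads(read_fastq_sequences(manifest$file[i]), panel,
                 max_dist = max_dist,
                 condition = manifest$condition[i],
                 replicate = manifest$replicate[i])
  })
  footprint_table(assays, pseudocount = pseudocount)
}
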