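#' Define an aptamer panel
#'
#' An ordered set of named reference sequences: the aptamers mixed in an
#' assay plus the scramble control. Validation requires every pairwise
#' reference edit distance to exceed the read-assignment radius, so that
#' [assign_reads()] is unambiguous; panels containing close variants
#' (e.g. a two-mutation variant of another member) must use a smaller
#' `max_dist`.
#'
#' @param sequences Character vector of reference sequences, optionally
#'   named; or a named list.
#' @param names Member names (unique); defaults to `names(sequences)`.
#' @param max_dist Assignment radius the panel must support, default 3.
#' @return An `aptamer_panel`: list with `members` (data.frame `name`,
#'   `sequence`) and `n`.
#' @export
aptamer_panel <- function(sequences, names = NULL, max_dist = 3L) {
  sequences <- normalize_seq(unlist(sequences))
  nm <- if (is.null(names)) base::names(sequences) else names
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    stop("panel members must have unique non-empty names")
  if (anyDuplicated(sequences)) stop("panel reference sequences must be unique")
  d <- adist(sequences)
  off <- d[upper.tri(d)]
  if (length(off) && min(off) <= max_dist) {
    bad <- which(d <= max_dist & upper.tri(d), arr.ind = TRUE)[1L, ]
    stop("panel references '", nm[bad[1L]], "' and '", nm[bad[2L]],
         "' are within the assignment radius (distance ",
         d[bad[1L], bad[2L]], " <= max_dist ", max_dist,
         "); reduce max_dist or revise the panel")
  }
  structure(list(members = data.frame(name = nm,
                                      sequence = unname(sequences),
                                      stringsAsFactors = FALSE),
                 n = length(sequences)),
            class = "aptamer_panel")
}

#' @export
print.aptamer_panel <- function(x, ...) {
  cat("Aptamer panel with", x$n, "members:",
      paste(x$members$name, collapse = ", "), "\n")
  invisible(x)
}

#' Read a panel from a FASTA file
#'
#' @param path FASTA file; record names become member names.
#' @inheritParams aptamer_panel
#' @export
read_panel_fasta <- function(path, max_dist = 3L) {
  x <- Biostrings::readBStringSet(path)
  aptamer_panel(as.character(x), names = names(x), max_dist = max_dist)
}

# Built-in synthetic 15-member panel: 14 aptamer labels plus a scramble
# control, with sequences generated once from a fixed seed (minimum
# pairwise edit distance 16). These are NOT the experimental aptamer
# sequences; they are stand-ins for simulation and testing.
PANEL_NAMES <- c("F0", "F0AC", "F1", "F2", "F3", "F4", "F5", "F15", "F20",
                 "F30", "F62", "F73", "F124", "F164", "Scr")
PANEL_SEQS <- c(
  "TAGAAGAAAACAAACGGCGTGCTGTGGCAAGAGAC",
  "CTCGCCCCAAGGCCCGGCTCTCGCATCAAGGGTTG",
  "CGACAACGGTTTTTGCGGTGCTAAGACATTTGAAA",
  "CGTACCTTCTTTCTTTGTTCTTTAATCCCCGGCTC",
  "TATGCCGGACACGCCCGTGCCACTGCCGGACGCAC",
  "TGCGAACAAACGGGTTACAATCGAAATGCGTAAAA",
  "TACACCCCAAATGCTTTACGATGGCATCACGATAG",
  "GCAACCAACCAACTACACTGAAATAATTTTCAGAT",
  "TCATTAGCGTGGCAGTATCCACTTATCCCTTTAAT",
  "TTGATATTAGGATCCTGCTTTTGTTCAGTGGGTGA",
  "TCCTTTAGTTAGTAAGAGTTTGTTGCGAACGCGGC",
  "GCCGTTAGCTACACATAAGTCTTCACAGGCGGAGG",
  "TCTATTGTTTGGCCACGCCTAAGCGATTAACTATC",
  "TTTCCTAGCCAACCTACCGGCCAAAGTGAAGTCGT",
  "TAAAGCATATACCGCAGCTGTTACCGACAACGGCC")

#' Built-in synthetic 15-member panel
#'
#' A synthetic stand-in for the experimental assay panel: 14 aptamer
#' labels plus a scramble control, with well-separated random 35-mer
#' reference sequences (minimum pairwise edit distance 16) fixed at
#' package build time. Intended for simulation and testing; real analyses
#' should load their panel with [read_panel_fasta()].
#'
#' @inheritParams aptamer_panel
#' @export
default_panel <- function(max_dist = 3L) {
  aptamer_panel(PANEL_SEQS, names = PANEL_NAMES, max_dist = max_dist)
}

#' Assign assay reads to panel members by edit distance
#'
#' Each read is assigned to the panel member at minimal Levenshtein
#' distance, provided that minimum is unique and at most `max_dist`;
#' reads with ties or larger distance are left unassigned. Exact matches
#' are resolved by lookup; only inexact reads incur the dynamic-programming
#' distance computation (over unique reads).
#'
#' @param reads Character vector of read sequences (already trimmed to the
#'   aptamer region, or full-length matching the panel references).
#' @param panel An [aptamer_panel()].
#' @param max_dist Assignment radius, default 3.
#' @param condition,replicate Labels stored on the result.
#' @return An `assay_counts` object: list with `condition`, `replicate`,
#'   `counts` (named integer vector over panel members, panel order),
#'   `n_unassigned`, `n_total`.
#' @export
assign_reads <- function(reads, panel, max_dist = 3L,
                         condition = "0", replicate = 1L) {
  stopifnot(inherits(panel, "aptamer_panel"))
  reads <- normalize_seq(reads)
  refs <- panel$members$sequence
  u <- unique(reads)
  hit <- match(u, refs)                       # exact fast path
  inexact <- which(is.na(hit))
  if (length(inexact)) {
    d <- adist(u[inexact], refs)
    dmin <- apply(d, 1L, min)
    unique_min <- rowSums(d == dmin) == 1L
    ok <- dmin <= max_dist & unique_min
    if (any(ok))
      hit[inexact[ok]] <- apply(d[ok, , drop = FALSE], 1L, which.min)
  }
  read_hit <- hit[match(reads, u)]
  counts <- tabulate(read_hit, nbins = panel$n)
  names(counts) <- panel$members$name
  new_assay_counts(counts, condition, replicate,
                   n_unassigned = sum(is.na(read_hit)))
}

#' Construct assay counts directly from a count vector
#'
#' @param counts Named integer vector (names must be panel member names)
#'   or data.frame with columns `member` and `count`.
#' @param panel An [aptamer_panel()]; counts are reordered to panel order,
#'   absent members get 0.
#' @inheritParams assign_reads
#' @param n_unassigned Reads not attributable to any member.
#' @export
assay_counts <- function(counts, panel, condition = "0", replicate = 1L,
                         n_unassigned = 0L) {
  stopifnot(inherits(panel, "aptamer_panel"))
  if (is.data.frame(counts)) {
    v <- counts$count
    names(v) <- counts$member
    counts <- v
  }
  if (is.null(names(counts))) stop("counts must be named by panel member")
  extra <- setdiff(names(counts), panel$members$name)
  if (length(extra)) stop("counts name unknown panel members: ",
                          paste(extra, collapse = ", "))
  full <- stats::setNames(rep(0L, panel$n), panel$members$name)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("counts must be non-negative")
  new_assay_counts(full, condition, replicate, n_unassigned)
}

new_assay_counts <- function(counts, condition, replicate, n_unassigned) {
  structure(list(condition = as.character(condition),
                 replicate = as.integer(replicate),
                 counts = counts,
                 n_unassigned = as.integer(n_unassigned),
                 n_total = sum(counts) + as.integer(n_unassigned)),
            class = "assay_counts")
}

#' @export
print.assay_counts <- function(x, ...) {
  cat("Assay counts: condition", x$condition, "replicate", x$replicate,
      "-", sum(x$counts), "assigned,", x$n_unassigned, "unassigned\n")
  invisible(x)
}

## ---- the RN cascade ----

#' Raw, normalized, and RN enrichment ratios
#'
#' The three-step cascade that turns per-member frequencies in a binding
#' condition `x` and in the starting mixture (condition 0) into the
#' normalized enrichment ratio RN:
#'
#' \deqn{r_{a,x/0} = f_{a,C=x} / f_{a,C=0}}
#' \deqn{r_{a,x} = r_{a,x/0} / \sum_{a \in A} r_{a,x/0}}
#' \deqn{RN_a = (r_{a,x} - 1/n) / (1/n) = n \, r_{a,x} - 1}
#'
#' where `n` is the panel size. Since the `r_{a,x}` sum to 1, the RN sum
#' to 0 identically: an aptamer can only be enriched at the expense of
#' others. RN ranges from -1 (complete depletion) to n - 1 (the only
#' retained member).
#'
#' @param fx,f0 Frequency vectors over the panel for condition `x` and the
#'   starting mixture. `f0` must be strictly positive (the starting
#'   mixture represents every member).
#' @return `enrichment_raw()`: the vector `fx / f0`.
#' @export
enrichment_raw <- function(fx, f0) {
  stopifnot(length(fx) == length(f0))
  if (any(f0 <= 0))
    stop("starting mixture frequency is zero for member(s): ",
         paste(if (!is.null(names(f0))) names(f0)[f0 <= 0]
               else which(f0 <= 0), collapse = ", "))
  fx / f0
}

#' @rdname enrichment_raw
#' @param r_raw Vector of raw ratios.
#' @return `normalize_enrichment()`: `r_raw / sum(r_raw)`, summing to 1.
#' @export
normalize_enrichment <- function(r_raw) {
  s <- sum(r_raw)
  if (s <= 0) stop("all raw enrichment ratios are zero: no panel reads in condition")
  r_raw / s
}

#' @rdname enrichment_raw
#' @param r_norm Normalized ratios summing to 1.
#' @param n Panel size, default `length(r_norm)`.
#' @return `enrichment_rn()`: the RN vector, summing to 0.
#' @export
enrichment_rn <- function(r_norm, n = length(r_norm)) {
  n * r_norm - 1
}

#' @rdname enrichment_raw
#' @return `rn_cascade()`: list with `r_raw`, `r_norm`, `rn`.
#' @examples
#' rn_cascade(fx = c(0.25, 0.60, 0.15), f0 = c(0.5, 0.3, 0.2))
#' @export
rn_cascade <- function(fx, f0) {
  r_raw <- enrichment_raw(fx, f0)
  r_norm <- normalize_enrichment(r_raw)
  list(r_raw = r_raw, r_norm = r_norm,
       rn = enrichment_rn(r_norm, length(r_norm)))
}

## ---- replicate tables and footprints ----

#' Full RN table for a set of assays
#'
#' Pairs every binding-condition assay with its condition-0 (starting
#' mixture) assay and runs the RN cascade per replicate. Condition-0
#' replicate `r` is paired with condition-x replicate `r` when available;
#' if condition 0 was sequenced once, that sample serves all replicates.
#'
#' @param assays List of `assay_counts` (from [assign_reads()] or
#'   [assay_counts()]), including the condition-0 samples. Condition `"0"`
#'   is the starting mixture.
#' @param pseudocount Reads added to every member count before computing
#'   frequencies (default 0; use e.g. 0.5 for low-depth data so complete
#'   depletion does not zero out a member).
#' @return A `footprint_table`: list with `long` (data.frame: `condition`,
#'   `replicate`, `member`, `count`, `f`, `r_raw`, `r_norm`, `rn`),
#'   `members`, `n`.
#' @export
footprint_table <- function(assays, pseudocount = 0) {
  stopifnot(length(assays) >= 2L,
            all(vapply(assays, inherits, logical(1), "assay_counts")))
  members <- names(assays[[1L]]$counts)
  same <- vapply(assays, function(a) identical(names(a$counts), members),
                 logical(1))
  if (!all(same)) stop("assays use inconsistent panels")
  conds <- vapply(assays, function(a) a$condition, "")
  reps <- vapply(assays, function(a) a$replicate, integer(1))
  if (!any(conds == "0")) stop("no condition-0 (starting mixture) assay supplied")

  freq_of <- function(a) {
    cnt <- a$counts + pseudocount
    tot <- sum(cnt)
    if (tot <= 0) stop("assay has no assigned reads (condition ",
                       a$condition, ", replicate ", a$replicate, ")")
    cnt / tot
  }
  zero_idx <- which(conds == "0")
  zero_by_rep <- stats::setNames(zero_idx, reps[zero_idx])

  rows <- list()
  for (i in which(conds != "0")) {
    a <- assays[[i]]
    j <- zero_by_rep[as.character(a$replicate)]
    if (is.na(j)) j <- zero_idx[1L]
    casc <- rn_cascade(freq_of(a), freq_of(assays[[j]]))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = a$condition, replicate = a$replicate, member = members,
      count = unname(a$counts), f = unname(freq_of(a)),
      r_raw = unname(casc$r_raw), r_norm = unname(casc$r_norm),
      rn = unname(casc$rn), stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  structure(list(long = long, members = members, n = length(members)),
            class = "footprint_table")
}

#' @export
print.footprint_table <- function(x, ...) {
  cat("Footprint table:", x$n, "panel members,",
      length(unique(x$long$condition)), "conditions,",
      nrow(unique(x$long[c("condition", "replicate")])), "assays\n")
  invisible(x)
}

#' Median footprint across technical replicates
#'
#' The footprint of a condition is the per-member median RN over its
#' replicates (for an even replicate count, the mean of the two middle
#' values — the standard sample-median convention).
#'
#' @param fp A `footprint_table` from [footprint_table()].
#' @return Numeric matrix, members x conditions, of median RN values —
#'   the heat-map / clustering input.
#' @export
median_footprint <- function(fp) {
  stopifnot(inherits(fp, "footprint_table"))
  long <- fp$long
  conds <- sort(unique(long$condition))
  out <- matrix(NA_real_, nrow = fp$n, ncol = length(conds),
                dimnames = list(fp$members, conds))
  for (cd in conds) {
    sub <- long[long$condition == cd, , drop = FALSE]
    med <- tapply(sub$rn, sub$member, median)
    out[, cd] <- as.numeric(med[fp$members])
  }
  out
}

#' Write the long RN table and the wide median footprint matrix as TSV
#'
#' @param fp A `footprint_table`.
#' @param dir Output directory.
#' @export
write_footprint_tsv <- function(fp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(fp$long, file.path(dir, "rn_long.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  med <- median_footprint(fp)
  write.table(data.frame(member = rownames(med), med, check.names = FALSE),
              file.path(dir, "footprint_median.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
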