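#' Levenshtein edit distance between sequences
#'
#' Unit-cost edit distance (substitutions, insertions, deletions), the
#' metric used both for family clustering and for read-to-panel
#' assignment. Elementwise over recycled `a`, `b`.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @seealso [levenshtein_matrix()] for the all-pairs form.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(normalize_seq(a), n)
  b <- rep_len(normalize_seq(b), n)
  as.integer(mapply(function(x, y) adist(x, y), a, b))
}

#' @rdname levenshtein
#' @return For `levenshtein_matrix()`, an integer matrix
#'   `length(a) x length(b)`.
#' @export
levenshtein_matrix <- function(a, b = a) {
  m <- adist(normalize_seq(a), normalize_seq(b))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(a, b)
  m
}

#' Select candidate sequences reaching an abundance threshold
#'
#' Keeps every unique sequence whose frequency is at least `threshold`
#' (inclusive) in at least one of the supplied round libraries. The
#' default 1e-5 corresponds to the 0.001\% rule.
#'
#' @param libs List of `round_library` objects (e.g. all rounds of one or
#'   both selections analysed jointly).
#' @param threshold Frequency threshold, default `1e-5`.
#' @return A data.frame (the candidate set) with columns `sequence`,
#'   `total_count` (summed read count across `libs`) and `max_freq`
#'   (highest per-round frequency attained), sorted by decreasing
#'   `total_count`, ties by sequence.
#' @export
select_candidates <- function(libs, threshold = 1e-5) {
  stopifnot(length(libs) >= 1L,
            all(vapply(libs, inherits, logical(1), "round_library")))
  if (all(vapply(libs, function(l) l$total, integer(1)) == 0L))
    stop("all round libraries are empty")
  per_lib <- lapply(libs, function(l) {
    if (l$total == 0L) return(NULL)
    data.frame(sequence = names(l$counts),
               count = unname(l$counts),
               freq = unname(l$counts) / l$total,
               stringsAsFactors = FALSE)
  })
  all_df <- do.call(rbind, per_lib)
  total <- tapply(all_df$count, all_df$sequence, sum)
  maxf <- tapply(all_df$freq, all_df$sequence, max)
  keep <- names(maxf)[maxf >= threshold]
  out <- data.frame(sequence = keep,
                    total_count = as.integer(total[keep]),
                    max_freq = as.numeric(maxf[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster candidate sequences into families by edit distance
#'
#' Greedy abundance-seeded clustering: candidates are processed in
#' decreasing total-count order (ties by sequence); each sequence joins the
#' earliest-founded family whose representative lies within `max_dist`
#' edits, otherwise it founds a new family. Because seeds are processed
#' first, each family's representative is its most abundant member (ties
#' resolved toward the lexicographically smaller sequence). Family ids
#' `F0, F1, ...` are assigned by decreasing family total count after
#' clustering.
#'
#' @param candidates A candidate set from [select_candidates()], or a
#'   data.frame with columns `sequence` and `total_count`.
#' @param max_dist Inclusive Levenshtein membership radius, default 7.
#' @return An `aptamer_families` object: list with `families` (data.frame:
#'   `family_id`, `representative`, `n_members`, `total_count`), `members`
#'   (data.frame: `sequence`, `family_id`, `total_count`), and `max_dist`.
#' @export
cluster_families <- function(candidates, max_dist = 7L) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L,
            all(c("sequence", "total_count") %in% names(candidates)))
  ord <- order(-candidates$total_count, candidates$sequence)
  seqs <- normalize_seq(candidates$sequence[ord])
  cnts <- candidates$total_count[ord]
  if (anyDuplicated(seqs)) stop("candidate sequences must be unique")

  reps <- character(0)
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    j <- 0L
    if (length(reps)) {
      d <- adist(seqs[i], reps)[1L, ]
      hit <- which(d <= max_dist)
      if (length(hit)) j <- hit[1L]       # earliest-founded family wins
    }
    if (j == 0L) {
      reps <- c(reps, seqs[i])
      j <- length(reps)
    }
    assignment[i] <- j
  }

  fam_total <- tapply(cnts, assignment, sum)
  fam_order <- order(-as.numeric(fam_total), reps)
  new_id <- integer(length(reps))
  new_id[fam_order] <- seq_along(reps) - 1L     # F0 = most abundant
  ids <- paste0("F", new_id)

  members <- data.frame(sequence = seqs,
                        family_id = ids[assignment],
                        total_count = cnts,
                        stringsAsFactors = FALSE)
  families <- data.frame(family_id = ids[fam_order],
                         representative = reps[fam_order],
                         n_members = as.integer(table(assignment)[as.character(fam_order)]),
                         total_count = as.integer(fam_total[as.character(fam_order)]),
                         stringsAsFactors = FALSE)
  rownames(families) <- NULL
  structure(list(families = families, members = members,
                 max_dist = as.integer(max_dist)),
            class = "aptamer_families")
}

#' @export
print.aptamer_families <- function(x, ...) {
  cat("Aptamer families:", nrow(x$families), "families over",
      nrow(x$members), "candidate sequences (radius", x$max_dist, ")\n")
  print(utils::head(x$families, 10L))
  invisible(x)
}

#' Per-round frequency trajectories of families
#'
#' For each family, the per-round sum of its members' frequencies (members
#' absent from a round contribute 0).
#'
#' @param fams An `aptamer_families` object.
#' @param libs List of `round_library` objects; column order follows
#'   `libs`.
#' @return Numeric matrix, families x rounds, rownames = family ids
#'   (F0 first), colnames = `<selex_id>.r<round_index>`.
#' @export
family_trajectories <- function(fams, libs) {
  stopifnot(inherits(fams, "aptamer_families"))
  ids <- fams$families$family_id
  traj <- matrix(0, nrow = length(ids), ncol = length(libs),
                 dimnames = list(ids, vapply(libs, function(l)
                   paste0(l$selex_id, ".r", l$round_index), "")))
  fam_of <- fams$members$family_id
  for (k in seq_along(libs)) {
    l <- libs[[k]]
    if (l$total == 0L) next
    f <- l$counts[fams$members$sequence] / l$total
    f[is.na(f)] <- 0
    traj[, k] <- as.numeric(tapply(f, fam_of, sum)[ids])
  }
  traj[is.na(traj)] <- 0
  traj
}

#' Number of families present per round
#'
#' Counts, per round, the families whose trajectory entry reaches the
#' presence threshold: strictly positive when `presence_threshold = 0`
#' (the default), otherwise `>= presence_threshold`.
#'
#' @param traj A families x rounds matrix from [family_trajectories()].
#' @param presence_threshold Frequency threshold, default 0.
#' @return Integer vector, one entry per round.
#' @export
diversity_per_round <- function(traj, presence_threshold = 0) {
  if (presence_threshold == 0) colSums(traj > 0)
  else colSums(traj >= presence_threshold)
}

#' Export family members as FASTA files
#'
#' One FASTA per family (for downstream multiple alignment or structure
#' prediction tools).
#'
#' @param fams An `aptamer_families` object.
#' @param dir Output directory (created if needed).
#' @export
write_family_fasta <- function(fams, dir) {
  stopifnot(inherits(fams, "aptamer_families"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in fams$families$family_id) {
    m <- fams$members[fams$members$family_id == id, , drop = FALSE]
    x <- Biostrings::DNAStringSet(m$sequence)
    names(x) <- paste0(id, "_", seq_len(nrow(m)), "_n", m$total_count)
    Biostrings::writeXStringSet(x, file.path(dir, paste0(id, ".fasta")))
  }
  invisible(dir)
}
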