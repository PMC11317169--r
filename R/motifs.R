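#' Define a sequence motif for approximate search
#'
#' @param name Motif label.
#' @param pattern Motif sequence (DNA-normalized; U accepted).
#' @param max_edits Maximum unit-cost edits tolerated when searching,
#'   default 1.
#' @return A `motif` object (list with `name`, `pattern`, `max_edits`).
#' @export
motif <- function(name, pattern, max_edits = 1L) {
  pattern <- normalize_seq(pattern)
  stopifnot(nchar(pattern) >= 4L, max_edits >= 0L,
            max_edits < nchar(pattern))
  structure(list(name = name, pattern = pattern,
                 max_edits = as.integer(max_edits)),
            class = "motif")
}

#' The three conserved selection motifs
#'
#' The conserved motifs recurrently found in enriched families
#' (DNA-normalized spellings of the RNA motifs), with the default edit
#' tolerance of 1.
#'
#' @return A named list of [motif()] objects.
#' @export
selex_motifs <- function() {
  list(motif1 = motif("motif1", "ACGCGTTTAC"),
       motif2 = motif("motif2", "CAACTTATAC"),
       motif3 = motif("motif3", "CAACCTTTGAAATCC"))
}

#' Approximate substring search for a motif
#'
#' Semi-global matching: the full pattern must align against some
#' substring of each sequence with at most `max_edits` unit-cost edits
#' (substitutions, insertions, deletions); the sequence's flanks are free.
#' The reported `edits` is the minimum over all placements; `start`/`end`
#' give the first best-scoring placement.
#'
#' @param m A [motif()] object.
#' @param seqs Character vector of sequences.
#' @param max_edits Optional override of the motif's edit tolerance.
#' @return A data.frame with columns `seq`, `hit` (logical), `edits`
#'   (NA when no hit), `start`, `end`.
#' @export
approx_contains <- function(m, seqs, max_edits = NULL) {
  stopifnot(inherits(m, "motif"))
  k_max <- if (is.null(max_edits)) m$max_edits else as.integer(max_edits)
  seqs <- normalize_seq(seqs)
  n <- length(seqs)
  edits <- rep(NA_integer_, n)
  subject <- Biostrings::DNAStringSet(seqs)
  pending <- seq_len(n)
  for (k in 0:k_max) {
    if (!length(pending)) break
    cnt <- Biostrings::vcountPattern(m$pattern, subject[pending],
                                     max.mismatch = k,
                                     with.indels = k > 0L)
    hit_now <- cnt > 0L
    edits[pending[hit_now]] <- k
    pending <- pending[!hit_now]
  }
  start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  found <- which(!is.na(edits))
  for (i in found) {
    mm <- Biostrings::matchPattern(m$pattern, subject[[i]],
                                   max.mismatch = edits[i],
                                   with.indels = edits[i] > 0L)
    start[i] <- BiocGenerics::start(mm)[1L]
    end[i] <- BiocGenerics::end(mm)[1L]
  }
  data.frame(seq = seqs, hit = !is.na(edits), edits = edits,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Per-round motif prevalence across families
#'
#' A family "contains" a motif iff the motif matches the family
#' representative within the motif's edit tolerance (set
#' `check_members = TRUE` for the strict mode where any member hit
#' counts). Per round, reports the summed frequency of containing
#' families (fraction of the library) and their number.
#'
#' @param m A [motif()] object.
#' @param fams An `aptamer_families` object.
#' @param traj A families x rounds trajectory matrix from
#'   [family_trajectories()].
#' @param check_members If TRUE, a family counts when any member matches.
#' @return A data.frame with one row per round: `round`,
#'   `library_fraction`, `n_families` (containing families observed in
#'   that round, i.e. with positive trajectory entry).
#' @export
motif_prevalence <- function(m, fams, traj, check_members = FALSE) {
  stopifnot(inherits(fams, "aptamer_families"),
            identical(rownames(traj), fams$families$family_id))
  if (check_members) {
    hits <- approx_contains(m, fams$members$sequence)$hit
    fam_hit <- tapply(hits, fams$members$family_id, any)
    containing <- as.logical(fam_hit[fams$families$family_id])
  } else {
    containing <- approx_contains(m, fams$families$representative)$hit
  }
  sub <- traj[containing, , drop = FALSE]
  data.frame(round = colnames(traj),
             library_fraction = as.numeric(colSums(sub)),
             n_families = as.integer(colSums(sub > 0)),
             stringsAsFactors = FALSE)
}

#' Prevalence table for several motifs
#'
#' @param motifs A list of [motif()] objects.
#' @inheritParams motif_prevalence
#' @return Long data.frame: `motif`, `round`, `library_fraction`,
#'   `n_families`.
#' @export
motif_prevalence_table <- function(motifs, fams, traj,
                                   check_members = FALSE) {
  out <- lapply(motifs, function(m) {
    df <- motif_prevalence(m, fams, traj, check_members = check_members)
    cbind(motif = m$name, df, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
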