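#' Trim fixed primer-binding sites off amplicon reads
#'
#' Recovers the random region of each read by anchored matching of the two
#' fixed flanking sequences: `primer5` is matched as a prefix of the read
#' and `primer3` at a window whose start is scanned over candidate insert
#' lengths, taking the minimal-mismatch placement (ties resolved toward the
#' shortest insert). Primers are matched by Hamming distance (no indels
#' inside the primers themselves; insert-length variation absorbs indels).
#' Ambiguous bases count as mismatches.
#'
#' The scan covers insert lengths `length_window` widened by `scan_slack`
#' on both sides, so that reads whose insert falls just outside the
#' retention window are classified as length rejections rather than
#' primer-matching failures.
#'
#' @param reads Character vector of read sequences (U is normalized to T,
#'   case-insensitive).
#' @param primer5,primer3 Fixed 5' and 3' flanking sequences.
#' @param max_mismatch Maximum Hamming mismatches tolerated in each primer
#'   (default 2).
#' @param length_window Closed interval of retained region lengths,
#'   default `c(33, 37)`.
#' @param scan_slack Extra insert lengths scanned on each side of
#'   `length_window` (default 2) so out-of-window inserts are still located.
#' @return A data.frame with one row per read: `region` (NA when rejected),
#'   `length`, `mismatch5`, `mismatch3`, and `reason` (`NA`,
#'   `"primer-not-found"`, or `"length-out-of-window"`).
#' @seealso [build_round_library()] for the full FASTQ-to-frequency-table
#'   step, [extract_random_region()] for the single-read form.
#' @export
trim_reads <- function(reads, primer5, primer3, max_mismatch = 2L,
                       length_window = c(33L, 37L), scan_slack = 2L) {
  stopifnot(nzchar(primer5), nzchar(primer3), length_window[1] >= 1L,
            length_window[2] >= length_window[1], scan_slack >= 0L)
  reads <- normalize_seq(reads)
  primer5 <- normalize_seq(primer5)
  primer3 <- normalize_seq(primer3)
  n5 <- nchar(primer5); n3 <- nchar(primer3)
  n <- length(reads)
  len <- nchar(reads)

  mm5 <- hamming_to(primer5, substr(reads, 1L, n5))
  ok5 <- mm5 <= max_mismatch

  lo <- max(0L, length_window[1] - scan_slack)
  Ls <- seq.int(lo, length_window[2] + scan_slack)
  best_mm <- rep(Inf, n)
  best_L <- rep(NA_integer_, n)
  for (L in Ls) {
    start3 <- n5 + L + 1L
    window <- substr(reads, start3, start3 + n3 - 1L)
    mm3 <- hamming_to(primer3, window)
    upd <- mm3 < best_mm            # strict: ties keep the smallest insert
    if (any(upd)) {
      best_mm[upd] <- mm3[upd]
      best_L[upd] <- L
    }
  }
  ok3 <- best_mm <= max_mismatch

  found <- ok5 & ok3
  in_window <- found & best_L >= length_window[1] & best_L <= length_window[2]
  region <- rep(NA_character_, n)
  region[in_window] <- substr(reads[in_window], n5 + 1L, n5 + best_L[in_window])
  reason <- rep(NA_character_, n)
  reason[!found] <- "primer-not-found"
  reason[found & !in_window] <- "length-out-of-window"
  data.frame(region = region,
             length = ifelse(found, best_L, NA_integer_),
             mismatch5 = ifelse(is.finite(mm5), mm5, NA_real_),
             mismatch3 = ifelse(is.finite(best_mm), best_mm, NA_real_),
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Extract the random region from a single read
#'
#' Single-read convenience wrapper around [trim_reads()] (without the
#' length window: any located insert is returned, so callers can apply
#' [length_filter()] separately).
#'
#' @inheritParams trim_reads
#' @param read A single read sequence.
#' @return A list with `region` (character or NA), `edits5`, `edits3`, and
#'   `reason` (NA or `"primer-not-found"`).
#' @export
extract_random_region <- function(read, primer5, primer3, max_mismatch = 2L,
                                  length_window = c(33L, 37L),
                                  scan_slack = 2L) {
  stopifnot(length(read) == 1L)
  if (is.na(read) || !nzchar(read)) {
    return(list(region = NA_character_, edits5 = NA_real_, edits3 = NA_real_,
                reason = "primer-not-found"))
  }
  wide <- c(max(1L, length_window[1] - scan_slack),
            length_window[2] + scan_slack)
  tr <- trim_reads(read, primer5, primer3, max_mismatch = max_mismatch,
                   length_window = wide, scan_slack = 0L)
  list(region = tr$region, edits5 = tr$mismatch5, edits3 = tr$mismatch3,
       reason = tr$reason)
}

#' Retention window on random-region length
#'
#' TRUE iff the region length lies in the closed interval `window`
#' (default 33--37 nt, tolerating small insertions/deletions around the
#' nominal 35-nt random region).
#'
#' @param region Character vector of region sequences (or NA).
#' @param window Closed length interval, default `c(33, 37)`.
#' @return Logical vector; NA regions give FALSE.
#' @export
length_filter <- function(region, window = c(33L, 37L)) {
  !is.na(region) & nchar(region) >= window[1] & nchar(region) <= window[2]
}

# Read sequences from a FASTQ(.gz) file. Returns a character vector;
# errors name the file. Quality strings are ignored by design.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(character(0))
  seqs <- tryCatch(
    as.character(Biostrings::readBStringSet(path, format = "fastq")),
    error = function(e) stop("failed to parse FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  unname(seqs)
}

#' Build a per-round frequency table from a FASTQ file
#'
#' Reads a FASTQ (optionally gzipped) round file, trims the fixed
#' primer-binding sites with [trim_reads()], applies the region-length
#' retention window, and tabulates read counts per unique region sequence.
#' Sequences are DNA-normalized (uppercase, U to T). Quality scores are
#' ignored unless `min_mean_q` is set.
#'
#' @param fastq Path to a FASTQ or FASTQ.gz file, or (for pre-trimmed
#'   input) a character vector of read sequences via `reads =`.
#' @param primer5,primer3 Fixed flanking sequences.
#' @param selex_id Label for the selection series (e.g. "S1").
#' @param round_index Non-negative integer round number.
#' @param max_mismatch,length_window,scan_slack Passed to [trim_reads()].
#' @param reads Optional character vector of raw reads, used instead of
#'   reading `fastq` from disk.
#' @return A `round_library` object: a list with `selex_id`, `round_index`,
#'   `counts` (named integer vector, unique region -> read count, sorted by
#'   decreasing count then sequence), `total`, `n_total`,
#'   `n_rejected_primer`, `n_rejected_length`.
#' @examples
#' lib <- build_round_library(reads = paste0(default_primer5(),
#'                                           strrep("A", 35),
#'                                           default_primer3()),
#'                            selex_id = "S1", round_index = 1)
#' frequency(strrep("A", 35), lib)
#' @export
build_round_library <- function(fastq = NULL,
                                primer5 = default_primer5(),
                                primer3 = default_primer3(),
                                selex_id = "S1", round_index = 0L,
                                max_mismatch = 2L,
                                length_window = c(33L, 37L),
                                scan_slack = 2L, reads = NULL) {
  if (is.null(reads)) {
    if (is.null(fastq)) stop("supply either `fastq` or `reads`")
    reads <- read_fastq_sequences(fastq)
  }
  if (length(reads) == 0L) {
    warning("no reads in input", if (!is.null(fastq)) paste0(" '", fastq, "'"))
    return(new_round_library(integer(0), selex_id, round_index,
                             n_total = 0L, n_rejected_primer = 0L,
                             n_rejected_length = 0L))
  }
  tr <- trim_reads(reads, primer5, primer3, max_mismatch = max_mismatch,
                   length_window = length_window, scan_slack = scan_slack)
  kept <- tr$region[!is.na(tr$region)]
  counts <- table_counts(kept)
  new_round_library(counts, selex_id, round_index,
                    n_total = length(reads),
                    n_rejected_primer = sum(tr$reason == "primer-not-found",
                                            na.rm = TRUE),
                    n_rejected_length = sum(tr$reason == "length-out-of-window",
                                            na.rm = TRUE))
}

# Tabulate sequences into a named integer vector sorted by decreasing
# count, ties broken by sequence, for deterministic output.
table_counts <- function(seqs) {
  if (length(seqs) == 0L) return(integer(0))
  tab <- table(seqs)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

new_round_library <- function(counts, selex_id, round_index,
                              n_total, n_rejected_primer, n_rejected_length) {
  counts <- as.integer(counts) |> stats::setNames(names(counts))
  structure(list(selex_id = selex_id,
                 round_index = as.integer(round_index),
                 counts = counts,
                 total = sum(counts),
                 n_total = as.integer(n_total),
                 n_rejected_primer = as.integer(n_rejected_primer),
                 n_rejected_length = as.integer(n_rejected_length)),
            class = "round_library")
}

#' Construct a round library directly from a count table
#'
#' Used when re-importing a previously emitted unique-sequence table (or
#' simulator truth counts) without re-trimming.
#'
#' @param counts Named integer vector or data.frame with columns
#'   `sequence` and `count`.
#' @inheritParams build_round_library
#' @export
round_library_from_counts <- function(counts, selex_id = "S1",
                                      round_index = 0L) {
  if (is.data.frame(counts)) {
    v <- as.integer(counts$count)
    names(v) <- normalize_seq(counts$sequence)
    counts <- v
  } else {
    names(counts) <- normalize_seq(names(counts))
  }
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  counts <- counts[order(-counts, names(counts))]
  new_round_library(counts, selex_id, round_index,
                    n_total = sum(counts), n_rejected_primer = 0L,
                    n_rejected_length = 0L)
}

#' @export
print.round_library <- function(x, ...) {
  cat("Round library", x$selex_id, "round", x$round_index, "\n")
  cat("  kept reads:   ", x$total, " (", length(x$counts), " unique)\n",
      sep = "")
  cat("  rejected:     ", x$n_rejected_primer, " primer, ",
      x$n_rejected_length, " length (of ", x$n_total, " raw)\n", sep = "")
  invisible(x)
}

#' Frequency of a sequence in a round library
#'
#' The read count of `seq` divided by the total kept reads of the round;
#' 0 for sequences absent from the round.
#'
#' @param seq Character vector of sequences (DNA-normalized internally).
#' @param lib A `round_library`.
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
frequency <- function(seq, lib) {
  stopifnot(inherits(lib, "round_library"))
  if (lib$total == 0L) stop("frequency undefined: round library is empty")
  cnt <- lib$counts[normalize_seq(seq)]
  cnt[is.na(cnt)] <- 0L
  unname(cnt) / lib$total
}

#' All per-sequence frequencies of a round library
#'
#' @param lib A `round_library` with `total > 0`.
#' @return Named numeric vector summing to 1.
#' @export
frequencies <- function(lib) {
  stopifnot(inherits(lib, "round_library"))
  if (lib$total == 0L) stop("frequencies undefined: round library is empty")
  lib$counts / lib$total
}

#' Write / read a round library as TSV
#'
#' The emitted table has columns `sequence`, `count`, `frequency`; a
#' round-trip through [read_round_tsv()] reproduces identical counts.
#'
#' @param lib A `round_library`.
#' @param path Output TSV path.
#' @export
write_round_tsv <- function(lib, path) {
  df <- data.frame(sequence = names(lib$counts),
                   count = unname(lib$counts),
                   frequency = unname(lib$counts) / max(lib$total, 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_round_tsv
#' @inheritParams build_round_library
#' @export
read_round_tsv <- function(path, selex_id = "S1", round_index = 0L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  round_library_from_counts(df, selex_id = selex_id,
                            round_index = round_index)
}
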