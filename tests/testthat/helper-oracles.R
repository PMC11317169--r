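# Independent oracles, implemented from first principles (pure-R dynamic
# programming), used to cross-check the package's primitives. They share
# no code with the implementation under test.

# Unit-cost Levenshtein distance by the textbook DP recurrence.
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1,
                        cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# Semi-global DP: minimum edits to align the full pattern against any
# substring of the subject (free subject ends).
dp_semiglobal <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p); m <- length(s)
  prev <- rep(0, m + 1)            # free start in subject
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1,
                        cur[j] + 1,
                        prev[j] + (p[i] != s[j]))
    }
    prev <- cur
  }
  as.integer(min(prev))            # free end in subject
}

# Naive re-implementation of greedy abundance-seeded clustering, used to
# confirm determinism and the cross-representative separation property.
naive_greedy_cluster <- function(seqs, counts, max_dist) {
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]
  reps <- character(0)
  member_of <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (j in seq_along(reps)) {
      if (dp_levenshtein(seqs[i], reps[j]) <= max_dist) {
        member_of[i] <- j; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps <- c(reps, seqs[i])
      member_of[i] <- length(reps)
    }
  }
  list(sequence = seqs, rep = reps[member_of], reps = reps)
}

# Random DNA string helper for property tests.
rand_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len[i],
                                  replace = TRUE), collapse = ""), "")
}

# Write a minimal 4-line-record FASTQ for fixture reads.
write_test_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  rec <- if (length(seqs)) {
    paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
           strrep("I", nchar(seqs)))
  } else character(0)
  writeLines(rec, path)
  path
}
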