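---
title: "Methods: SELEX enrichment analysis and aptamer footprinting"
author: "aptafootseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SELEX enrichment analysis and aptamer footprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptafootseq)
```

# Overview

`aptafootseq` analyses two kinds of sequencing experiments on aptamer
libraries:

1. **SELEX round series** — a random-region oligonucleotide library is
   subjected to iterative rounds of binding selection and amplification;
   each round is sequenced, and the analysis tracks which sequence
   *families* enrich, how library diversity collapses, and which conserved
   motifs spread.
2. **Mixture-binding assays ("footprinting")** — a defined panel of
   selected aptamers plus a scramble control is incubated with a target
   (here, distinct amyloid fibrillar polymorphs), the bound fraction is
   sequenced, and the differential retention of each panel member is
   summarised as a *normalized enrichment ratio* vector — the footprint —
   which discriminates targets by correlation distance.

Everything operates in the DNA alphabet: the library chemistry
(2'-fluoro-pyrimidine RNA) is metadata, and U is normalized to T on
ingest.

# Read ingest and frequency tables

Reads are amplicons of the form *primer5 + random region + primer3*. The
library design fixes the primer positions, so matching is anchored:
`primer5` is matched as a read prefix and `primer3` at a window whose
start is scanned over candidate insert lengths, each by Hamming distance
with a per-primer mismatch allowance (default 2; ambiguous bases count as
mismatches). Indels are not modelled *inside* the primers — insert-length
variation absorbs them, which is why the retention window on the
recovered region is 33–37 nt around the nominal 35-mer: deletions and
insertions of a few bases are common during selection and amplification.

Two design details are deliberate:

* **Scan slack.** The primer3 scan covers insert lengths 31–39 (the
  retention window widened by 2 on each side). A read whose insert has
  drifted to 32 nt is thereby recognised and rejected *for length*, not
  mis-reported as a primer-matching failure; the ingest report
  partitions every raw read into kept / rejected-primer /
  rejected-length.
* **Minimal-mismatch placement, smallest insert on ties.** Deterministic
  and independent of read order.

Frequencies are computed over kept reads only: the denominator of every
per-sequence frequency is the round's kept-read total. Rejected reads
carry no usable random region, and including them would only rescale all
frequencies by a round-specific constant. Quality scores are ignored by
default (no quality filter is part of the procedure); an optional mean-Q
threshold could be layered on upstream, but trimming plus the length
window already removes the reads a quality filter would target.

# Family clustering

Sequences whose frequency reaches **0.001 % (1e-5) in at least one
round** — the threshold is inclusive — form the candidate set. Candidates
are clustered into families by Levenshtein (unit-cost edit) distance with
an inclusive radius of **7**: of the two possible readings ("distance of
7" vs "less than seven edits"), the inclusive one is the default and
`max_dist` is exposed so either convention can be reproduced.

The clustering is **greedy, abundance-seeded and
representative-anchored**: candidates are processed in decreasing
total-count order (ties broken lexicographically); each joins the
earliest-founded family whose representative is within `max_dist` edits,
otherwise it founds a new family. Consequences worth knowing:

* each family's representative is its most abundant member;
* representatives of different families are always separated by more
  than `max_dist` edits (a sequence that close would have joined);
* the result is deterministic and costs O(candidates × families), with
  no need for an all-pairs distance matrix;
* unlike single-linkage, families cannot chain: every member is within
  `max_dist` of its representative (the radius bound), which matches the
  observation that families mostly contain sequences within about three
  edits of each other.

Family trajectories are per-round sums of member frequencies; diversity
is the number of families observed (trajectory > 0 by default, or above
a supplied presence threshold) per round.

# Motif scoring

Conserved motifs are scored by **semi-global approximate matching**: the
full motif must align against some substring of the sequence within
`max_edits` unit-cost edits (default 1), with free ends on the sequence.
A family *contains* a motif when its representative matches — the
representative defines the family — and a strict mode
(`check_members = TRUE`) counts a family when any member matches.
Per round, the motif's prevalence is the summed trajectory of containing
families (fraction of the library) and the number of such families
observed in the round. A family counts once per motif regardless of how
many positions hit. The three built-in motifs use the longer printed
spellings (`ACGCGTTTAC`, `CAACTTATAC`, `CAACCTTTGAAATCC`, DNA-normalized);
alternative spellings can be supplied as `motif()` objects.

# The RN cascade and footprints

For each panel member *a* with frequency *f(a, x)* in condition *x* and
*f(a, 0)* in the starting mixture (condition 0), with *n* the panel size:

$$r_{a,x/0} = \frac{f_{a,C=x}}{f_{a,C=0}}, \qquad
  r_{a,x} = \frac{r_{a,x/0}}{\sum_{b \in A} r_{b,x/0}}, \qquad
  RN_a = \frac{r_{a,x} - 1/n}{1/n} = n\,r_{a,x} - 1.$$

Because the $r_{a,x}$ lie on the unit simplex, $\sum_a RN_a = 0$
identically: enrichment of one member forces depletion of others. RN is
bounded below by −1 (complete depletion) and above by $n - 1$ (sole
survivor). The cascade is computed **per replicate, then the footprint
is the per-member median across replicates** (three technical replicates
typically; even counts use the standard middle-mean median) — median of
RNs, not RN of medians.

Numerical choices:

* *Frequencies over assigned reads only.* The mixture is closed over the
  panel (14 aptamers + scramble = 15 members); contaminant or unassigned
  reads must not distort the simplex.
* *Read assignment* maps each read to the panel member at minimal edit
  distance when that minimum is unique and ≤ `max_dist` (default 3);
  ties and distant reads are left unassigned. Panel validation requires
  all pairwise reference distances to exceed `max_dist` at load — a panel
  containing a close variant pair (e.g. a two-mutation variant of
  another member) is only valid at `max_dist` 1, and the loader says so
  rather than silently mis-assigning.
* *Zero counts in condition x* give $r_{a,x/0} = 0$ and hence
  $RN_a = -1$, a meaningful "completely depleted" signal. A pseudocount
  option (e.g. +0.5 reads to every member) is available for low-depth
  data where sampling zeros would otherwise masquerade as depletion.
* *Zero counts in condition 0* are a hard error: the starting mixture is
  equimolar by design and must represent every member.

# Footprint comparison

Footprints are compared by **Pearson-correlation distance**
$d(x,y) = 1 - r(x,y)$ between median-RN vectors (centered correlation by
default; the uncentered variant used by some Cluster-3.0-family tools is
available). Agglomerative clustering uses **average linkage** by default
— the Cluster-3.0/TreeView family default, since the original analysis
was performed in such a viewer without stating its settings — with
single and complete linkage as options. Conditions are sorted
lexicographically before clustering so equal-height merges resolve
reproducibly. The dendrogram is exported as Newick (branch lengths
derived from merge heights, so branch length reflects footprint
dissimilarity) and as a Cluster-3.0-style `.cdt`/`.gtr` pair for
TreeView-family viewers. Replicate reproducibility is summarised as the
squared Pearson correlation between replicate RN vectors.

# The synthetic-data generator

The simulators exist so that every stage can be verified against planted
ground truth without downloading the original sequencing runs.

**SELEX simulator.** A small set of founder 35-mers is planted in a
neutral random background. Each round applies one multiplicative
selection step ($f' = w f / \sum w f$ — a deliberate simplification: no
explicit wash/elution sub-steps), multinomial resampling at the
sequencing depth, per-base substitution mutations (default 1e-3/base per
round) and rare single-base indels (default 1e-3/read per round), which
generate the within-family variant clouds and the off-nominal insert
lengths that exercise the 33–37 window. Emitted reads get iid
substitution sequencing errors (default 5e-4/base) and the fixed
primers. Defaults mirror the study conditions at desk scale: **15
rounds**, **1e5 reads per round** (scaled down from the millions of
reads per round of the full experiment), 10 founder families at initial
frequency 1e-3 each with fitness evenly spaced 1.1–1.8. These defaults
reproduce the qualitative dynamics the analysis must detect — exponential
family enrichment reaching a large fraction of the library by the final
rounds and a collapse of family diversity in late rounds. When
analysing runs at this scaled depth the candidate threshold should scale
accordingly (1e-4 ≈ 10 reads at 1e5 depth, proportional to ~100 reads at
full scale); the package default remains the full-scale 1e-5 rule.

**Assay simulator.** The starting mixture has composition `f0`
(equimolar by default) over the panel; the bound fraction under
condition *x* has composition `q_x`; observed counts per replicate are
multinomial draws at ~1e5 reads. The implied truth is
$RN_a = n\,\frac{q_a/f_{0,a}}{\sum_b q_b/f_{0,b}} - 1$, recorded
alongside the data; `q = f0` models the no-protein control, whose truth
footprint is identically zero. FASTQ output adds substitution errors to
panel reference reads; count-table output skips read-level noise.

What the simulators do **not** emulate: PCR chimeras, realistic
position-dependent Illumina error profiles, competition or cooperativity
between aptamers for binding sites, and RT-PCR amplification bias.
Passing the recovery tests therefore shows the *analysis* is correct and
well-calibrated under multinomial sampling and uniform error, not that
any particular biological dataset is free of those artefacts — the
no-protein control exists precisely to detect such bias empirically.

The built-in 15-member panel (`default_panel()`) carries the familiar
member labels but **synthetic, well-separated reference sequences**
(minimum pairwise edit distance 16, fixed at build time); real analyses
load their panel from FASTA.

# Problem sizes used in the tests

The test-suite recovery checks run at the scaled study conditions: assay
recovery at 1e5 reads × 3 replicates × 20 seeds (mean absolute RN error
below 0.05, and all |median RN| < 0.05 for the no-protein analogue);
polymorph discrimination with two classes of three conditions each over
10 seeds (exact bipartition, adjusted Rand index 1); SELEX recovery at
15 rounds × 1e5 reads with 10 planted families over 5 seeds (founders
recovered as the top-10 family representatives, radius and separation
bounds verified, Spearman ρ ≥ 0.9 between planted fitness and log
round-15/round-1 enrichment).

# Known limitations

* Primer matching tolerates substitutions only; a read with an indel
  *inside* a primer is rejected rather than rescued.
* Greedy clustering is order-dependent by design (abundance order); a
  different tie in total counts can found families in a different order.
  The determinism guarantees make this reproducible, not assumption-free.
* `n_families` in motif prevalence counts containing families observed
  in the round, so it can dip when a containing family drops out of a
  round entirely.
* The assignment radius interacts with panel design; very close panel
  variants (edit distance ≤ 3) force `max_dist = 1`, where a read with
  two sequencing errors becomes unassignable rather than guessed.
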