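---
title: "panelforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panelforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

# The problem

Functional-gene families such as the reductive dehalogenases (RdhA), the
enzymes of anaerobic organohalide respiration, are too divergent for a
single universal PCR primer pair.  A practical survey instrument is a
*suite* of degenerate primer pairs: the family phylogeny is cut into
coherent sub-groups, one degenerate pair is designed per group against the
group consensus, and all pairs are run under common cycling conditions.
Sequenced amplicons are then classified back onto the reference family,
screened for chimeras, clustered into ortholog "types" at ≥90% pairwise
amino-acid identity (PID), binned by novelty against the reference
database, and tabulated across samples.

panelforge implements that whole workflow — grouping, design,
in-silico validation, and amplicon analysis — plus a seeded synthetic
gene-family generator so that every stage is testable without any external
download.

# Partitioning the family tree

Groups must be clades whose members are mutually similar, either in
patristic distance (branch-length sum along the tree path,
substitutions/site) or in percent nucleotide identity over the master
alignment.  `partition_tree()` returns the **maximal clades** whose leaf
sets satisfy the closeness constraint.  Because the constraint is monotone
(a clade inside a satisfying clade also satisfies it), this set is exactly
the fixed point of a bottom-up greedy merge and is the unique minimal
clade partition; the test suite verifies minimality against an exhaustive
enumeration of all clade partitions on trees of up to 8 leaves.

Choices a user should know about:

* **Threshold.** The published grouping of the RdhA family was a manual
  judgment call; no numeric rule is stated anywhere.  The default maximum
  within-group patristic distance is 2.0 substitutions/site (identity
  metric: minimum within-group PID, default 70 in the CLI).  Both are
  tunable; we deliberately do not search for a threshold that reproduces
  any particular published group count, since that count is an outcome of
  one dataset, not a property of the algorithm.
* **Rooting.** Clade extraction needs a root; unrooted input is
  midpoint-rooted (`phangorn::midpoint`).
* **Small groups.** With `min_group_size > 1`, an undersized clade can
  only be merged by promoting it to an enclosing clade.  Under a
  max-distance constraint the enclosing clade necessarily violates the
  constraint (otherwise it would already be a group), so such groups are
  kept and flagged; the merge path exists for identity-metric edge cases.
* **Sub-group re-alignment** is replaced by column subsetting of the
  master alignment with group-wise all-gap columns removed.  An external
  re-aligner would introduce non-determinism for no benefit at primer
  scale.

# Degenerate primer design

For one group alignment, every gap-free window of 18–28 columns whose
IUPAC consensus degeneracy is at most 512 is a candidate primer site; the
consensus matches every group member at every position *by construction*,
which is what makes in-silico self-coverage of 100% a meaningful check
rather than an accident.

## Thermodynamics

Melting temperatures use unified nearest-neighbor ΔH/ΔS dimer parameters
with terminal initiation terms, the entropic salt correction
ΔS + 0.368·(N−1)·ln[Na⁺]eq, divalent ions folded in as
[Na⁺]eq(mM) = mono + 120·√(Mg), and duplex concentration term R·ln(CT/4).
Defaults mirror the published PCR mix: 50 mM monovalent, 1.5 mM Mg²⁺,
0.5 µM of each primer, ΔG reported at 37 °C.  The vendor calculator used
in the original screen is proprietary; a published NN table is the
reproducible stand-in, and the test suite pins `tm_nn()` to eight values
computed by an independent implementation of the same parameter set
(agreement < 0.01 °C, asserted at 0.5 °C).

A degenerate primer's Tm is reported as the min/max over its plain-DNA
expansions, exact up to a cap (default 32 for screening) and otherwise a
seeded sample that always contains the lexicographic extremes.

## The three constraints

Every emitted pair must satisfy, for both primers:

1. **Tm window** — expansion Tm range inside [40, 65] °C;
2. **Hairpin** — best intramolecular stem (stem ≥ 3 bp, loop ≥ 3 nt, NN
   stem energetics plus a fixed −18 cal/(mol·K) loop entropy) melts at
   ≤ 25 °C;
3. **Dimer rule** — the most stable dimer (cross-dimer over all ungapped
   antiparallel offsets, plus each primer's self-dimer) has
   |ΔG₃₇| ≤ ⅓ · min(|full-duplex ΔG| of the two primers).  "Total ΔG" is
   read conservatively as the primer's own perfect-duplex ΔG, and the
   weaker primer sets the cap.

Dimer ΔG sums NN stacks over contiguous complementary stretches of ≥2 bp
at each offset; the implementation computes this as diagonal sums of a
shifted match matrix, which the tests prove equal to the explicit
per-offset enumeration.

## Ranking and pruning

Feasible pairs are ranked by (lower combined degeneracy, wider Tm headroom
inside the window, longer amplicon, leftmost forward start).  Two bounded
scans keep pure-R runtime at desk scale: only the 8 least-degenerate
windows per 50-column start bin enter thermodynamic screening (preserving
candidates along the whole alignment), and at most `max_dimer_checks`
(default 100) ranked candidates are dimer-screened.  A primer whose
self-dimer already violates the ratio against its own full duplex can
never appear in a valid pair, so it is rejected at window stage.  An empty
result carries per-constraint rejection counts.

# In-silico PCR

Matching is IUPAC-against-IUPAC by expansion-set intersection, so
degenerate primers and ambiguous target bases (N in contigs) both match
permissively.  A binding site needs ≤ `max_mm` mismatches overall and
**zero** mismatches in the 3′ clamp (default 3 bases) — mismatches at the
extending end block polymerisation far more strongly than internal ones.
Amplicons are every (left site, right site on the opposite strand,
non-overlapping, product ≤ 4000 bp) combination, in both orientations
relative to the deposited strand; all nested/overlapping products are
reported because enumeration, not amplification kinetics, is the
verifiable contract.  Tolerant mode defaults (2 mismatches, clamp 3) are
in-silico stand-ins for the deliberately permissive wet-lab cycling; they
are configurable and not claimed to reproduce any particular wet-lab
judgment.

# Amplicon analysis

* **Trimming** removes fixed 5′/3′ pads (defaults 4 and 21 bases, the
  dimensions of the published 102→77 trim), drops adapter-bearing reads
  (exact 12-mer seed, then ≥90% identity over the adapter length) and
  low-complexity reads (any 32-base window with Shannon entropy below 0.5
  bits/base).  The published run's exact artifact-filter settings are not
  stated; these are documented stand-ins.
* **Length gates** are strict: contigs >250 bp form the reporting set,
  >500 bp the external-search subset, proteins >200 aa pass the
  phylogeny/typing gate.  Boundary values are excluded, matching the
  wording "longer than", and unit tests pin the boundaries.
* **Translation** takes the longest stop-free codon run over all six
  frames (≥30 codons; a start codon is not required because amplicons
  enter mid-gene), ties broken +1, +2, +3, −1, −2, −3 then leftmost.
* **Identity** (`compute_pid`) is a global affine-gap alignment (BLOSUM62,
  gap open 10 / extend 0.5; +2/−3 for nucleotides); PID counts identities
  over columns where both sequences are non-gap, and results feed novelty
  binning only when >90% of the query sits in such columns.  BLAST e-value
  gates are database-size dependent and non-deterministic across database
  builds, so classification instead uses score + PID + coverage gates
  (best hit by score, ties by PID then reference id; PID < 25 or coverage
  < 0.5 ⇒ "non-specific", the fate of off-target amplification products).
* **Chimera screen**: the contig is split at its midpoint and the halves
  classified independently; a verdict of chimeric requires both halves to
  hit ≥80% PID references from *different* groups.  A sliding-breakpoint
  scan would be more sensitive but the midpoint rule is deterministic,
  matches how the synthetic chimeras are built, and errs toward
  conservatism — exactly one half of a mid-gene splice retains its donor
  signal even when the breakpoint is off-centre.
* **Ortholog types**: greedy centroid clustering, longest sequence first
  (ties by id), joining the first centroid at ≥90 PID and >0.9 coverage;
  every emitted type is then verified all-pairs and violations are
  re-split by a complete-linkage greedy pass, so the all-pairs ≥90%
  guarantee is unconditional.  Greedy centroid clustering is not optimal
  in general; the acceptance tests check optimality on near-transitive
  instances (mutated prototypes), which is the regime ortholog typing
  operates in.
* **Novelty bins** on the maximum PID to the reference database:
  identical (=100), high (90–<100), novel (30–<90), unassigned (<30);
  90.0 falls in the high bin.
* **Distribution matrix** rows are ordered by number of study samples
  containing the type, then total labels, then type id; types in exactly
  one study sample with no reference member and best database PID <90 are
  flagged unique.

# The synthetic generator: what it does and does not emulate

`simulate_family()` evolves sequences down a coalescent (or birth-death)
tree under a two-parameter (K2P, transition/transversion κ = 2) model,
rescaled so the mean root-to-tip path equals `mean_divergence` (default
0.15 substitutions/site), with per-site rates multiplied down inside
declared conserved blocks (default: two 60-bp blocks at positions 101 and
601 of a 900-bp gene, rate multiplier 0.02).  Conserved blocks are
**primer-able by construction**: block sequence is rejection-sampled until
at least a third of its 18-mers pass the default thermodynamic screen.
This is deliberate — the generator's contract is to produce families with
conserved primer-able blocks, and without it a GC-extreme random block
makes design fail for reasons that say nothing about the algorithms under
test.

Not emulated: indels (the true alignment is gap-free, so gap handling is
exercised by hand-built fixtures instead), sequencing error and quality
scores, abundance/coverage structure, and within-PCR chimera kinetics
(chimeras are clean midpoint splices with recorded breakpoints).  A green
end-to-end test therefore establishes algorithmic correctness on clean
data, not robustness to assembler artifacts.

`make_samples()` mixes random member subsets with composition-preserving
shuffled decoys — the hardest non-specific case for a best-match
classifier, mirroring real off-target amplification — and midpoint
chimeras whose donors come from different groups whenever the grouping
allows.  `fragment_reads()` tiles padded fixed-length reads so that
trimming with the matching spec reconstructs exact source substrings.  All
randomness flows from one integer seed through one RNG stream, giving
byte-identical fixtures.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; strands are `+`/`-`.
* Lowercase input is upper-cased; `U` maps to `T` with a warning; FASTQ
  qualities are Phred+33.
* Alignment rows with zero mutual non-gap overlap get identity 0 with a
  warning rather than NaN.
* A primer longer than its target yields an empty site list, not an
  error; an empty panel is an error in `screen_panel` (a screen without
  primers is a caller bug, not a result).
* `hairpin_tm` returns `-Inf` when no stem of ≥3 bp exists.
* Expansion sampling above the cap always includes the lexicographic
  extremes, so Tm ranges never collapse to an interior sample.
* Ties everywhere break by explicit deterministic keys (documented per
  function), so permuting inputs never changes results.

# Known limitations

* Tm/hairpin/dimer values for degenerate primers above the expansion caps
  are sampled bounds, not exact extrema.
* No dangling-end or mismatch NN corrections; no multiplex compatibility
  optimization across groups; no probe design.
* The classifier's 25%-PID non-specific gate is calibrated for protein
  space; very short queries should rely on the coverage gate.
* The published three-stage touchdown cycling program is wet-lab protocol
  and is not modelled; the annealing constraint is applied to the NN Tm
  directly, with no Tm−5 °C offset, so users comparing against annealing
  temperatures should recalibrate the window.
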