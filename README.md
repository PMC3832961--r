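# panelforge

Degenerate PCR primer suites for gene families, and analysis of the
amplicons they recover.

## Who this is for

Environmental microbiologists and molecular ecologists who want to survey
a *whole* gene family — not just its handful of characterised members —
from mixed community DNA.  The motivating case is the reductive
dehalogenase (*rdhA*) family behind anaerobic organohalide respiration:
hundreds of known genes, deep divergence, and no conserved region that a
single primer pair can span.  The workable instrument is a *suite* of
degenerate primer pairs, one per phylogenetically coherent sub-group of
the family, all running under common PCR conditions.

## What the package does

1. **Group** — partition the family phylogeny into primer-design groups:
   the maximal clades whose members stay within a branch-length or
   percent-identity threshold (`partition_tree`).
2. **Design** — per group, slide 18–28-column gap-free windows over the
   group alignment, build the minimal IUPAC consensus (which matches every
   member by construction), and screen candidates against
   nearest-neighbor thermodynamics: expansion Tm range inside
   [40, 65] °C, hairpin Tm ≤ 25 °C, and worst dimer
   |ΔG₃₇| ≤ ⅓·min(full-duplex |ΔG|) (`design_pair`, `design_panel`).
3. **Validate** — in-silico PCR with IUPAC set-intersection matching, a
   3′ clamp rule, perfect and mismatch-tolerant modes
   (`find_binding_sites`, `amplify`, `screen_panel`, `validate_panel`).
4. **Analyse amplicons** — trim padded reads, gate contigs (>250 bp /
   >500 bp) and proteins (>200 aa), translate the longest ORF across six
   frames, classify against a grouped reference database by affine-gap
   alignment, screen midpoint chimeras, cluster proteins into ≥90%-PID
   ortholog types, bin novelty (identical / 90–99 / 30–89 / <30), and
   build sample-by-type presence tables (`classify`, `cluster_types`,
   `novelty_bins`, `distribution_matrix`).
5. **Simulate** — a seeded generator of gene families with conserved
   primer-able blocks, sample mixtures with decoys and chimeras, and
   padded reads, so the whole loop is testable offline
   (`simulate_family`, `make_samples`, `fragment_reads`).

The melting-temperature model is the unified nearest-neighbor table with
entropic salt correction ΔS + 0.368·(N−1)·ln[Na⁺]eq,
[Na⁺]eq = mono + 120·√[Mg²⁺] (mM), and Tm = 1000·ΔH/(ΔS + R·ln(CT/4)) −
273.15, at defaults of 50 mM monovalent, 1.5 mM Mg²⁺ and 0.5 µM of each
primer.  See `vignette("panelforge-methods")` for every model decision and
its rationale.

## Worked example

```r
library(panelforge)

fam    <- simulate_family(family_spec(n_taxa = 12, seed = 7))
groups <- partition_tree(fam$tree, patristic_distances(fam$tree),
                         max_within = 0.4)
res    <- design_panel(fam$alignment, groups, seed = 7)
res$panel
#>   group_id            fwd_seq            rev_seq tm_min_c tm_max_c expected_len_bp
#> 1        1 TGTGACAGAACTTAGTGT ATCGAATCATGGGTACGA    54.61    57.14             518

validate_panel(res$panel, fam$sequences, group_membership(groups))
#>   group_id n_members n_amplified coverage
#> 1        1        12          12        1

screen_panel(res$panel, fam$sequences[1:3], mode = "perfect")
#> <panel_screen> mode=perfect, 1 group(s) x 3 target(s)
#>   member_01                1 positive of 1 primer sets
#>   member_02                1 positive of 1 primer sets
#>   member_03                1 positive of 1 primer sets
```

The panel row is the designed degenerate pair for group 1: both primers
are degeneracy-1 here (the conserved blocks are near-frozen at this
divergence), their expansion Tm range sits inside the 40–65 °C window,
and the expected product is 518 bp.  `validate_panel` confirms the
in-silico self-coverage contract — every one of the 12 family members
yields a perfect-match amplicon from its own group's pair — and
`screen_panel` reports per-target positives the way a primer-suite survey
table does ("n positive of N primer sets").

A command-line mirror of the workflow ships in `inst/cli/panelforge`:

```sh
Rscript inst/cli/panelforge simulate --outdir fx --seed 7
Rscript inst/cli/panelforge group    --alignment fx/alignment.fasta \
        --tree fx/tree.nwk --metric patristic --max-within 2 --out fx/groups.tsv
Rscript inst/cli/panelforge design   --groups fx/groups.tsv \
        --alignment fx/alignment.fasta --seed 7 --out fx/panel.tsv
Rscript inst/cli/panelforge screen   --panel fx/panel.tsv \
        --targets fx/family.fasta --mode tolerant --out fx/hits.tsv
```

All outputs are plain TSV/FASTA and byte-identical across runs with the
same seed.

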