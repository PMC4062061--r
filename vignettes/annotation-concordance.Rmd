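---
title: "Consequence annotation regimes and concordance accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consequence annotation regimes and concordance accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varconcord)
```

## The problem

Assigning a functional consequence term to a sequence variant — missense,
frameshift, splice donor, intronic, and so on — sounds mechanical, but the
answer depends on two choices that are easy to overlook: *which transcript
set* describes the gene structure, and *which definitional conventions* the
annotation algorithm uses (what counts as a splicing variant, what to report
when several transcripts give different answers, whether an indel that
creates a premature stop is "frameshift" or "stop-gain"). Published
comparisons of widely used tools found that loss-of-function calls — the
variants of most interest in disease studies — agree far less often than the
headline concordance numbers suggest, and that much of the disagreement is
definitional rather than algorithmic.

varconcord makes those definitional choices explicit and testable. It
implements a from-definitions consequence engine over explicit transcript
models, two configurable **regimes** that emulate the two definitional
styles, severity-precedence reporting, harmonization into high-level
categories, and the concordance statistics used to compare annotation runs.
Everything is exercised on seeded synthetic genomes with designed
ground-truth consequences, so every rule in this document is backed by an
executable test. No fidelity to any particular existing tool's corner-case
behaviour is claimed — the regimes implement the published *definitions*,
not reverse-engineered binaries.

## Data model and coordinate conventions

All internal coordinates are 0-based half-open; the GTF (1-based inclusive)
and VCF (1-based, anchor-base indel representation) conventions are
converted at the file boundary only. Variants are held in a minimal
left-aligned representation: shared prefix/suffix trimmed, pure indels
shifted left through homopolymer runs, so classification is independent of
the VCF dialect that produced them. A pure insertion has an empty reference
allele and a zero-width footprint that associates with the base to its left.

A transcript is its exons, CDS intervals, strand and biotype. Coding
transcripts whose CDS length is not a multiple of 3 are flagged
`cds_incomplete` and annotated best-effort up to the last complete codon
(flagged `low_confidence`) rather than rejected, because real GTFs contain
truncated CDS records. Codons containing `N` yield the term `unknown` for
that (variant, transcript) pair; `unknown` deliberately matches nothing in
category accounting, not even itself.

## The two regimes

```{r}
a_style_regime()
v_style_regime()
```

* **A_style** uses one broad `splicing` term: any variant within
  `splicing_window_bp` (default 6) *intronic* bases of an exon/intron
  junction. The width mirrors the broad window a user would configure in
  the single-category tool; whether the window also swallows exonic
  near-junction bases is genuinely ambiguous in the published description,
  so it is configurable (`window_side`, default `"intronic_only"`, meaning
  exonic near-junction variants keep their exonic consequence). A_style
  also enables the indel **stop-scan**: an indel whose re-translated CDS
  gains a premature stop is reported stop-gain rather than frameshift. Stop
  terms keep the historical `_SNV` suffix (`stopgain_SNV`) even for indel
  stop-gains, matching the vocabulary of the published comparison tables.
* **V_style** uses the fine splicing subcategories: `splice_donor_variant`
  and `splice_acceptor_variant` are the two intronic bases at the 5' and 3'
  end of an intron (strand-aware), and `splice_region_variant` covers
  exonic positions 1–3 bp or intronic positions 3–8 bp from a junction. It
  adds three exonic terms with no A_style equivalent: initiator-codon,
  stop-retained and other-coding (`coding_sequence_variant`).

Both regimes share `flank_bp = 1000` for upstream/downstream (a documented
default of the broad-vocabulary tool; not derivable from the comparison
itself) and `report_policy = "most_severe_only"`: when several transcripts
(or several rules) produce calls, the severity ranking picks one, with ties
broken by lexicographic transcript id for determinism.

## Coding classification

For a variant inside the CDS the engine rebuilds the spliced coding
sequence (reverse-complemented for minus-strand transcripts), applies the
variant, re-translates, and compares proteins:

* protein and stop position unchanged → synonymous; if the variant overlaps
  the stop codon, V_style reports `stop_retained_variant` (the
  **stop-retained** rule: an insertion inside `TGA` that leaves the first
  three bases a stop codon is synonymous, not frameshift, not stop-loss);
* length change not a multiple of 3 → frameshift, unless the stop-scan is
  active and the shifted frame contains a premature stop (first stop
  strictly before the final complete codon of the alternate CDS), in which
  case stop-gain;
* SNVs classify by codon comparison: stop→non-stop is stop-loss,
  non-stop→stop is stop-gain, first-codon `ATG` disruption is
  initiator-codon (V_style) or nonsynonymous (A_style, which has no
  initiator term — the structural zero visible in cross-tool tables);
* in-frame indels are inframe insertions/deletions; an in-frame indel
  overlapping the stop codon without retaining it is stop-loss.

The "premature stop anywhere in the re-translated frame" reading of the
stop-scan follows the published description of the broad-vocabulary tool
inspecting the transcript produced by the indel; it is also the definition
a brute-force translation oracle can check directly, which the test suite
does for every designed coding variant via an independent translation route.

## Severity and harmonization

Each vocabulary carries a total severity order (shipped as YAML, user
overridable). Only the block structure is treated as substantive: all LoF
terms above all missense-level terms above synonymous-level above
non-exonic, with stop-gain above frameshift. Any within-block permutation
validates; the shipped order is one possible common-sense choice.

Harmonization deliberately keeps **two** maps:

* the *category map* used for category matching: frameshift, stop-gain,
  stop-loss, donor/acceptor and the broad splicing term are `LOF`;
  `splice_region_variant` and initiator-codon sit at `MISSENSE` level;
  stop-retained and other-coding at `SYNONYMOUS_OTHER`;
* the *rollup grouping* used for report rows, in which **all** splicing
  subterms are tabulated under LoF — because the broad vocabulary cannot
  split them, comparison tables keep splicing together.

The distinction is forced by the published tables themselves: their LoF
rollup counts include all splice subterms on the fine-vocabulary side,
while their category definitions place general splice-region variants at
missense level. Keeping one map for each role reproduces both facts
consistently.

Exact matching across vocabularies follows a shipped equivalence map; the
broad `splicing` term is exact-equivalent to all three fine splice terms.
Exact matches always count as category matches in the report accounting, so
`exact ⇒ category` holds by construction even for pairs (like
splicing/splice-region) whose category-map labels differ.

## Concordance accounting

`build_comparison()` full-outer-joins two most-severe runs on the variant
key, with an explicit `absent` marker. `summarize_concordance()` then emits:

* **fine rows** per equivalence family (per term, when the two runs share a
  vocabulary): `match` = both runs report the family and the pair is exact;
  `union = count_a + count_b − match`;
* **rollup rows** (`LOF_total`, `MISSENSE_total`,
  `SYNONYMOUS_OTHER_total`): counts by rollup group; the category-match
  column counts records with both terms in the row's group;
  `union = count_a + count_b − category_match` for cross-vocabulary runs
  (− exact match otherwise);
* **combined rollups** (`ALL_LOF_AND_MISSENSE`, `ALL_EXONIC`) as sums of
  their member group rows, and an **ALL** row whose union is the number of
  compared variants (both runs annotate every variant, so the subtraction
  identity deliberately does not apply there).

These conventions were derived by requiring every arithmetic identity in
the published summary tables to hold; the shipped transcriptions of those
tables are revalidated cell by cell by `validate_printed_tables()` in the
test suite and the acceptance script. Rates are stored at full precision
and *presented* rounded half-up to 2 decimal places; a zero denominator
prints as `-`. Cross-tabulations are normalized as `log10(count + 1)`
followed by per-row (or per-column) centring and scaling with the
population standard deviation (divide by *n*; the published description
does not specify *n* versus *n−1*, so the simpler convention is used and
tested); zero-variance axes map to zeros.

## The synthetic-data generator

`simulate_genome_and_transcripts()` draws, from one seed, a single-
chromosome genome of about 90 kb: 20 shared genes (about 15% non-coding,
alternating strands), each with 2–4 exons, 50–90 codon CDSs with an `ATG`
start, internal codons free of stops and an in-frame terminal stop, 12–60 bp
UTRs, 150–400 bp introns, and 2.2–3 kb intergenic gaps. About 30% of shared
coding genes carry a second isoform extending the final exon's 3'UTR
(present in both sets, so it never perturbs designed truths). Set B adds
25% extra whole genes placed inside gaps wide enough (> 2 × the 1 kb flank)
that they are intergenic under set A — the superset structure behind the
transcript-set asymmetry. These sizes are the package's reference study
conditions: large enough that every designed class has many candidate
sites, small enough that the whole suite re-simulates in seconds.

`simulate_variants()` places 13 variants in each of 16 designed classes
(208 in total) by deterministic scanning — candidate positions are tried in
a fixed order and the first feasible one is taken, so generation is
byte-reproducible without rejection sampling. Placement enforces the
conditions that make each truth unambiguous: coding placements keep > 8 bp
from junctions (outside every splicing definition), frameshift placements
verify the shifted frame is premature-stop-free (and stop-gain-via-indel
placements the opposite) by construction-time translation, indel placements
reject candidates that left-alignment would move (or, for stop-retained
insertions, move out of the CDS — left-alignment through a homopolymer can
otherwise relocate an insertion from a minus-strand stop codon into the
UTR, a genuine representational subtlety the generator must respect).

What the generator does **not** emulate: realistic human gene-structure
statistics, sequence composition (uniform A/C/G/T, no N in truth fixtures —
N handling is tested separately), overlapping or nested genes (tool
behaviour there is unspecified, so they are excluded from truth-bearing
fixtures and covered only by crash-safety), allele-frequency structure, and
the 80-million-variant scale of production studies. Passing tests therefore
demonstrate that the definitional rules are implemented exactly, not that
any particular real-data concordance number would be reproduced.

## The discordance scenario

`make_discordance_scenario()` adds one missense and one stop-gain variant
inside each set-B-only gene. Under set A these are intergenic; under set B
they are exonic. With both sides annotated under one regime, the exonic
overall match rate has the closed form
`100 · n_shared_exonic / (n_shared_exonic + n_B_only)` — with the default
mix, `100 · 156/166 ≈ 93.98%` — and the report must reproduce it exactly,
while set B's LoF+missense count exceeds set A's by exactly the number of
B-only variants. This is the published transcript-set asymmetry mechanism
(a superset of transcripts can only increase the severity of a most-severe
report) reproduced at desk scale.

## Numerical and degenerate-input choices

* Rounding: half-up at 2 dp for presentation only (`round_half_up()`).
* Ties in severity: lexicographic transcript id.
* Junction-spanning variants: A_style classifies them `splicing` (they
  always touch the intronic window); V_style emits the splice-site call
  plus a `coding_sequence_variant`/location call and lets severity
  selection resolve — the published tools demonstrably disagree here, so
  the choice is exposed rather than hidden.
* Variants overlapping CDS but not contained in it (UTR-boundary indels)
  get a coarse length-based call flagged `low_confidence`.
* Single-exon transcripts have no splice sites; transcripts with no
  overlapping variant and no flank hit produce `intergenic`.
* The published supplementary severity table is not transcribed here; only
  the orderings stated in the main text are treated as constraints, and the
  shipped ranking documents itself as one possible prioritisation.

## Problem sizes used by tests and the acceptance script

The default test and acceptance runs use the reference conditions above
(208 designed variants over ~25 transcripts, plus 10 B-only scenario
variants; ~1,000-position index oracles; full-position splicing scans over
a hand-built two-exon fixture). A full suite runs in roughly two minutes on
one CPU.

## Known limitations

Fidelity to the exact corner-case behaviour of any real annotation tool is
explicitly out of scope (their algorithms are not fully documented); the
regimes implement published definitions. Phase is unused. No
nonsense-mediated-decay prediction, no protein-impact scores, no
multi-gene-overlap truths, and no attempt to reproduce production-scale
variant counts, which are not publicly deposited.
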