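---
title: "Methods: small-RNA tag processing and miRNA inference in apomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA tag processing and miRNA inference in apomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apomir)
```

apomir implements a complete small-RNA-sequencing analysis for contrasting
genotypes — here framed as an apomictic versus a sexual plant cultivar, the
setting the defaults emulate, but nothing in the code is specific to that
system. This vignette is the package's own account of the methods: the model
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical choices that make results reproducible.

## The pipeline at a glance

Raw reads from four libraries (2 genotypes × 2 biological replicates) flow
through eight stages:

1. **Trimming** (`trim_reads()`): 3' adapter removal, quality tail removal,
   17–33 nt length window.
2. **Collapsing** (`collapse_tags()`): one *sequence tag* per distinct
   insert per library, labelled `LIBRARY_count`.
3. **Minimum count** (`filter_min_count()`): tags with per-library count
   below 3 are discarded, the conventional depth filter for sRNA libraries.
4. **Depuration** (`depure()`): sequential subtraction of tags matching
   mitochondrial, chloroplast and ncRNA-family references.
5. **Conserved annotation** (`classify_conserved()`,
   `summarize_families()`, `consensus_name()`): homology to a mature +
   hairpin miRNA database, family aggregation, consensus naming.
6. **Novel discovery** (`discover_novel()`, `name_novel()`): exact
   transcriptome mapping, degradation filtering by coverage breadth,
   candidate loci.
7. **Target scoring** (`scan_transcript()`, `predict_targets()`):
   plant-style complementarity scoring with an expectation penalty.
8. **Differential expression** (`de_test()`) and **qPCR validation**
   (`qpcr_relative()`, `qpcr_compare()`).

`run_pipeline()` orchestrates stages 1–8 and writes one TSV report per
stage; every report carries a header line with the thresholds used, and the
same configuration and seed reproduce reports byte-identically.

## Read cleanup

The adapter rule is the leftmost exact suffix–prefix overlap of at least 8
nt between the read and the 3' adapter; the read is cut at the first
position where its suffix matches an adapter prefix. Exact matching is the
deliberate default — small-RNA adapters are ligated, not sequenced through
errors at any appreciable rate at these read lengths — and the overlap
minimum prevents spurious 1–3 nt "adapters" from truncating real inserts.
Trimming is idempotent by construction: the kept insert precedes the
leftmost match, so a second pass finds nothing.

Quality trimming removes trailing bases below Q20 (configurable). Inserts
outside 17–33 nt are discarded, as are inserts containing N (an N cannot be
matched ungapped without ambiguity rules). U and T are treated as the same
symbol throughout; the internal canonical alphabet is DNA.

The minimum tag count is applied **per library** (each library is collapsed
separately), with the boundary kept inclusive: a count of exactly 3
survives.

## Depuration

Contamination subtraction uses end-to-end ungapped matching at 0 mismatches
by default — the zero-mismatch setting conventionally used for
contamination filters — in the fixed order mitochondria → chloroplast →
ncRNA, so each stage's percentages nest relative to that stage's input.
Organellar DNA is matched on both strands; ncRNA references, being
RNA-derived, on the forward strand only (both policies configurable per
reference set). Correctness is defined by the exhaustive sliding-window
scan; the implementation (a substring hash for the exact case, pattern
matching for the mismatch case) is tested against a brute-force oracle at
every radius.

## Conserved miRNA annotation

A tag is *conserved* when it has an ungapped local alignment to a mature or
hairpin database entry with ≤ 2 substitutions and coverage ≥ 90%. Coverage
is defined as aligned length over **tag** length — defining it over the
database entry would make every tag fail against hairpins — and tags may
overhang either end of an entry. Multi-hit tags are assigned to one family
by a deterministic best-hit rule: mature entries take precedence over
hairpin-only hits, then fewest mismatches, longest alignment,
lexicographically smallest identifier. The conserved fraction is reported
both over unique tags and over total read counts, the two denominators used
in sRNA studies.

Consensus naming aligns each family's member tags at their best-hit offsets
on a common database anchor and takes the positional majority (ties broken
toward the more abundant member, then alphabetically). Clusters with
identical consensus merge; survivors receive letter suffixes in descending
count order, giving names like `ecu-miR2275a`.

## Novel miRNA discovery and the degradation filter

Non-conserved depured tags are mapped to the reference transcriptome
exactly (no mismatches, no gaps, forward strand — transcripts are oriented
mRNA), multi-mapping retained. Each mapped transcript gets a coverage
profile; depth is weighted by read counts by default because degradation
signal is abundance-driven (unique-tag weighting is available).

The classical call "reads targeting across the transcript's entire length
are degradation products" was a manual, visual judgement; apomir
operationalizes it as: a transcript is degradation when coverage breadth
≥ 0.8, **or** it carries more than 2 merged loci, **or** any locus is wider
than 30 nt. Runs of covered positions separated by ≤ 5 uncovered bases
merge into one locus. All four thresholds are configurable and recorded in
the output metadata. The call is monotone in breadth — adding covering tags
can never turn a degradation call into a candidate — and invariant under
tag input order. Each locus of a candidate transcript yields one candidate,
represented by its highest-count tag; candidates inherit a family name from
a relaxed homology search (≤ 5 mismatches, coverage ≥ 0.7) or fall back to
serial `ecu-novel-N` names.

Candidates are deliberately **not** screened for hairpin-precursor folding:
the discovery route here identifies novel miRNAs through their targets, and
secondary-structure validation is out of scope.

## Target scoring

The duplex scorer follows the plant target-prediction convention: the miRNA
(5'→3') is aligned antiparallel to a transcript window and accumulates an
*expectation* penalty

| pair | penalty |
|------|---------|
| Watson–Crick | 0 |
| G:U wobble | 0.5 |
| mismatch | 1.0 |
| bulged miRNA base | 2.0 |

with penalties **doubled** at seed positions 2–13. A duplex is rejected if
any true mismatch falls in the seed (wobbles are penalized but allowed — a
necessity, since the central window 9–11 sits inside the seed yet must be
able to carry the non-WC pair that switches the mode to translational
inhibition), if the alignment would need a bulge on the target side, or if
the expectation exceeds 2.5. At most one miRNA-side bulge is permitted, and
bulged terminal bases are disallowed. Accessibility filtering (UPE ≤ 20
over the site plus 17 nt upstream / 13 nt downstream flanks) is a pluggable
backend; the package ships `upe_stub()`, a deterministic
sequence-composition heuristic (0.3 per G/C, 0.1 per A/T), and any function
from site-plus-flank sequence to energy — e.g. a partition-function folder —
can be supplied instead.

`scan_transcript()` is *defined* as exhaustive window enumeration (window
widths equal to the miRNA length and one less); the implementation first
screens offsets with a vectorized lower bound on the number of non-WC pairs
and then re-scores every surviving offset exactly, so the screen can never
change a result — a property the test suite checks against a brute-force
enumerator. Overlapping accepted sites are reduced greedily to
local-minimum-expectation sites (ties broken by position), which keeps all
non-overlapping accepted sites per miRNA–transcript pair.

One scoring property worth stating precisely: expectation is *not*
invariant under reverse-complementing both the miRNA and the window. It
cannot be — penalties are position-dependent (the seed doubling) and G:U
wobbles are not complement-symmetric pairs. The invariance holds exactly
for perfect-complement duplexes, and that is what the tests assert.

## Differential expression

The paper-scale tool for this job is edgeR; apomir instead ships a
self-contained, documented approximation: an **exact conditional
negative-binomial test**. Libraries are scaled to the geometric-mean
library size and summed within genotype (a deterministic simplification of
edgeR's quantile adjustment); conditional on the total $n = y_A + y_B$, the
p-value is the probability of every split as or less likely than the
observed one under NB sums with common dispersion $\varphi$ (sums of $k$
i.i.d. NB variables enter as size $k/\varphi$). At $\varphi = 0$ this is
the exact conditional binomial test, and ties in outcome probability are
included in the rejection sum — the conservative choice. Numerical identity
with edgeR is neither claimed nor tested.

The common dispersion is estimated by moments, pooled over within-genotype
replicates: $\hat\varphi = \sum(s^2 - \bar m)/\sum(\bar m^2 - s^2/k)$,
floored at 0; the $s^2/k$ term debiases $\bar m^2$, and seeded simulations
verify recovery ($\varphi = 0.2$ recovered within $[0.1, 0.3]$ at 2000
tags; Poisson data within $\pm 0.05$ of 0). p-values are Benjamini–Hochberg
adjusted, and calls use **strict** thresholds: adjusted $p < 0.01$ and
$|\log_2 FC| > 2$ — a tag at exactly $\log_2 FC = 2$ is not called. Fold
changes add a pseudo-count of 0.5 per side so genotype-exclusive tags stay
finite.

One pipeline-level subtlety the synthetic experiment exposed: testing the
*filtered* tag table directly fabricates differential expression. A tag
kept in one library (count ≥ 3) may sit just below the minimum count in
another; zeroing those sub-threshold counts turns ordinary sampling noise
into an apparently genotype-exclusive pattern that an exact test finds
highly significant. `run_pipeline()` therefore tests the full clean counts
of every depured tag while keeping the depured totals as library sizes.

## qPCR quantification

`qpcr_relative()` implements 2^-ddCt: technical replicates average per
biological sample, dCt = Ct(target) − Ct(reference), ddCt subtracts the
calibrator genotype's mean dCt, and relative expression is $2^{-\Delta\Delta
C_t}$ with amplification efficiency fixed at 2.0 (instrument-software
efficiency corrections are out of scope). Genotypes are compared with
Student's equal-variance two-sided t-test at $p < 0.05$; Welch's variant is
a flag.

## The synthetic experiment

`sim_config()` / `sim_references()` / `sim_libraries()` generate the whole
study in silico with complete per-read truth, and the defaults *are* the
study conditions every recovery test runs under:

* four libraries (`O2P1`, `O2P2` sexual; `T3P1`, `T3P2` apomictic), 20,000
  reads each — large enough that every stage sees realistic tag-count
  distributions, small enough that the full test suite and the acceptance
  script run in minutes;
* insert lengths bimodal at 21 and 24 nt (weights 0.55/0.45 with ±1–2 nt
  jitter on a quarter of the background), the canonical plant sRNA
  signature;
* class mix per library: ~0.5% organellar, 4.5% ncRNA, 0.4%
  conserved-miRNA reads (split over 0–3-mismatch variants of planted mature
  miRNAs, weights 0.55/0.25/0.15/0.05, so the 2-mismatch acceptance
  boundary and the 3-mismatch rejection are both exercised), 20%
  degradation windows (17–30 nt, uniform starts, tiling six designated
  transcripts), 0.6% planted novel loci (exact 21-nt transcript
  substrings), and a random background whose singleton-heavy tail makes
  roughly a sixth of reads fall under the minimum count — the discard
  magnitude real libraries show;
* planted differential expression: |log2FC| = 3 multipliers on two novel
  loci and ten abundant spike tags, balanced across genotypes, with ≥ 30
  expected reads per tag on the low side;
* three transcripts carry a perfect complementary site for a planted
  mature miRNA, giving the target scanner known positives;
* every read is insert + 3' adapter (+ constant filler) truncated to a
  50-nt instrument read, so every insert carries adapter and the trimmer is
  always exercised. The adapter default is the standard Illumina small-RNA
  3' adapter, and tests pass it explicitly.

Sampling is one multinomial draw per library over the class-weighted tag
pool (fold-change multipliers applied to the genotype's weights), the
simplest model consistent with count data. The generator deliberately does
**not** emulate sequencing errors beyond this (no substitution noise, no
quality-score realism, no PCR duplicates), so passing recovery tests show
the pipeline's logic is correct under clean signal — they do not show
robustness to base-calling error, which real data would add on top.
Everything is a deterministic function of the seed; identical
configurations give byte-identical FASTQ and truth files.

## Problem sizes and numerical choices

The default test and acceptance runs use 4 × 20,000 reads, a 60-transcript
transcriptome (350–700 nt), 5 planted miRNA families, ~2-kb organellar
genomes and 20 ncRNA references — sizes chosen so the complete suite runs
in about a minute while every stage still sees non-trivial input. Oracle
equivalence runs on 500+ random instances with references up to 5 kb.
Percentages in reports are rounded to 2 decimals but always recomputable
from the printed counts; p-value tie comparisons use a relative tolerance
of 1e-12; the conditional-test enumeration is linear in the conditioned
total, which stays in the hundreds at these depths.

## Command-line interface

The exported functions are the primary interface; a thin Rscript
(`inst/cli/apomir`) wraps the three entry points a shell user would want —
`simulate`, `run` (YAML config), and `qpcr` — without adding logic of its
own.

## Known limitations

* Degradation thresholds formalize what was historically a visual call;
  the defaults are sensible but not canonical, which is why they are
  configurable and echoed in output metadata.
* The exact NB test approximates, but is not, edgeR's pipeline (no
  tagwise dispersion shrinkage, no TMM normalization).
* `upe_stub()` is a composition heuristic, not a thermodynamic model;
  accessibility filtering is only as good as the supplied backend.
* Novel candidates are not validated by hairpin folding or phasing
  analysis, and conserved annotation inherits whatever redundancy the
  miRNA database contains.
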