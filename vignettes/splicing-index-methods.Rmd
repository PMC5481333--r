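---
title: "Junction-based differential splicing with the splicing index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-based differential splicing with the splicing index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceIndex)
```

## The problem and the model

Bulk RNA-Seq of a treatment time course — e.g. a breast-cancer cell line
under a normoxia control, an acute (hours) and a chronic (a day) hypoxia
phase, sequenced with one library per condition — shows splicing changes
that cannot be modelled with replicate-aware tools. spliceIndex implements
the count-ratio approach suited to that design: all evidence is reduced to
junction-proximal read counts, effects are expressed as a difference of
ratios, and inference is exact and per event.

Every read is assigned to exactly one of three groups, in order of evidence
strength: exon–exon junction reads (spliced alignments with sufficient
anchors), exon–intron boundary reads (contiguous alignments bridging an
annotated border), and intronic reads. Gap evidence takes precedence: a read
with a well-anchored splice gap is a junction read even if it also touches
an intron. Intronic reads never select candidates; they only quantify
retention coverage and depth, because intronic coverage alone cannot
distinguish retention from unannotated transcription.

For an event with variant support $a$ and canonical support $b$ the
splicing index is

$$ SI = \frac{a}{a+b} \in [0,1], $$

the fraction of informative molecules carrying the variant form, and the
effect between a treated and the control condition is
$\Delta SI = SI_t - SI_c \in [-1, 1]$. The per-type reduction of evidence to
$(a, b)$ is deliberately symmetric:

* **Intron retention** — $a$ is the *mean* of the two boundary counts
  (averaging rather than summing avoids giving retention twice the weight of
  a single spliced read, since one retained molecule can produce two
  boundary reads); $b$ is the spliced-junction count.
* **Exon skipping** — $a$ is the skip-junction count; $b$ the mean of the
  two inclusion junctions, again so that one included molecule is not
  counted twice.
* **Alternative 5′/3′ splice sites** — the two competing junction counts
  directly.
* **Alternative first exon** — this donor's junction count against the sum
  of the gene's other first-exon donors (the natural "all other starts"
  denominator).

Fractional means are rounded half away from zero so the downstream exact
test sees integers.

## Inference and gates

With a single library per condition the only replication is the read count
itself, so each event is tested with a two-sided Fisher exact test on the
2×2 table of (variant, canonical) × (treated, control). The test identity is
this package's explicit choice: counts are integers, depths are modest, and
exactness matters at low support. q-values are Benjamini–Hochberg, pooled
across all testable events of the five classes within one comparison
(acute-vs-control and chronic-vs-control are adjusted independently, one FDR
per phase). Both gates are applied jointly after adjustment: an event is
significant iff $|\Delta SI| \ge 0.15$ and $q < 0.01$. Whether the effect
gate should be applied before or after ranking is genuinely open; applying
the FDR over the full testable pool and gating afterwards is the
conservative reading and keeps the pool definition independent of the effect
size.

Events whose informative total $a+b$ falls below `min_support` (default 10)
in either condition have an undefined SI and are excluded from the pool
rather than treated as zeros — a ratio of 2/3 reads is noise, not evidence.

Tunable parameters, defaults, and why:

| parameter | default | role |
|---|---|---|
| `min_overhang` | 6 nt | anchor on each side of a gap/border; short anchors are alignment-error-prone |
| `min_support` | 10 reads | minimum informative depth per condition for a defined SI |
| `dsi_min` | 0.15 | effect gate on the SI difference |
| `fdr_max` | 0.01 | BH q-value gate, per comparison |
| `fc_min` | 1.5 | expression fold gate (CPM ratio, pseudocount 0.5) |
| `max_middle_exon` | 10 kb | cassette-exon length guard against chimera-like triples |
| mapping quality | ≥ 1 | drops multimappers under the MAPQ-0 convention |

## Design choices in detection

* **Junction identity is the intron interval** (chrom, start, end, strand of
  the gap), matching how spliced aligners report gaps; all internal
  coordinates are 0-based half-open, converted once at the GTF/SAM boundary.
* **Novelty** is membership of the event's defining keys in the supplied
  annotation. Intron retention is special: the retention *state* is known
  only if some annotated transcript contains an exon spanning the whole
  intron. An annotated intron with no annotated retained form still yields a
  novel retention event — which is why most retention events in a typical
  annotation are novel.
* **Canonical orientation for competing splice sites**: the annotated
  junction; if both or neither are annotated, the higher control count,
  ties to the longer intron. When both forms are annotated and roughly
  balanced the orientation can flip between datasets; `evaluate_calls()`
  therefore matches ground truth under both orientations with the sign
  reversed.
* **First-exon donors vs A5SS**: two transcription start sites produce
  junction pairs sharing an acceptor, indistinguishable in junction space
  from an alternative donor. Pairs in which both junctions are annotated
  first-exon donors of one gene — or one is and the other's donor end lies
  outside every annotated exon of that gene — are classified AFE and
  excluded from A5SS, so the same evidence is not reported twice under two
  types.
* **One event per candidate**: an exon-skipping triple counts once, each
  competing first-exon donor yields its own event (a two-donor gene whose
  usage shifts thus contributes two complementary significant events), and
  summaries count events, not splice sites.
* Genes overlapping on opposite strands stay separate; events or junctions
  matching more than one gene are flagged ambiguous and excluded from
  gene-level summaries. Strand-unknown junctions take the strand of the
  unique overlapping gene and are excluded from AFE detection when
  unresolvable.

## Expression calls

Gene counts use exonic-union overlap with an ambiguous-read drop; values are
CPM with a 0.5 pseudocount for stability at zero, and the call is the fold
gate alone, inclusive at 1.5 and 1/1.5. No p-value is attached: with n = 1
per condition a dispersion model would be fiction, so "significant" for
expression means exactly "≥ 1.5-fold". This is a deliberate divergence from
wording that implies a test; it is the only call the design supports.
Overlap accounting (phase Venn cells, expression-versus-splicing overlap)
uses exact set partitions; fractions are reported over the union of the
input sets, which is the denominator that reproduces ratios like 39/2518
printed in studies of this kind.

## What the simulator emulates — and what it does not

The generator builds multi-isoform gene models on synthetic chromosomes,
plants a configurable plan of true events (type, true ΔSI, affected phase,
baseline SI), and draws counts per condition as Poisson (optionally negative
binomial, dispersion 0.05) around `depth × SI` and `depth × (1 − SI)`.
Retention boundary reads are split binomially between the two borders;
intronic depth scales with the retention level; expression counts are
log-normal across genes with planned fold changes. SAM output realises every
count as a literal read with fixed geometry (80 nt reads, 40 nt anchors —
single-end is sufficient for junction counting), so extraction must
reproduce the tables *exactly*, read for read.

Defaults are the desk-scale study conditions: 200 genes, three conditions
(control first), 60 events across the five classes with true ΔSI in
{0, ±0.2, ±0.4} and phases cycling both/acute/chronic, 200 informative reads
per event, constitutive junctions at depth 50, and half of the planned
events left out of the emitted GTF. Baselines are 0.3 for non-negative
effects and 0.5 for negative ones so that `baseline + ΔSI` stays in [0, 1].

What passing tests on this generator shows: the arithmetic chain from CIGAR
to significance call is exact; the test is calibrated under the generator's
null; effects ≥ 0.3 at realistic depth are recovered with the stated
sensitivity. What it does not show: robustness to alignment artefacts,
sequence-dependent coverage bias, fragment-length effects, overdispersion
beyond the NB option, or degraded annotations — the generator has no
sequence level at all. Numbers from genome-scale data (thousands of
significant events from ~180 M-read libraries) are not reproducible at this
scale and are only checked as summary arithmetic.

Problem sizes used by the test-suite and acceptance runs, chosen as
desk-scale defaults: 2000 null retention events at depth 100 for
calibration; 50 events (ten per class) with |ΔSI| ∈ {0.3, 0.4} at depth 200
for recovery; the 200-gene default fixture (three samples, ~90 k reads per
sample) for the SAM round-trip; a 40-gene fixture for the byte-level
determinism check.

## Numerical details and degenerate inputs

Fisher p-values use point-probability summation (a zero row or column margin
gives p = 1); BH q-values are capped at 1 and order-preserving. SI bounds
[0, 1] and ΔSI bounds [−1, 1] hold by construction. An event with zero
support everywhere keeps an undefined SI rather than 0/0. Duplicate
identifiers in overlap sets are deduplicated with a warning. Empty inputs
(no reads, empty GTF, empty junction files) return empty, well-typed tables.
All outputs are deterministically ordered so identical inputs are
byte-identical outputs; the run manifest records parameters and input
checksums, never timestamps.

## Known limitations

Mates of a pair are treated as independent reads; mutually exclusive exons,
alternative last exons and complex events are outside the five-class
taxonomy; no transcript-level quantification or ORF/NMD consequence
annotation is attempted; novelty is relative to whatever GTF is supplied —
no fixed annotation release is assumed. Collateral candidates are expected
and harmless: a true skipping event, for example, also yields competing
splice-site candidates built from its junctions, which simply track the same
underlying change.
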