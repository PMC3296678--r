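---
title: "Methods: inferring intron gain and loss and attributing mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring intron gain and loss and attributing mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures, the tunable parameters and why their defaults are what they
are, what the bundled simulator does and does not emulate, and the
numerical choices a maintainer would want spelled out.

## The inference model

The package treats intron presence at a homologous gene position as a
binary character evolving on a rooted species tree under Dollo's
assumption: the derived state (presence) arises exactly once and may be
lost repeatedly. The steps from raw genomes to event calls are:

**Orthology by reciprocal best hits.** Coding sequences are compared
all-against-all with affine-gap Smith–Waterman (match +5, mismatch −4,
gap open 16, extension 8). A cross-species pair is kept when each gene is
the other's unique best-scoring hit and both directions satisfy e ≤
10⁻³⁰, identity ≥ 70% and query coverage ≥ 80%; kept pairs are joined
into connected components and any component containing two genes from one
species is discarded as unresolved paralogy. The designated outgroup is
attached per group at relaxed thresholds (60/60), since it diverged much
earlier and serves only to polarize root states. A strided shared k-mer
prescreen (k = 12) skips sequence pairs that cannot approach these
thresholds; it does not change the result, only the running time.

**Marked alignment.** Every CDS receives a block of thirty `X`
characters at each intron position; groups are aligned progressively
(UPGMA guide tree on 6-mer distances, profile–profile merges). `X`
scores +5 against `X`, −20 against nucleotides and 0 against gaps, so
homologous marker blocks stack into shared columns while never absorbing
coding sequence. Transitions are penalised −3 versus −4 for
transversions. Gap opening costs 40, extension 0, plus a surcharge of 10
within ten columns of an existing gap — the high-open/zero-extension
spirit of classic CDS aligners, re-expressed on this package's
substitution scale (see *Numerical choices*).

**Columns, flanks, matrix.** Marker blocks whose start columns lie
within ten columns of each other merge into one intron-position class
(ascending start, a gap larger than the window opens a new class; ties
resolve to the leftmost). Classes are screened by a flank-identity
filter: over the fifteen nearest marker-free, comparable columns on each
side, mean pairwise identity of non-gap positions must reach 0.8 on both
sides, with fewer than five comparable columns on a side dropping the
class outright. This automates what would otherwise be manual alignment
inspection; the window and threshold are configuration keys
(`flank_window`, `flank_min_identity`). Surviving classes become rows of
a presence/absence matrix (1/0, with NA for species absent from the
group; missing data constrains nothing and is never read as absence).

**Dollo calling and polarization.** A non-missing outgroup state fixes
the root state of a row. Without it, a row is decided from ingroup states
alone only when the two candidate reconstructions — gain inside the
ingroup at the MRCA of present species (cost 1 + minimal losses below)
versus presence at the ingroup root (cost: minimal losses from the root)
— differ in total cost; rows whose costs tie are excluded, mirroring the
exclusion of outgroup-less alignments in the study design this package
follows. Given the root state, the intron gains at the MRCA of the
present species (or is ancestral), and losses are the minimal set of
edges into maximal all-absent subtrees.

**Annotation-error quality controls.** Gains confined to one species are
rejected when the intron has length 3n and no premature stop codon in the
reading frame fixed by its CDS offset (such "introns", if retained in the
transcript, would escape nonsense-mediated decay — the classic footprint
of a gene-model error), or when its terminal dinucleotides are not GT–AG
(the canonical set is configurable). Ancestral gains and all losses are
exempt: their support comes from multiple genomes.

## Mechanism attribution

Accepted gains are scanned against the transposon library and the
mitochondrial genome on both strands; a hit needs query coverage ≥ 90%
and e ≤ 0.1. Transposon hits trigger a target-site-duplication scan: the
longest 4–15-mer opening the intron that recurs within fifteen positions
of the 3′ junction with at most one mismatch. Mitochondrial hits are
confirmed against a shuffle null: the intron is shuffled 1000 times
(mononucleotide permutation; dinucleotide tiling available via
`shuffle_mode`) and realigned to the matched segment, with
p = (1 + #{shuffled ≥ observed})/(N + 1). Losses are examined for NHEJ
residues: alignment columns near the lost position where the losing
species retains sequence against gaps in every intron-bearing member are
extracted and aligned to the conserved orthologous intron of the closest
(minimal patristic distance, ties alphabetical) species; e ≤ 0.1 marks an
imprecise NHEJ loss, and junction direct repeats (≥ 5 bp within 30-nt
windows) are reported alongside. Column-class pairs 11–100 columns apart
with complementary membership are candidate intron slides; sequence
similarity between the two introns at e ≤ 0.1 separates sliding from
coincidental loss-plus-gain.

Three bias statistics address transcript-mediated mechanisms: a
Kolmogorov–Smirnov test of event positions (CDS offset over CDS length of
the nearest intron-bearing member) against Uniform(0,1); a Pearson
chi-square (no continuity correction) of germline-expression counts among
event genes versus the background; and the adjacent-loss excess, a
goodness-of-fit chi-square of the observed number of same-branch losses
at consecutive intron positions against its within-gene permutation
expectation (default 10,000 permutations).

## The simulator: what it emulates, and what it does not

`evolve_family()` forward-simulates gene families over a random
coalescent ingroup tree (unit depth, node-labelled) with a distant
outgroup on a branch of length 1.0. Defaults describe the study setting
the package targets: 8 ingroup species, 50 families, CDS of 150–450
codons, a Poisson mean of 4 ancestral introns per gene at AT fraction
0.6 with lengths 60 + geometric (mean 400), gain/loss rates 0.20/0.30
events per gene per unit branch length (roughly 1.3 events per family,
biased toward losses as observed in comparable clades), gain mechanisms
¼ transposon, ¼ mitochondrial filler, ½ plain insertion, losses 80%
precise / 20% imprecise NHEJ, and germline flags drawn with probability
0.68 for event families versus 0.52 background (matching the published
contingency tables these statistics are validated against).

Mechanism fidelity is taken seriously where the scans need it:
transposon insertions duplicate a GT-initiated target site of 8 nt so
the copy doubles as the donor site and the coding sequence is unchanged;
mitochondrial filler is a verbatim slice (mean 113 nt) of a simulated
16-kb organelle genome at 80% AT, optionally entering at a microhomology
so its 5′ end duplicates the upstream exon terminus (probability 0.3,
repeat length 5–7); imprecise NHEJ losses leave 12–24 nt of intron
terminus at the junction, in frame and chosen to keep the CDS an open
reading frame; annotation errors are injected at leaves as 3n, stop-free,
canonically-ended pseudo-introns. Substitutions are applied after events
and never touch splice dinucleotides. Every event is accepted only if
its column's final leaf pattern remains Dollo-consistent with the truth
log — the generator-side counterpart of "no homoplasy at one column",
without which exact recovery would be unattainable for *any* inference
method (a gain whose child subtree is later wholly lost is provably
reinterpreted by parsimony). Gains also keep 60 nt of distance from
every intron position ever used in the family (tracked in root
coordinates across NHEJ-induced frame shifts), so independent events
cannot collide into one alignment column.

What the simulator does *not* emulate: alternative isoforms, splice-site
degeneration, paralogy and gene duplication, rate heterogeneity across
lineages or genes, indel noise in exons beyond NHEJ remnants, and
sequencing/assembly artifacts other than the stylised annotation errors.
Passing the recovery tests therefore demonstrates correctness of the
inference machinery under the stated model, not robustness of the method
to everything real annotation pipelines produce.

## Numerical choices

**Gap costs and e-values.** With gap extension at −2 (a common default
elsewhere), random local-alignment scores under this match/mismatch pair
grow nearly linearly with sequence length — the alignment leaves the
logarithmic (Gumbel) regime, and no single Karlin–Altschul (λ, K)
describes all the sizes the pipeline scans: any λ permissive enough to
accept true orthologs at e ≤ 10⁻³⁰ assigns e ≈ 10⁻⁷ to random 400-nt
intron pairs, destroying the sliding and mitochondrial scans. The default
gap costs (open 16, extend 8) keep the null in the Gumbel regime;
`calibrate_evalue()` then fits λ by pooled method-of-moments over a grid
of query (24–400 nt) × target (400–16,000 nt) lengths and takes K from
the most liberal grid cell, so e-values stay conservative in every
regime. The shipped constants are λ = 0.19504, K = 0.57195; rerunning the
calibration reproduces them.

**Marker stacking radius.** An `X`/`X` reward of r per column lets the
aligner coalesce two marker blocks up to ≈ 30·r / match-score nucleotides
apart regardless of true homology (the stacking reward beats the exon
match opportunity cost). At r = +10 that radius is ~60 nt, which would
contradict the 10-column merge window and absorb genuine intron slides;
at the default r = +5 the radius is ~30 nt, below both the simulator's
60-nt position spacing and biologically sensible inter-intron distances.
Simulated slides move 40–55 nt for the same reason: far enough to resist
coalescence, close enough for the sliding scan's 100-column ceiling.

**MSA gap open of 40.** On the +5/−4 substitution scale, an opening cost
of 80 exceeds the cost of absorbing a 12-nt insertion as mismatches
(≈ 81) whenever an adjacent marker gap lets the alignment re-synchronise
for free, so optimal alignments would smear NHEJ junction remnants into
mismatch columns and the flank filter would (correctly, but fatally)
discard the column. Opening at 40 keeps real insertions gapped while
still far above any plausible run of substitutions.

**NHEJ remnant length.** Junction residues shorter than ~10 nt cannot
reach e ≤ 0.1 against any donor intron (a perfect 9-mer scores 45), so
similarity-based attribution — the only method available — is blind to
them. The simulator draws remnants of 12–24 nt, the shortest length class
that carries mechanistic signal. Even there the limit is visible: a
12-nt remnant against a multi-kilobase donor intron sits almost exactly
at e = 0.1 (E scales with donor length), so attribution recall for NHEJ
is expected near, not at, 1.0.

**KS p-values.** The asymptotic Kolmogorov tail is computed in-package
from the alternating theta series to machine precision;
`stats::ks.test()`'s asymptotic path truncates the same series at an
absolute tolerance of 10⁻⁶, too coarse for this package's 10⁻¹⁰
cross-validation against the conjugate series representation.
`stats::chisq.test()` (uncorrected) is used as-is for all chi-squares.

**Direct-repeat windows.** Repeats ≥ 5 bp are scanned within 30-nt
windows on each side of each junction. Two random 30-nt windows share a
≥ 5-mer with probability near one half, so the *absolute* flanking rate
is dominated by chance co-occurrence; only comparisons between an event
set and a matched background are meaningful, which is how
`repeat_flanking_rate()` is meant to be used (it carries a companion
chi-square for exactly that purpose). Likewise the TSD scan at its
permissive defaults (4-mers, one mismatch) fires frequently on random
junctions: a detected TSD corroborates a transposon-library hit, it does
not diagnose transposition on its own.

**Tie-breaks and degenerate inputs.** Ambiguity codes never count as
matches anywhere. Score ties for "best hit" disqualify the pair rather
than picking arbitrarily; guide-tree and donor-species ties resolve
alphabetically; marker-block class ties resolve to the leftmost start.
All-N queries yield zero-score hits; empty simulated datasets write and
read back as valid (header-only) files; a gain and a loss of the same
column on the same branch cannot co-occur by construction.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the Dollo sweep over
every rooted binary tree with up to six leaves × all leaf patterns ×
both root states (≈ 128,000 cases), exact recovery and quality-control
rates on a 50-family × 8-taxon zero-divergence simulation with 5%
annotation-error injection, mechanism recall on an equally sized planted
simulation, 500-replicate shuffle-null calibration at query length 60,
and 200 random Smith–Waterman oracle comparisons at lengths up to 60 nt.
These sizes were chosen so each property is exercised at the scale where
its failure modes live (column collisions, outgroup exclusions, long
donor introns) while a full run stays comfortably on a laptop.

## Known limitations

Dollo parsimony cannot see parallel gains at one homologous position
(true homoplasy is folded into a single ancestral gain), and events whose
pattern is reshaped by later events on the same column are recovered as
the parsimony-equivalent set, not the historical one. The outgroup is
assumed structurally static; a loss on the outgroup lineage would
masquerade as an ingroup root-edge gain for any ingroup-based method.
Attribution is conservative by construction: plain insertions carry no
signature and remain unassigned, precise losses cannot be split between
RTMIL and precise genomic deletion at the single-event level (hence the
`precise_or_rtmil` verdict and the reliance on the cohort-level bias
statistics), and sequence divergence will erode transposon, filler and
remnant signatures on real data faster than the zero- and low-divergence
settings exercised here.
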