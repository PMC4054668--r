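---
title: "Pooled miRNA discovery and validation: models and methods"
author: "miRpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled miRNA discovery and validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRpool)
```

## The problem

Mature microRNAs are ~22-nt RNAs excised from precursor stem-loops by
Drosha/DGCR8 and Dicer. Lowly and narrowly expressed miRNA genes escape
single-experiment annotation: in any one library they are indistinguishable
from the sea of degradation fragments. Pooling many independent small
RNA-seq datasets changes the statistics. A genuine miRNA leaves the same
processing signature — an identical 5' end, a star partner with a 2-nt 3'
overhang — in every library that expresses it, while degradation fragments
recur at random positions. `miRpool` implements a discovery pipeline built
on that idea, plus the downstream analytics used to validate candidates:
biogenesis knock-down response, CLIP/CLASH interaction evidence,
evolutionary dating, genomic-source attribution, expression metrics,
capture-bait design and saturation analysis.

## The discovery pipeline

Reads from all datasets are adapter-clipped (primary pass: leftmost exact
match of the adapter's first 8 nt; fallback cascade: the first k adapter
nucleotides against the last k read nucleotides for k = 7 down to 6 by
default — the cascade's lower bound is open in principle and exposed as a
parameter, since shorter suffix matches increasingly clip random sequence),
filtered at 18 nt, and collapsed to unique sequences. Each sequence's
*prevalence* is the number of datasets in which it occurs. The pipeline then:

1. discards sequences with prevalence < 2;
2. maps the rest to the genome, exact matches only, discarding sequences
   with more than 5 genomic loci, and assigns each sequence the weight
   prevalence / n\_mappings;
3. resolves same-strand overlaps greedily by descending weight, so one
   major form survives per locus (ties: higher prevalence, then leftmost
   coordinate, then sequence lexicographic — fully deterministic);
4. removes sequences overlapping annotated miRNA/tRNA/rRNA intervals on
   the same strand (strand-specificity chosen for consistency with step 3);
5. excises each survivor twice — with 10 nt upstream + 70 nt downstream,
   and with 70 + 10 — covering both the 5'-arm and 3'-arm hypotheses;
6. keeps excisions that fold into a single stem-loop with at least 14 of
   the seeding sequence's bases paired to the opposite arm at
   -14 kcal/mol or lower (an explicit, reproducible stand-in for a trained
   hairpin classifier; thresholds configurable);
7. maps all pooled reads back onto each hairpin and scores Dicer
   consistency (below), discarding candidates with more than 10 percent
   inconsistent signal;
8. reports one hairpin per locus, keeping the most prevalent seeding
   sequence at overlaps.

### Dicer consistency

The mature window is anchored at the most abundant read on the hairpin
(pooled copy count; prevalence breaks ties). The star window is derived
from the constrained fold: its 3' end is the partner of the mature 5' end
plus a 2-nt overhang, its 5' end the partner of (mature 3' end − 2). The
loop window lies between them. A read is *consistent* when its 5' end
falls within ±2 nt of the 5' end of any window and the read lies entirely
inside the hairpin. The inconsistent fraction is computed over read
*copies*, each weighted by its sequence's prevalence / n\_mappings —
copy-level counting is chosen (the alternative, counting distinct
sequences once, lets a handful of rare degradation species outvote
thousands of precisely processed copies). The mature and star windows
must additionally pair with each other: at least 14 base pairs between
them under the fold (the same duplex minimum as the structure filter),
which rejects hairpins whose entire read support is one tight cluster at
a window edge — such a cluster is trivially "consistent" with itself but
has no Dicer geometry. Candidates pass at inconsistent fraction ≤ 0.10;
the boundary passes.

## The folding model

Structure decisions use a self-contained simplified nearest-neighbour
model rather than an external folding library, so that every energy the
package reports can be verified against an exhaustive enumeration of
structures (`foldEnergyBruteForce`, `duplexEnergyBruteForce`). Watson-Crick
and GU pairs are allowed; a stack of two pairs contributes
−(s₁+s₂)/2 kcal/mol with pair strengths GC = 3, AU = 2, GU = 1; hairpin
loops cost 3.0 + 0.3·(L−3) with minimum loop 3; internal loops and bulges
cost 2.0 + 0.3·u for u ≤ 30 unpaired nucleotides (larger interior loops
are disallowed, as in standard folding implementations); multibranch
loops cost 3.4 + 0.4 per branch + 0.1 per unpaired base; external bases
are free. "No bifurcation" is enforced structurally: the constrained
search admits exactly one terminal loop. The −14 kcal/mol thresholds used
in filtering are parameters *of this model*; they are configurable and
should be recalibrated if the model is swapped for a full thermodynamic
parameterization. Intermolecular duplexes (chimera analysis) use the same
table with intramolecular pairing forbidden, in the style of hybrid-min.

Worth knowing: the dynamic programs are validated against brute-force
enumeration on short sequences (≤ ~30 nt; the number of structures of a
random 40-mer already exceeds 10⁷, which is why the equivalence tests
sample lengths 12-30).

## Knock-down statistics

For each reference the control and treatment counts are summed; sums
below 30, or a zero in either condition, exclude the reference. The log2
ratio treatment/control is shifted so the median of the control classes
(snoRNA, tRNA, miscellaneous RNA) is zero — the median is the default
because snRNAs can respond in the opposite direction to miRNAs and a mean
would follow them; a mean-shift is available by argument. Significance
uses subsets of control fold-changes matched to the group size: the
one-sided p-value is (1 + #{subset statistic ≤ observed}) / (1 + iterations),
with the median as default statistic (the fraction below the 30 percent
down-regulation cut is available; the choice is exposed because either is
defensible). The add-one correction avoids Monte-Carlo zeroes.

## Interaction evidence

CLIP tags support a hairpin when a same-strand tag overlaps it or lies
within 20 nt; one uniformly random supporting tag per hairpin provides the
plotted offset (one RNG draw per hairpin in sorted order, so a seed fixes
the figure). The genomic null samples 100 positions per hairpin mapping,
uniformly over nucleotides and strands, excises the 80 bracketing
nucleotides, and scales the supported count back by mappings/controls.
Chimeric reads are called by exact arm matching: a read prefix of at
least 17 nt matching a mature miRNA (up to 3 nt short at the 3' end) plus
a suffix of at least 17 nt matching a transcript; sites within 4 nt are
clustered into one interaction. This is a deliberate reduction of
alignment-based chimera pipelines — adequate for synthetic validation,
and stated as such. Seed classes: canonical (all of positions 2-8
Watson-Crick paired), imperfect (≥ 5 of 7 paired, GU allowed), non-seed.

## Evolutionary dating and genomic sources

A homolog call requires the hairpin criteria above plus the presence of a
human seed (positions 2-8 of either strand) as an exact substring.
Origins are assigned along the human lineage: the branch point minimising
one gain plus the Dollo losses among its non-missing descendants, with
present species outside the clade each charged one independent gain (the
cost of out-of-lineage presence has to be defined somehow; charging
leaf-level gains keeps the optimisation well-posed without modelling gains
on branches off the human path). Ties resolve to the more recent branch.
Species absent from an alignment are ignored, not counted as losses.

Genomic sources use a floating hierarchy — mitochondrion > snoRNA > rRNA
> tRNA > miscellaneous RNA > lncRNA > pseudogene > protein\_coding >
repeat > intergenic (pseudogene above protein-coding is deliberate,
mirroring the convention this hierarchy derives from) — and each mapping
contributes 1/n\_mappings to the class of its center nucleotide
(floor((start+end−1)/2) in 0-based half-open coordinates; the floor makes
even-length centers deterministic).

## Capture baits and saturation

Baits are 120 nt. The hybridized region — insert plus adapter tails —
is held constant at H = 60 nt per design (H is not dictated by the
measurements the design derives from; 60 balances binding strength
against adapter-driven off-target pulldown for 18-30-nt inserts and is
configurable). The adapter contribution splits evenly, odd nucleotide to
the 3'-adapter side; the bait is the reverse complement of the hybridized
region padded with an inert ACT-repeat spacer validated to share no 8-mer
with either adapter. Saturation curves shuffle reads once under a seed
and count targets detected (5' exact, ≤ 3 nt 3' difference) among each
prefix of the shuffled reads.

## The synthetic study

The generator emulates the pooled design at a desk scale: a 500-kb random
genome (42 percent GC), 20 planted miRNA loci and 20 decoy loci, 10
datasets of 200,000 reads, 30 percent uniform degradation background.
Planted precursors are mature/loop/star stems with three central stem
mismatches — real precursor duplexes are imperfect, and a perfect stem
would make the mature read its own star block's antisense, creating
minus-strand shadow loci no real genome exhibits — verified, not
assumed, to pass the structure thresholds after the 10/70 excision. Reads
from miRNA loci carry a 5' fidelity of 0.9 (90 percent at the consensus,
the rest split over ±1/±2 nt, interpolated linearly for other fidelity
values), 0-3 nt of 3' jitter, ~10 percent star and ~2 percent loop reads,
and 2 percent deliberately inconsistent positions. Decoy loci produce
abundant but positionally scattered reads — the signature of a degraded
transcript — and background reads are uniform over both strands. Every
locus is expressed in at least two datasets by construction (prevalence-1
behaviour is exercised by dedicated tests that restrict a locus to one
dataset). Knock-down pairs scale miRNA expectations by (1 − efficiency)
and multinomially resample both libraries to fixed depth.

What passing on this synthetic study shows — and what it does not: the
pipeline's rules are implemented correctly and are jointly sufficient to
separate Dicer-faithful signal from positionally random background at
realistic depths. It does not show performance on real data, where
degradation is transcript-shaped rather than uniform, genomes repeat,
adapters vary, and hairpin structure statistics differ from random
sequence. The problem sizes above keep a full end-to-end run in the
low minutes on a single core; they are the package's default study
conditions, not a limit of the method.

## Numerical and degenerate-input choices

Ties everywhere resolve deterministically (weight, prevalence, leftmost
coordinate, sequence); pipeline output is invariant to input order.
Energies are reported to 0.1 kcal/mol in text outputs but compared at
full precision internally. Zero counts exclude a reference from
fold-change analysis rather than being pseudocounted. Hairpins with no
mapped reads fail Dicer evaluation with reason "no support"; mature ends
that fall on unpaired bases search ±3 nt for the nearest paired position
before declaring "no duplex". The consensus-position tie in processing
precision resolves to the 5'-most coordinate. Contig-edge excisions drop
only the impossible flank hypothesis and record why.

## Known limitations

The energy model is deliberately minimal; absolute energies are not
comparable to full thermodynamic parameter sets, only thresholds tuned
for this model should be used with it. Exact-match mapping ignores
sequencing error and SNPs. Chimera calling does not model gapped or
reversed arm order. The parsimony dating does not reconstruct ancestral
sequences and assigns origins only along the human lineage. The CLI
wraps the R functions thinly and is not a workflow engine.
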