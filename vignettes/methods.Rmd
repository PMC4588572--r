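---
title: "Models and methods behind allodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind allodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

allodiv re-implements, as a tested pipeline over synthetic data with known
ground truth, the comparative molecular-evolution analyses that accompany an
allotetraploid plant genome: homoeolog identification, Ka/Ks estimation and
clock dating, LTR retrotransposon dating and family clustering, pseudogene
detection and classification, subgenome partitioning, and expression-bias
calling. This vignette is the package's account of the models, the
parameters that matter, and the design decisions taken where the methods
left room.

## The substitution process and its estimators

All sequence divergence is simulated under the Kimura (1980) two-parameter
model with transition/transversion rate ratio kappa (default 2) and rates
normalized so that branch length is measured in expected substitutions per
site. Site end states are drawn from the exact K80 transition-probability
matrix P(d), so multiple hits per site are implicit in the draw. This is
deliberate: the K2P distance estimator,

K = -(1/2) log((1 - 2P - Q) sqrt(1 - 2Q)),

inverts exactly this process, so simulated branch lengths are recovered
without bias (the package's Monte-Carlo tests check the mean estimate at
d = 0.1 over 10-kb sequences against a 3-standard-error band). A
single-event-per-site ("thinned") sampler was considered and rejected: it
makes the raw mismatch proportion equal the branch length, so any
multiple-hit correction applied afterwards overestimates it by ~7% at
d = 0.1 — an inconsistency between generator and estimator that would
propagate into every dated quantity.

Ka/Ks uses Nei–Gojobori (1986) counting: synonymous site fractions from the
single-site mutational neighbourhood of each codon (changes to stop codons
count as nonsynonymous, so N + S = 3 × codons), difference counts averaged
over all orderings of single-base steps with stop-crossing pathways
excluded, and Jukes–Cantor correction of both proportions; p >= 3/4 flags
saturation. The implementation is table-driven (precomputed 64×64
pathway-averaged difference counts); the test suite checks it codon pair by
codon pair against an independent recursive pathway-enumeration oracle.
"Model averaging" as performed by KaKs_Calculator is *not* reproduced: NG86
is fully specifiable and oracle-testable, which is what a validation
pipeline needs. The universal code is assumed (the code table is a single
internal switch).

NG86 is known to overestimate Ks under transition-biased neutral evolution,
because synonymous changes are enriched among transitions while site
counting weights all changes equally. The generators therefore calibrate
branch lengths *against the estimator*: for coding divergence, only third
positions of fourfold-degenerate codons are mutated and the branch length
is solved (per gene, by root finding on the K80 mismatch curve) so that the
expected NG86 Ks equals the target; for neutral pseudogene divergence, the
expected NG86 Ks of a uniformly evolving CDS is computed from the codon
transition matrix and inverted the same way. "True Ks" in all truth tables
is thus on the estimator's own scale, which is what a recovery experiment
must hold fixed.

## Clock dating

All dates use T = K / (2 r) with r = 2.6e-9 substitutions per site per
year, the standard cotton rate. On that clock,
Ks 0.005 dates to ~0.96 Myr (the "approximately 1 Mya" species split),
Ks 0.04 to ~7.7 Myr (the A/D-genome split), and the pseudogene Ks band
0.06–0.1 to 11.5–19.2 Myr. The factor 2 reflects divergence along two
lineages; the same formula with the *inter-LTR* distance dates an LTR
element insertion, because the two terminal repeats are identical at
insertion and each accumulates substitutions independently thereafter.

## Synthetic allopolyploid and the Ks-peak experiment

`gen_allopolyploid()` simulates, per gene, an ancestral CDS (uniform sense
codons, ATG start) and evolves it along the tree (A/D split, then the
species split on each subgenome; optional diploid-relative tips), with
pairwise path lengths calibrated to the scheduled Ks targets (defaults:
At:Dt 0.04, Gb:Gh 0.005, Dt:D-diploid 0.011). With `omega > 0`,
nonsynonymous divergence at Ka = omega × Ks is added at second codon
positions with stop-creating changes rejected; omega = 0.2 is used where
realistic proteins matter (BBH), omega = 0 where a clean Ks axis matters.

The Ks-peak recovery experiment fixes 500 pairs and the 0.001 bin width and
asks the modal bin to sit at the target. The per-pair sampling error is
SD(Ks) ≈ sqrt(Ks/S) with S the synonymous-site count, so modal-bin
stability at 0.001 resolution needs S ≈ 10^4 per pair — hence the
experiment simulates 15,000-codon coding units (SD ≈ 0.0019 at Ks 0.04),
chosen by this power analysis. That compensates, at desk scale, for the
~21,600 pairs a genome-wide analysis pools; ordinary gene sets default to a
realistic 400 codons. Peak recovery is scored as the modal bin being the
target's bin or an adjacent one (the targets sit exactly on bin edges, so
mass necessarily splits between the two central bins).

## Alignment engine

Global and local affine-gap alignment are dynamic programming via
Biostrings::pairwiseAlignment (a gap of length L costs open + L × extend;
DNA defaults +1/−2 with 5/2 gaps, proteins BLOSUM62 with 10/0.5). A shared
k-mer prefilter (5-mers for protein, 12-mers for DNA) skips unrelated
pairs; long DNA subjects are narrowed to the best k-mer-seeded diagonal
window before the DP. HSP sets come from iterated local alignment with
masking, and E-values are ungapped Karlin–Altschul: lambda is solved from
sum p_i p_j exp(lambda s_ij) = 1 under a uniform residue background, K is
fixed at the conventional 0.1. E-values here only rank hits and gate them
at 1e-3 (the same operational role they play in a BLASTP-based pipeline);
they are approximations for gapped scores and are documented as such. On
sequences of a few bases the DP score is checked against brute-force
enumeration of all alignments.

## Homoeologs, unique genes, partitioning

BBH follows the 30%/30% rule: a pair is reported iff each member is the
other's best qualifying hit, qualifying meaning identity > 30% and query
coverage > 0.30 at E <= 1e-3. "Best" is highest score, ties broken by
identity then lexicographic id. Coverage is applied to the query (the
conventional reading; both coverages are reported). Unique genes require
both no protein hit at E <= 1e-3 and total non-overlapping HSP coverage of
the CDS against the other genome strictly below one third of the CDS
length.

Partitioning labels a sequence A_unique / D_unique / shared / none from its
qualifying hits against the two diploid references; the thresholds
(identity 0.95 over coverage 0.9, score-ratio tie band delta = 0.02) are
package configuration: published read groupings report only outcome
percentages (a 44.9/26.9/9.7%-style split), never their criteria, and such
splits are data-dependent, so no percentage is a target here. Note one contract subtlety: with
both a qualification threshold and a tie band, raising `min_identity` can
in principle flip a shared call to unique when one side's hit drops out;
for equal-length full-coverage reads, identity and score are monotonically
linked and the package's property test never observes it.

## LTR dynamics

Insertion ages: global alignment of the two terminal repeats, K2P over
gap-free columns, T = K/(2r); pairs below 50% global identity or with
saturated distances are flagged undated and excluded from distributions.
Only elements with both LTRs present are dated (solo LTRs have no partner
to compare). Burst detection bins ages (1-Myr default), smooths with a
centred 3-bin moving average to suppress Poisson jitter, and calls a local
maximum a burst when its drop to the deepest within-range valley separating
it from higher ground is at least 25% of its height (prominence fraction,
configurable; published burst figures come with no detection criterion,
so this is declared configuration). Flat histograms with adequate counts
yield no bursts; a three-component mixture at 1/5/12 Myr yields exactly
three.

Families follow the 80-80-80 rule — >= 80% identity over >= 80% of the
shorter sequence with an alignment longer than 80 bp — applied to the
terminal-repeat sequences, with single-linkage connected components as
families and the singleton ratio reported as singleton families over total
families. The 20-kb upstream windows for gene proximity are strand-aware
(minus-strand genes extend toward larger coordinates) and computed with
GenomicRanges half-open-safe arithmetic.

## Pseudogenes

Detection screens intergenic regions against the parent CDS set with the
k-mer prefilter and seeds local alignments for the best-ranked parents;
disablements (in-frame premature stops; gaps of non-codon length) are read
off the alignment in the parent reading frame. Detection is DNA-level: at
the divergences the generator produces (Ks ~0.08, under 10% nucleotide
divergence) it finds the same loci a protein-vs-DNA search would, at a
fraction of the cost; genuinely ancient pseudogenes would need the
protein-level search this package does not implement — a stated limitation.

Classification aligns each parent exon to the locus: processed requires a
multi-exon parent aligned contiguously across at least one exon–exon
junction (junction gap <= 30 bp) at parent coverage >= 0.70; duplicated
requires intron-scale junction gaps (> 30 bp) or a single-exon parent at
the same coverage; fragmented is everything else. The 30-bp "intron-scale"
constant separates alignment jitter from the smallest plausible intron and
is configurable, as is the > 30 bp overlap that operationalizes
"significant overlap" in the exclusion filter (neither constant has a
published value). The three filters — gene overlap, TE/plastid parent, locus
< 150 bp (strict, so a 150-bp locus is kept) — commute, which the tests
check. Divergence to parent repairs frameshifts by treating shifted columns
as gaps (never by editing sequence), drops codons containing gaps or stops,
and runs NG86.

The classification-recovery experiment (300 loci, equal category mix,
Ks 0.08 to parents of 2–4 exons) is scored against generator truth. The
Ks-to-parent distribution test uses 800-codon parents so that the modal
0.001 bin of 300 loci falls reliably inside the 0.06–0.1 band; at
realistic 400-codon parents the per-locus SD (~0.016) makes a specific
modal bin meaningless, which is why the band — not a single bin — is the
assertion.

## Expression

RPKM is 1e9 × count / (lib_size × gene_length) with lib_size the total
mapped reads per sample (gene-assigned totals are the configurable
alternative). Differential calls replace the DEGseq MARS statistic with a
two-sided exact binomial test of pooled counts against the library-size
proportion, BH-adjusted, keeping the published thresholds verbatim:
FDR <= 0.001 and |log2 ratio| >= 1, the ratio computed from group-mean
RPKM with a one-read pseudocount (ratio only, never the test). The
binomial test models technical (Poisson-level) variation, like the tool it
replaces; the null error-control experiment therefore runs at dispersion 0,
which is the model under which the test's FDR statement is defined.
Count matrices with biological overdispersion will inflate its calls — a
known property of this test family, not of this implementation.

Tissue-preferential genes must be significant against the pooled other
tissues *and* maximal in the target tissue. Homoeolog bias applies the same
binomial machinery to the two copies' pooled counts (equal expectation,
since both copies are measured in the same libraries) with a length-aware
ratio. The LTR-proximity contrast compares stratum means of per-gene mean
RPKM with a seeded label-permutation p-value (10,000 permutations).

## What the generators do and do not emulate

They emulate: divergence with known Ks on a fixed topology, terminal
repeats of known age, the three pseudogene constructions with injected
disablements, reads of known origin with substitution errors, and
negative-binomial counts with known fold changes. They do not emulate:
indels during evolution (alignment difficulty is therefore understated),
rate heterogeneity across sites or lineages, gene conversion between
subgenomes, TE nesting and truncation, sequencing quality or indel errors,
or compositional/GC bias. Passing recovery tests therefore demonstrates
correctness of the estimators and decision rules under their own model
assumptions — not robustness to everything real data does.

## Numerical and interface conventions

Coordinates are 0-based half-open internally (HSPs) and 1-based inclusive
at GFF3/report boundaries. Histograms are left-closed from zero;
`find_peak` breaks ties toward smaller Ks. Saturated estimates are flagged
and excluded from histograms and dating. All randomness flows through
per-call seeds with entity-hashed substreams, so insertion order cannot
change results and reruns are byte-identical. Problem sizes used by the
validation suite (500 pairs × 15,000 codons; 600 elements × 2-kb LTRs; 300
pseudogene loci; 2,000-gene count matrices) were chosen by the power
considerations above and are stated in `analysis/06_recovery_experiments.R`
and the acceptance script, which recompute everything from scratch.
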