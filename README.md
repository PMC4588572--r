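# allodiv — comparative molecular-evolution analyses for allopolyploid genomes

Allotetraploid plant genomes (the cotton AD genomes are the motivating
case) carry two diverged subgenomes, At and Dt, whose history is read from
sequence: homoeologous gene pairs identified by bidirectional best hit
(BBH), their synonymous divergence Ks converted to dates with a molecular
clock, LTR retrotransposon insertions dated from the divergence of their
two terminal repeats, pseudogenes detected in intergenic space and
classified, and expression asymmetries called between the subgenomes.
allodiv implements this analysis suite as a tested R package for people who
want each step reproducible and checkable against known ground truth, and
pairs it with a seeded synthetic-data layer that generates allopolyploid
gene complements, LTR elements, pseudogene loci, reads and count matrices
whose true parameters are recorded — so every estimator can be validated by
parameter recovery.

The core quantities, in the field's standard notation:

* **Ka/Ks** by Nei–Gojobori (1986) counting: synonymous/nonsynonymous site
  counts from each codon's single-site mutational neighbourhood, pathway-
  averaged difference counts (stop-crossing paths excluded), Jukes–Cantor
  correction d = −(3/4)·log(1 − (4/3)p), saturation flagged at p ≥ 3/4.
* **K2P distance** K = −(1/2)·log((1 − 2P − Q)·√(1 − 2Q)) with P, Q the
  transition/transversion proportions.
* **Molecular clock** T = K/(2r), r = 2.6×10⁻⁹ substitutions/site/year;
  the same formula dates LTR insertions from inter-LTR K2P.
* **Decision rules**: BBH at identity > 30% and query coverage > 0.30;
  DE at FDR ≤ 0.001 and |log2 ratio| ≥ 1 (exact binomial test,
  Benjamini–Hochberg); TE families by the 80–80–80 rule; pseudogene
  filters (> 30 bp gene overlap, TE/plastid parent, < 150 bp locus).

## Worked example

Simulate 40 homoeolog pairs whose At:Dt synonymous divergence is targeted
at Ks = 0.04, estimate Ks for one pair, and date the subgenome split:

```r
library(allodiv)

sim <- gen_allopolyploid(divergence_schedule(AD = 0.04, GbGh = 0.005),
                         n_genes = 40, n_codons = 2000, seed = 15)
at <- as.character(sim$sets$At); dt <- as.character(sim$sets$Dt)

ng86(as_codon_alignment(at[[1]], dt[[1]], ids = c("At_g0001", "Dt_g0001")))
#> NG86 divergence (At_g0001 vs Dt_g0001): 2000 codons
#>   N = 4539.67  S = 1460.33  Nd = 0.00  Sd = 63.00
#>   Ka = 0.0000  Ks = 0.0444  Ka/Ks = 0.0000

ks <- vapply(seq_along(at), function(i)
  ng86(as_codon_alignment(at[[i]], dt[[i]]))$Ks, 0)
peak <- find_peak(ks_histogram(ks, 0.001))
clock_convert(peak) / 1e6
#> [1] 7.596154
```

The modal bin of the Ks distribution sits next to 0.04 (40 pairs of 2,000
codons leave ~0.005 of per-pair sampling noise; the full-scale recovery
experiment pins it to the 0.04 bin) and dates the A/D-genome split to
~7.6–8 Myr on the cotton clock; Ks 0.005, the species split, dates to
~0.96 Myr the same way. The printed `N + S = 6000` (3 × codons) and
`Ka = 0` reflect the generator: divergence was placed only at
fourfold-degenerate third positions, so all 63 counted differences are
synonymous.

The numbered drivers under `analysis/` run the full study on simulated
data — `01_simulate_genomes.R` writes FASTA/GFF3/TSV ground truth;
`02`–`05` run homoeolog/Ks dating, LTR dynamics, pseudogene, and
expression analyses; `06_recovery_experiments.R` re-runs the full-scale
parameter-recovery experiments. Each writes its tables under `results/`
and narrates what it found.

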