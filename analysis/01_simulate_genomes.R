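#!/usr/bin/env Rscript
# Simulate the synthetic allotetraploid study system: homoeologous gene
# complements for two allotetraploid species (At/Dt subgenomes diverged at
# Ks 0.04, species split at Ks 0.005, D-diploid relative at Ks 0.011),
# a structured chromosome of multi-exon genes, LTR retroelements with known
# insertion ages, pseudogene loci of known category, and count matrices
# with known fold changes.  Everything downstream consumes these outputs.

library(allodiv)

seed <- 20260101
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

message("## gene complements (200 homoeolog pairs, 400 codons, omega 0.2)")
poly <- gen_allopolyploid(
  divergence_schedule(AD = 0.04, GbGh = 0.005, D_diploid = 0.011),
  n_genes = 200, n_codons = 400, omega = 0.2, seed = seed)
for (nm in names(poly$sets))
  write_fasta(poly$sets[[nm]], file.path(outdir, paste0(nm, "_cds.fasta")))
write_tsv(poly$truth, file.path(outdir, "homoeolog_truth.tsv"))

message("## structured chromosome (60 multi-exon genes)")
models <- gen_gene_models(60, n_exons_range = c(1, 5), seed = seed + 1)
write_fasta(models$genome, file.path(outdir, "chromosome.fasta"))
write_fasta(models$cds, file.path(outdir, "gene_cds.fasta"))
write_gene_gff3(models, file.path(outdir, "genes.gff3"))

message("## LTR retroelements (3 age components x 100)")
ltr <- gen_ltr_elements(300,
                        data.frame(age_years = c(1e6, 5e6, 12e6),
                                   weight = c(1, 1, 1)),
                        ltr_len = 1000, seed = seed + 2)
write_fasta(ltr$left, file.path(outdir, "ltr_left.fasta"))
write_fasta(ltr$right, file.path(outdir, "ltr_right.fasta"))
write_tsv(ltr$meta, file.path(outdir, "ltr_truth.tsv"))

message("## pseudogene loci (90, equal category mix, Ks 0.08)")
ps <- gen_pseudogenes(models, 90, ks = 0.08, seed = seed + 3)
write_fasta(ps$intergenic, file.path(outdir, "intergenic.fasta"))
write_tsv(ps$truth, file.path(outdir, "pseudogene_truth.tsv"))

message("## expression counts (1000 genes, 10% DE at fold 4)")
fc <- rep(1, 1000); fc[1:100] <- 4
cnt <- gen_counts(1000, tissues = c("fiber", "ovule", "leaf"), n_rep = 3,
                  fold_change = fc, seed = seed + 4)
write_tsv(data.frame(gene_id = rownames(cnt$mat$counts),
                     cnt$mat$counts, check.names = FALSE),
          file.path(outdir, "counts.tsv"))
write_tsv(cnt$truth, file.path(outdir, "de_truth.tsv"))
write_tsv(cnt$mat$meta, file.path(outdir, "samples.tsv"))
write_tsv(data.frame(gene_id = rownames(cnt$mat$counts),
                     length = cnt$mat$gene_length),
          file.path(outdir, "gene_lengths.tsv"))

st <- gene_stats(models)
message(sprintf(
  "simulated: %d genes (mean gene %d bp, CDS %d bp, %.2f exons/gene), %s",
  st$gene_count, st$mean_gene_size, st$mean_cds_size, st$exons_per_gene,
  "300 LTR elements, 90 pseudogene loci, 1000 expression genes"))
message("outputs under ", outdir)
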