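#!/usr/bin/env Rscript
# Detect pseudogenes in the simulated intergenic regions, classify each as
# duplicated / processed / fragmented, apply the exclusion filters
# (>30 bp overlap with a functional gene, TE/plastid parent, <150 bp), and
# estimate each locus's synonymous divergence to its parent.

library(allodiv)

ind <- "results/simulated"
outdir <- "results/pseudogenes"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

intergenic <- read_fasta(file.path(ind, "intergenic.fasta"))
cds <- read_fasta(file.path(ind, "gene_cds.fasta"))
models <- read_gene_gff3(file.path(ind, "genes.gff3"))
models$cds <- cds
truth <- read_tsv(file.path(ind, "pseudogene_truth.tsv"))

message("## detection in intergenic space")
cands <- detect_pseudogenes(intergenic, cds)
message(sprintf("  %d/%d loci detected, %d with a premature stop, %d with",
                nrow(cands), nrow(truth), sum(cands$n_stop > 0),
                sum(cands$n_frameshift > 0)))
message("  a frameshift recorded")

message("## three-way classification")
cands$category <- vapply(seq_len(nrow(cands)), function(i)
  as.character(classify_pseudogene(
    as.character(intergenic)[[cands$region_id[i]]],
    allodiv:::exon_cds_segments(models, cands$parent_gene_id[i]))), "")
tr <- truth$category[match(cands$region_id, truth$region_id)]
message(sprintf("  category accuracy %.1f%%",
                100 * mean(cands$category == tr)))
print(table(truth = tr, called = cands$category))

message("## divergence to parent (NG86 Ks after frame repair)")
cands$ks_to_parent <- vapply(seq_len(nrow(cands)), function(i)
  tryCatch(ks_to_parent(
    as.character(intergenic)[[cands$region_id[i]]],
    as.character(cds)[[cands$parent_gene_id[i]]])$Ks,
    error = function(e) NA_real_), 0)
h <- ks_histogram(cands$ks_to_parent, 0.001)
write_tsv(as.data.frame(h), file.path(outdir, "ks_to_parent_hist.tsv"))
message(sprintf("  mean Ks to parent %.3f (peak bin %.4f); at r = 2.6e-9%s",
                mean(cands$ks_to_parent, na.rm = TRUE), find_peak(h),
                sprintf(" the mean dates to %.1f Mya",
                        clock_convert(mean(cands$ks_to_parent,
                                           na.rm = TRUE)) / 1e6)))

message("## exclusion filters")
# place candidate loci on the chromosome coordinate system of their regions
cands$chrom <- cands$region_id
region_genes <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))
filtered <- filter_pseudogenes(cands, region_genes, parent_labels = NULL)
message(sprintf("  %d/%d candidates pass (none of the synthetic loci are",
                nrow(filtered), nrow(cands)))
message("  shorter than 150 bp, TE-parented, or gene-overlapping)")
write_tsv(filtered, file.path(outdir, "pseudogene_calls.tsv"))
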