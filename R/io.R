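# Interchange: FASTA (60-column wrap), GFF3 (1-based inclusive) and TSV.

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings with 60-column wrapping on output.
#'
#' @param x a `DNAStringSet`/`AAStringSet` or named character vector.
#' @param path file path.
#' @param type "dna" or "protein" for reading.
#' @return `read_fasta` returns an `XStringSet`.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (type == "dna") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
}

#' Write and read gene models as GFF3
#'
#' Genes and exons (1-based inclusive coordinates) via rtracklayer; exon
#' features carry a `Parent` attribute naming their gene.
#'
#' @param models list with `genes` and `exons` data.frames
#'   (see [gen_gene_models()]).
#' @param path file path.
#' @return `read_gene_gff3` returns a list with `genes` and `exons`.
#' @export
write_gene_gff3 <- function(models, path) {
  g <- models$genes; e <- models$exons
  gr_g <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$start, g$end),
                                 strand = g$strand)
  gr_g$type <- "gene"; gr_g$ID <- g$gene_id
  chrom_of <- setNames(g$chrom, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)
  gr_e <- GenomicRanges::GRanges(chrom_of[e$gene_id],
                                 IRanges::IRanges(e$start, e$end),
                                 strand = strand_of[e$gene_id])
  gr_e$type <- "exon"
  gr_e$ID <- paste0(e$gene_id, ".exon", e$exon_rank)
  gr_e$Parent <- e$gene_id
  all <- c(gr_g, gr_e)
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_gff3
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gdf <- as.data.frame(gr[gr$type == "gene"])
  edf <- as.data.frame(gr[gr$type == "exon"])
  genes <- data.frame(gene_id = gdf$ID, chrom = as.character(gdf$seqnames),
                      start = gdf$start, end = gdf$end,
                      strand = as.character(gdf$strand))
  parent <- vapply(edf$Parent, function(p) as.character(p)[1], "")
  exons <- data.frame(gene_id = parent,
                      exon_rank = as.integer(sub(".*\\.exon", "", edf$ID)),
                      start = edf$start, end = edf$end)
  o <- order(exons$gene_id, exons$exon_rank)
  list(genes = genes[order(genes$gene_id), , drop = FALSE],
       exons = exons[o, , drop = FALSE])
}

#' TSV helpers
#'
#' Tab-separated tables with a header row, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path file path.
#' @return `read_tsv` returns a data.frame.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
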