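# Synthetic gene models (exon/intron structure on a chromosome), pseudogene
# loci of known category, and sequencing reads of known origin.

#' Generate a synthetic chromosome of multi-exon genes
#'
#' Genes are placed head-to-tail on the plus strand of one chromosome,
#' separated by random intergenic spacers.  Every CDS is a valid ORF (ATG,
#' no internal stop, trailing stop codon) split across exons at codon
#' boundaries.
#'
#' @param n_genes number of genes.
#' @param n_exons_range inclusive range of exon counts per gene.
#' @param exon_codons_range inclusive range of codons per exon.
#' @param intron_len_range inclusive range of intron lengths (bp).
#' @param intergenic_len length of intergenic spacers (bp).
#' @param seed integer RNG seed.
#' @return list with `genome` (`DNAStringSet`, one chromosome), `genes` and
#'   `exons` (data.frames, 1-based inclusive coordinates), `cds` and
#'   `gene_seq` (`DNAStringSet`s; `gene_seq` spans exons + introns).
#' @export
gen_gene_models <- function(n_genes, n_exons_range = c(1, 5),
                            exon_codons_range = c(40, 150),
                            intron_len_range = c(100, 400),
                            intergenic_len = 2000, seed = 1) {
  chrom <- "chrS"
  out <- with_seed(seed, {
    parts <- character(0)
    pos <- 1
    genes <- list(); exons <- list(); cds <- character(0)
    gene_seq <- character(0)
    for (g in seq_len(n_genes)) {
      spacer <- random_dna(intergenic_len)
      parts <- c(parts, spacer); pos <- pos + nchar(spacer)
      ne <- sample(seq(n_exons_range[1], n_exons_range[2]), 1)
      exon_codons <- sample(seq(exon_codons_range[1], exon_codons_range[2]),
                            ne, replace = TRUE)
      cds_g <- paste0(ancestral_cds_chr(sum(exon_codons)), "TAA")
      exon_nt <- exon_codons * 3
      exon_nt[ne] <- exon_nt[ne] + 3  # stop codon in last exon
      introns <- if (ne > 1)
        vapply(seq_len(ne - 1), function(i)
          random_dna(sample(seq(intron_len_range[1], intron_len_range[2]),
                            1)), "") else character(0)
      gid <- fmt_id("gene", g)
      gstart <- pos
      cum <- cumsum(exon_nt)
      estarts <- c(1, head(cum, -1) + 1)
      gene_parts <- character(0)
      for (e in seq_len(ne)) {
        ex_seq <- substr(cds_g, estarts[e], cum[e])
        exons[[length(exons) + 1]] <- data.frame(
          gene_id = gid, exon_rank = e, start = pos,
          end = pos + exon_nt[e] - 1)
        gene_parts <- c(gene_parts, ex_seq)
        pos <- pos + exon_nt[e]
        if (e < ne) {
          gene_parts <- c(gene_parts, introns[e])
          pos <- pos + nchar(introns[e])
        }
      }
      gseq <- paste(gene_parts, collapse = "")
      parts <- c(parts, gseq)
      genes[[g]] <- data.frame(gene_id = gid, chrom = chrom, start = gstart,
                               end = pos - 1, strand = "+", n_exons = ne)
      cds[gid] <- cds_g
      gene_seq[gid] <- gseq
    }
    parts <- c(parts, random_dna(intergenic_len))
    list(genome = paste(parts, collapse = ""),
         genes = do.call(rbind, genes), exons = do.call(rbind, exons),
         cds = cds, gene_seq = gene_seq)
  })
  list(genome = Biostrings::DNAStringSet(setNames(out$genome, chrom)),
       genes = out$genes, exons = out$exons,
       cds = Biostrings::DNAStringSet(out$cds),
       gene_seq = Biostrings::DNAStringSet(out$gene_seq))
}

#' Generate pseudogene loci of known category
#'
#' Builds degenerate gene copies in three categories: `duplicated` (genomic
#' copy retaining intron structure), `processed` (intron-less copy of the
#' mRNA; requires a parent with >= 2 exons) and `fragmented` (contiguous
#' copy of < 70% of the parent CDS).  Each copy is evolved neutrally under
#' K80 to the target divergence and receives at least one disablement (a
#' premature stop and/or a 1-bp frameshift), then is embedded mid-way in a
#' random intergenic region.
#'
#' @param models output of [gen_gene_models()].
#' @param n number of pseudogene loci.
#' @param mix named proportions over
#'   `c("duplicated", "processed", "fragmented")`.
#' @param ks target neutral divergence to the parent (default 0.08, the
#'   observed pseudogene Ks peak region).
#' @param flank_len intergenic flank on each side of the inserted copy (bp).
#' @param kappa K80 transition/transversion ratio.
#' @param seed integer RNG seed.
#' @return list with `intergenic` (`DNAStringSet`, one region per locus) and
#'   `truth` (data.frame: `region_id`, `parent_gene_id`, `category`,
#'   `insert_start`, `insert_end` 1-based inclusive within the region,
#'   `disablements`).
#' @export
gen_pseudogenes <- function(models, n,
                            mix = c(duplicated = 1, processed = 1,
                                    fragmented = 1) / 3,
                            ks = 0.08, flank_len = 800, kappa = 2,
                            seed = 1) {
  cats <- c("duplicated", "processed", "fragmented")
  mix <- mix[cats]; mix[is.na(mix)] <- 0
  names(mix) <- cats
  if (sum(mix) <= 0) stopf("category mix must have positive total")
  multi <- models$genes$gene_id[models$genes$n_exons >= 2]
  if (mix["processed"] > 0 && length(multi) == 0)
    stopf("'processed' pseudogenes need a parent with >= 2 exons")
  cds <- as_seq_chr(models$cds)
  gseq <- as_seq_chr(models$gene_seq)
  # branch length chosen so the *expected NG86 estimate* equals `ks`
  # (NG86 overestimates under transition-biased neutral evolution)
  d_neutral <- calibrate_neutral_cds_distance(ks, kappa)
  with_seed(seed, {
    category <- sample(cats, n, replace = TRUE, prob = mix / sum(mix))
    regions <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      cat_i <- category[i]
      parent <- if (cat_i %in% c("processed", "duplicated"))
        multi[sample.int(length(multi), 1)]
      else models$genes$gene_id[sample.int(nrow(models$genes), 1)]
      base <- switch(cat_i,
        processed = cds[parent],
        duplicated = gseq[parent],
        fragmented = {
          L <- nchar(cds[parent])
          flen <- 3 * floor(runif(1, 0.30, 0.60) * L / 3)
          s0 <- 3 * sample.int((L - flen) %/% 3, 1)
          substr(cds[parent], s0 + 1, s0 + flen)
        })
      ps <- as.character(evolve_sequence(base, evolve_params(d_neutral,
                                                             kappa)))
      dis <- character(0)
      # premature stop, written codon-aligned in CDS frame (the copy starts
      # in frame for all three construction types)
      if (cat_i != "fragmented" || runif(1) < 0.5) {
        cpos <- 3 * sample.int(max(nchar(ps) %/% 3 - 2, 1), 1) + 1
        substr(ps, cpos, cpos + 2) <- "TAA"
        dis <- c(dis, sprintf("premature_stop@%d", cpos))
      }
      if (length(dis) == 0 || runif(1) < 0.5) {
        fpos <- sample.int(nchar(ps) - 1, 1)
        ps <- paste0(substr(ps, 1, fpos - 1),
                     substr(ps, fpos + 1, nchar(ps)))
        dis <- c(dis, sprintf("frameshift@%d", fpos))
      }
      regions[i] <- paste0(random_dna(flank_len), ps, random_dna(flank_len))
      truth[[i]] <- data.frame(
        region_id = sprintf("ig_%04d", i), parent_gene_id = unname(parent),
        category = cat_i, insert_start = flank_len + 1,
        insert_end = flank_len + nchar(ps),
        disablements = paste(dis, collapse = ";"))
    }
    names(regions) <- sprintf("ig_%04d", seq_len(n))
    list(intergenic = Biostrings::DNAStringSet(regions),
         truth = do.call(rbind, truth))
  })
}

#' Generate reads of known subgenome origin
#'
#' Uniformly positioned substrings of the two genomes (equal mixture), with
#' independent substitution errors at rate `err`.
#'
#' @param genome_a,genome_d source sequences (single strings or
#'   `DNAStringSet`s; sampled per-sequence proportional to length).
#' @param read_len read length (<= the shortest source sequence).
#' @param n_reads number of reads.
#' @param err substitution error rate in [0, 0.2].
#' @param seed integer RNG seed.
#' @return list with `reads` (`DNAStringSet`) and `truth` (data.frame:
#'   `read_id`, `origin` in `c("A", "D")`, `source_id`, `pos`).
#' @export
gen_reads <- function(genome_a, genome_d, read_len = 100, n_reads = 1000,
                      err = 0.01, seed = 1) {
  if (err < 0 || err > 0.2) stopf("err must be in [0, 0.2]")
  ga <- as_seq_chr(genome_a); gd <- as_seq_chr(genome_d)
  if (min(nchar(c(ga, gd))) < read_len)
    stopf("read_len exceeds the shortest source sequence")
  if (n_reads == 0)
    return(list(reads = Biostrings::DNAStringSet(
      setNames(character(0), character(0))),
      truth = data.frame(read_id = character(0), origin = character(0),
                         source_id = character(0), pos = integer(0))))
  with_seed(seed, {
    origin <- sample(c("A", "D"), n_reads, replace = TRUE)
    reads <- character(n_reads); src <- character(n_reads)
    pos <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      g <- if (origin[i] == "A") ga else gd
      si <- sample.int(length(g), 1, prob = nchar(g))
      p <- sample.int(nchar(g[si]) - read_len + 1, 1)
      rd <- substr(g[si], p, p + read_len - 1)
      if (err > 0) {
        hit <- which(runif(read_len) < err)
        if (length(hit)) {
          ch <- strsplit(rd, "")[[1]]
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(DNA_BASES, b), 1), "")
          rd <- paste(ch, collapse = "")
        }
      }
      reads[i] <- rd; src[i] <- names(g)[si]; pos[i] <- p
    }
    ids <- sprintf("read_%05d", seq_len(n_reads))
    list(reads = Biostrings::DNAStringSet(setNames(reads, ids)),
         truth = data.frame(read_id = ids, origin = origin,
                            source_id = src, pos = pos))
  })
}
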