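# Pseudogene detection in intergenic space, three-way classification,
# exclusion filters, and divergence-to-parent estimation.

#' Detect pseudogene candidates in intergenic regions
#'
#' Each (repeat-masked) intergenic region is screened against the parent CDS
#' set with a shared k-mer prefilter; the best-matching parents are aligned
#' locally (affine gaps) and regions with a qualifying alignment become
#' candidate loci.  Disablements (in-frame premature stops, frameshifting
#' gaps) are read off the alignment in the parent reading frame.
#'
#' @param intergenic named `DNAStringSet`/character of intergenic regions.
#' @param parents_cds named parent CDS set.
#' @param scoring DNA [scoring_scheme()].
#' @param min_identity_pct minimum best-HSP identity to call a candidate.
#' @param min_kmer minimum shared 12-mers to attempt alignment.
#' @param top_parents number of k-mer-ranked parents to align (the best
#'   aligning one is reported as the closest parent).
#' @return data.frame with `region_id`, `parent_gene_id`, `start`, `end`
#'   (1-based inclusive within the region), `identity_pct`,
#'   `parent_coverage`, `n_stop`, `n_frameshift`, `disablements`.
#' @export
detect_pseudogenes <- function(intergenic, parents_cds,
                               scoring = scoring_scheme("dna"),
                               min_identity_pct = 60, min_kmer = 8,
                               top_parents = 2) {
  intergenic <- as_seq_chr(intergenic)
  parents_cds <- as_seq_chr(parents_cds)
  if (length(intergenic) == 0)
    return(empty_pseudo_calls())
  k <- 12
  parent_kmers <- lapply(parents_cds, kmers, k = k)
  lambda <- ka_lambda(scoring)
  rows <- list()
  for (ri in seq_along(intergenic)) {
    region <- intergenic[[ri]]
    rk <- kmers(region, k)
    shared <- vapply(parent_kmers, function(pk) sum(pk %in% rk), 0)
    cand <- order(shared, decreasing = TRUE)[seq_len(top_parents)]
    cand <- cand[shared[cand] >= min_kmer]
    if (length(cand) == 0) next
    best <- NULL
    for (pi in cand) {
      h <- local_hsps(parents_cds[[pi]], region, scoring, lambda,
                      e_max = 1e-3, max_hsps = 8)
      if (is.null(h)) next
      if (is.null(best) || max(h$score) > max(best$h$score))
        best <- list(pi = pi, h = h)
    }
    if (is.null(best)) next
    h <- best$h
    top <- which.max(h$score)
    if (100 * h$identities[top] / h$aligned_len[top] < min_identity_pct)
      next
    dis <- hsp_disablements(parents_cds[[best$pi]], region, h, scoring)
    rows[[length(rows) + 1]] <- data.frame(
      region_id = names(intergenic)[ri],
      parent_gene_id = names(parents_cds)[best$pi],
      start = min(h$s_start) + 1L, end = max(h$s_end),
      identity_pct = 100 * h$identities[top] / h$aligned_len[top],
      parent_coverage = interval_union_len(h$q_start, h$q_end) /
        nchar(parents_cds[[best$pi]]),
      n_stop = dis$n_stop, n_frameshift = dis$n_frameshift,
      disablements = dis$label)
  }
  if (length(rows) == 0) return(empty_pseudo_calls())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_pseudo_calls <- function()
  data.frame(region_id = character(0), parent_gene_id = character(0),
             start = integer(0), end = integer(0),
             identity_pct = numeric(0), parent_coverage = numeric(0),
             n_stop = integer(0), n_frameshift = integer(0),
             disablements = character(0))

# Read disablements from the HSP set of one parent/region pair: in-frame
# stop codons in the candidate, and gaps of non-codon length (frameshifts).
hsp_disablements <- function(parent_cds, region, hsps, scoring) {
  n_stop <- 0L; n_fs <- 0L; labels <- character(0)
  for (i in seq_len(nrow(hsps))) {
    hs <- hsps[i, ]
    pa <- Biostrings::pairwiseAlignment(
      xstring(substr(parent_cds, hs$q_start + 1, hs$q_end), "dna"),
      xstring(substr(region, hs$s_start + 1, hs$s_end), "dna"),
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "global")
    a_par <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    a_can <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    # frameshifts: runs of gap columns with length not divisible by 3
    for (v in list(a_par, a_can)) {
      r <- rle(v == "-")
      bad <- sum(r$values & r$lengths %% 3 != 0)
      if (bad > 0) { n_fs <- n_fs + bad
        labels <- c(labels, rep("frameshift", bad)) }
    }
    # in-frame stops: candidate triplets aligned to parent codon positions
    ppos <- cumsum(a_par != "-") + hs$q_start  # 1-based parent positions
    keep <- a_par != "-"
    cand_at <- rep("-", nchar(parent_cds))
    cand_at[ppos[keep]] <- a_can[keep]
    frame_start <- (hs$q_start %/% 3) * 3 + 1
    cstarts <- seq(frame_start, nchar(parent_cds) - 2, by = 3)
    trip <- paste0(cand_at[cstarts], cand_at[cstarts + 1],
                   cand_at[cstarts + 2])
    stops <- trip %in% STOP_CODONS
    if (any(stops)) { n_stop <- n_stop + sum(stops)
      labels <- c(labels, sprintf("premature_stop@codon%d",
                                  which(stops))) }
  }
  list(n_stop = n_stop, n_frameshift = n_fs,
       label = paste(labels, collapse = ";"))
}

#' Classify a pseudogene candidate
#'
#' Aligns each parent exon (CDS segment) to the candidate region and applies
#' the category rules: `processed` if a multi-exon parent aligns contiguously
#' across at least one exon-exon junction (junction gap <= `junction_gap`)
#' with parent coverage >= `min_cov`; `duplicated` if junctions are
#' interrupted by intron-scale gaps (> `junction_gap`) or the parent is
#' single-exon, again at coverage >= `min_cov`; `fragmented` otherwise.
#'
#' @param region_seq candidate region sequence (character/`DNAString`).
#' @param parent_exons character vector of the parent's exon CDS segments in
#'   order.
#' @param junction_gap intron-scale gap threshold in bp (default 30).
#' @param min_cov parent CDS coverage required for the non-fragmented
#'   categories (default 0.70).
#' @param scoring DNA [scoring_scheme()].
#' @return one of "processed", "duplicated", "fragmented" with attribute
#'   `details` (per-exon hit table).
#' @export
classify_pseudogene <- function(region_seq, parent_exons, junction_gap = 30,
                                min_cov = 0.70,
                                scoring = scoring_scheme("dna")) {
  if (length(parent_exons) == 0) stopf("parent exon structure is required")
  region_seq <- as_aln_chr(region_seq)
  lambda <- ka_lambda(scoring)
  ne <- length(parent_exons)
  hit <- data.frame(exon = seq_len(ne), s_start = NA_real_,
                    s_end = NA_real_, q_len = NA_real_, aligned = FALSE)
  total_aln <- 0
  for (e in seq_len(ne)) {
    h <- local_hsps(parent_exons[e], region_seq, scoring, lambda,
                    e_max = 1e-3, max_hsps = 2)
    if (is.null(h)) next
    b <- which.max(h$score)
    hit$s_start[e] <- h$s_start[b]; hit$s_end[e] <- h$s_end[b]
    hit$q_len[e] <- h$q_end[b] - h$q_start[b]
    hit$aligned[e] <- TRUE
    total_aln <- total_aln + h$q_end[b] - h$q_start[b]
  }
  coverage <- total_aln / sum(nchar(parent_exons))
  junction_gaps <- numeric(0)
  for (e in seq_len(ne - 1)) {
    if (hit$aligned[e] && hit$aligned[e + 1] &&
        hit$s_start[e + 1] >= hit$s_start[e])
      junction_gaps <- c(junction_gaps,
                         hit$s_start[e + 1] - hit$s_end[e])
  }
  category <-
    if (coverage < min_cov) "fragmented"
    else if (ne == 1) "duplicated"
    else if (length(junction_gaps) == 0) "fragmented"
    else if (any(junction_gaps > junction_gap)) "duplicated"
    else "processed"
  attr(category, "details") <-
    list(coverage = coverage, junction_gaps = junction_gaps, hits = hit)
  category
}

#' Apply the pseudogene exclusion filters
#'
#' Drops candidates that (1) overlap a functional gene annotation by more
#' than `max_overlap` bp, (2) have a parent labelled as a transposon or
#' plastid gene, or (3) are shorter than `min_len` bp (strict <; a candidate
#' of exactly `min_len` is kept).  The three rules commute.
#'
#' @param cands data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and `parent_gene_id`.
#' @param genes functional gene annotations (data.frame with `chrom`,
#'   `start`, `end`); may have zero rows.
#' @param parent_labels named character vector mapping parent gene ids to
#'   labels; values "TE" or "plastid" trigger exclusion (missing ids count
#'   as nuclear).
#' @param min_len minimum locus length in bp (default 150).
#' @param max_overlap maximum tolerated overlap with a functional gene in bp
#'   (default 30; "significant overlap" has no published quantification,
#'   so this is configuration).
#' @return the filtered data.frame, with a `drop_reason` attribute recording
#'   what was removed.
#' @export
filter_pseudogenes <- function(cands, genes = NULL, parent_labels = NULL,
                               min_len = 150, max_overlap = 30) {
  if (nrow(cands) == 0) return(cands)
  len <- cands$end - cands$start + 1
  drop_len <- len < min_len
  drop_parent <- if (is.null(parent_labels)) rep(FALSE, nrow(cands)) else {
    lab <- parent_labels[cands$parent_gene_id]
    !is.na(lab) & lab %in% c("TE", "transposon", "plastid")
  }
  drop_overlap <- rep(FALSE, nrow(cands))
  if (!is.null(genes) && nrow(genes) > 0) {
    cr <- GenomicRanges::GRanges(cands$chrom,
                                 IRanges::IRanges(cands$start, cands$end))
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(cr, gr, minoverlap = 1L)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(cr)[S4Vectors::queryHits(ov)],
        IRanges::ranges(gr)[S4Vectors::subjectHits(ov)]))
      bad <- unique(S4Vectors::queryHits(ov)[w > max_overlap])
      drop_overlap[bad] <- TRUE
    }
  }
  keep <- !(drop_len | drop_parent | drop_overlap)
  out <- cands[keep, , drop = FALSE]
  attr(out, "drop_reason") <- data.frame(
    row = which(!keep),
    too_short = unname(drop_len[!keep]),
    bad_parent = unname(drop_parent[!keep]),
    gene_overlap = unname(drop_overlap[!keep]),
    row.names = NULL)
  out
}

#' Synonymous divergence between a pseudogene and its parent
#'
#' Aligns the parent CDS to the candidate locus (local, affine gaps),
#' projects the candidate onto the parent reading frame (frameshifts are
#' repaired by treating the shifted columns as alignment gaps, never by
#' editing sequence), drops codons containing gaps or stops, and estimates
#' Ks with [ng86()].
#'
#' @param region_seq candidate locus sequence.
#' @param parent_cds parent coding sequence.
#' @param scoring DNA [scoring_scheme()].
#' @return a `div_estimate` (see [ng86()]); errors with class
#'   `allodiv_unalignable` if no alignable frame remains.
#' @export
ks_to_parent <- function(region_seq, parent_cds,
                         scoring = scoring_scheme("dna")) {
  region_seq <- as_aln_chr(region_seq); parent_cds <- as_aln_chr(parent_cds)
  lambda <- ka_lambda(scoring)
  h <- local_hsps(parent_cds, region_seq, scoring, lambda, e_max = 1e-3,
                  max_hsps = 8)
  if (is.null(h))
    stop(structure(class = c("allodiv_unalignable", "error", "condition"),
                   list(message = "no alignable frame to the parent",
                        call = NULL)))
  tab <- codon_tables()
  cand_at <- rep("-", nchar(parent_cds))
  for (i in seq_len(nrow(h))) {
    hs <- h[i, ]
    pa <- Biostrings::pairwiseAlignment(
      xstring(substr(parent_cds, hs$q_start + 1, hs$q_end), "dna"),
      xstring(substr(region_seq, hs$s_start + 1, hs$s_end), "dna"),
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "global")
    a_par <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    a_can <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    keep <- a_par != "-"
    ppos <- cumsum(keep) + hs$q_start
    cand_at[ppos[keep]] <- a_can[keep]
  }
  nc <- (nchar(parent_cds) %/% 3) * 3
  cstarts <- seq(1, nc - 2, by = 3)
  par_cod <- substring(parent_cds, cstarts, cstarts + 2)
  can_cod <- paste0(cand_at[cstarts], cand_at[cstarts + 1],
                    cand_at[cstarts + 2])
  ok <- !grepl("-", can_cod, fixed = TRUE) &
    !(can_cod %in% STOP_CODONS) & !(par_cod %in% STOP_CODONS)
  if (sum(ok) == 0)
    stop(structure(class = c("allodiv_unalignable", "error", "condition"),
                   list(message = "no intact codons after frame repair",
                        call = NULL)))
  ng86(as_codon_alignment(paste(par_cod[ok], collapse = ""),
                          paste(can_cod[ok], collapse = ""),
                          ids = c("parent", "pseudogene")))
}
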