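# Homoeolog identification (bidirectional best hit), unique-gene detection,
# and subgenome partitioning of sequences against two diploid references.

best_hits <- function(hits) {
  # per query: highest best_score, ties -> highest identity_pct, then
  # lexicographic subject id
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_id, -hits$best_score, -hits$identity_pct,
             hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Homoeolog pairs by bidirectional best hit (BBH)
#'
#' A pair (a, d) is reported iff d is a's best qualifying hit and a is d's
#' best qualifying hit, where qualifying means identity > `min_identity_pct`
#' and query coverage > `min_cov` at E-value <= `e_max` (the 30%/30% rule).
#' "Best" is the highest score; ties break by identity, then id.
#'
#' @param prots_a,prots_d named protein sets (character or `AAStringSet`).
#' @param scoring protein [scoring_scheme()].
#' @param min_identity_pct,min_cov qualification thresholds (defaults 30 and
#'   0.30).
#' @param e_max E-value cutoff for hits (default 1e-3).
#' @return data.frame with `gene_a_id`, `gene_d_id`, `identity_pct`,
#'   `q_coverage`, `best_score`; each gene appears in at most one pair.
#' @export
bbh_pairs <- function(prots_a, prots_d,
                      scoring = scoring_scheme("protein"),
                      min_identity_pct = 30, min_cov = 0.30,
                      e_max = 1e-3) {
  prots_a <- as_seq_chr(prots_a); prots_d <- as_seq_chr(prots_d)
  if (length(prots_a) == 0 || length(prots_d) == 0)
    stopf("protein sets must be non-empty")
  qualify <- function(h)
    h[h$identity_pct > min_identity_pct & h$q_coverage > min_cov, ,
      drop = FALSE]
  # two shared 5-mers prune unrelated pairs while retaining homologues well
  # below the 30% identity floor; two HSP rounds suffice for coverage
  fwd <- best_hits(qualify(local_search(prots_a, prots_d, scoring,
                                        e_max = e_max, min_shared = 2,
                                        max_hsps = 2)))
  rev <- best_hits(qualify(local_search(prots_d, prots_a, scoring,
                                        e_max = e_max, min_shared = 2,
                                        max_hsps = 2)))
  if (nrow(fwd) == 0 || nrow(rev) == 0)
    return(data.frame(gene_a_id = character(0), gene_d_id = character(0),
                      identity_pct = numeric(0), q_coverage = numeric(0),
                      best_score = numeric(0)))
  rev_best <- setNames(rev$subject_id, rev$query_id)
  keep <- !is.na(rev_best[fwd$subject_id]) &
    rev_best[fwd$subject_id] == fwd$query_id
  out <- data.frame(gene_a_id = fwd$query_id[keep],
                    gene_d_id = fwd$subject_id[keep],
                    identity_pct = fwd$identity_pct[keep],
                    q_coverage = fwd$q_coverage[keep],
                    best_score = fwd$best_score[keep])
  out[order(out$gene_a_id), , drop = FALSE]
}

#' Genes with no counterpart in the other subgenome
#'
#' A gene is "unique" with respect to set y iff (1) its protein has no hit in
#' `prots_y` at E <= `e_max`, and (2) the total non-overlapping HSP length of
#' its CDS against `genome_y` is strictly less than one third of its CDS
#' length.
#'
#' @param prots_x named query proteins; `cds_x` the matching CDS (same ids).
#' @param prots_y proteins of the other subgenome.
#' @param genome_y genomic sequences of the other subgenome.
#' @param e_max E-value cutoff (default 1e-3).
#' @return character vector of unique gene ids.
#' @export
unique_genes <- function(prots_x, prots_y, genome_y, cds_x, e_max = 1e-3) {
  prots_x <- as_seq_chr(prots_x); prots_y <- as_seq_chr(prots_y)
  genome_y <- as_seq_chr(genome_y); cds_x <- as_seq_chr(cds_x)
  missing_cds <- setdiff(names(prots_x), names(cds_x))
  if (length(missing_cds))
    stopf("missing CDS for protein(s): %s",
          paste(head(missing_cds, 3), collapse = ", "))
  prot_hits <- local_search(prots_x, prots_y, scoring_scheme("protein"),
                            e_max = e_max)
  has_prot_hit <- names(prots_x) %in% prot_hits$query_id
  dna_hits <- local_search(cds_x, genome_y, scoring_scheme("dna"),
                           e_max = e_max)
  hsps <- attr(dna_hits, "hsps")
  hsp_len <- setNames(numeric(length(cds_x)), names(cds_x))
  if (!is.null(hsps)) {
    for (qid in unique(hsps$query_id)) {
      h <- hsps[hsps$query_id == qid, , drop = FALSE]
      hsp_len[qid] <- interval_union_len(h$q_start, h$q_end)
    }
  }
  ids <- names(prots_x)
  ids[!has_prot_hit & hsp_len[ids] < nchar(cds_x[ids]) / 3]
}

#' Partition sequences between two subgenome references
#'
#' Each sequence is aligned against both reference sets; a hit qualifies if
#' identity >= `min_identity` over coverage >= `min_cov`.  Label `A_unique`
#' if only the A reference qualifies, or both qualify and
#' score_a / score_d > 1 + delta; `D_unique` symmetrically; `shared` when
#' both qualify within `delta`; `none` otherwise.  Thresholds are
#' configuration, not published constants: read groupings in the
#' literature report only outcome percentages, never their criteria.
#'
#' @param seqs named sequences to classify (e.g. reads).
#' @param ref_a,ref_d reference sequence sets for the two subgenomes.
#' @param min_identity,min_cov qualification thresholds (defaults 0.95, 0.9).
#' @param delta score-ratio band treated as a tie (default 0.02, >= 0).
#' @param scoring DNA [scoring_scheme()].
#' @return data.frame with `sequence_id`, `label`, `score_a`, `score_d`.
#' @export
partition_sequences <- function(seqs, ref_a, ref_d, min_identity = 0.95,
                                min_cov = 0.9, delta = 0.02,
                                scoring = scoring_scheme("dna")) {
  if (delta < 0) stopf("delta must be >= 0")
  if (min_identity <= 0 || min_identity > 1 || min_cov <= 0 || min_cov > 1)
    stopf("min_identity and min_cov must be in (0, 1]")
  seqs <- as_seq_chr(seqs)
  score_side <- function(refs) {
    h <- local_search(seqs, refs, scoring, e_max = 10)
    b <- best_hits(h)
    sc <- setNames(rep(NA_real_, length(seqs)), names(seqs))
    ok <- setNames(rep(FALSE, length(seqs)), names(seqs))
    if (nrow(b)) {
      sc[b$query_id] <- b$best_score
      ok[b$query_id] <- b$identity_pct >= 100 * min_identity &
        b$q_coverage >= min_cov
    }
    list(score = sc, qual = ok)
  }
  a <- score_side(as_seq_chr(ref_a))
  d <- score_side(as_seq_chr(ref_d))
  label <- character(length(seqs))
  for (i in seq_along(seqs)) {
    qa <- a$qual[i]; qd <- d$qual[i]
    sa <- a$score[i]; sd_ <- d$score[i]
    label[i] <-
      if (qa && !qd) "A_unique"
      else if (qd && !qa) "D_unique"
      else if (qa && qd) {
        ratio <- sa / sd_
        if (ratio > 1 + delta) "A_unique"
        else if (1 / ratio > 1 + delta) "D_unique"
        else "shared"
      } else "none"
  }
  data.frame(sequence_id = names(seqs), label = label,
             score_a = unname(a$score), score_d = unname(d$score))
}
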