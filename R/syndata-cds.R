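# Synthetic coding sequences and allopolyploid gene sets with known truth.

#' Generate random ancestral coding sequences
#'
#' Codons are drawn uniformly from the 61 sense codons; every sequence starts
#' with ATG and contains no internal stop codon.
#'
#' @param n_genes number of sequences.
#' @param n_codons codons per sequence (>= 2).
#' @param seed integer RNG seed.
#' @return a named `DNAStringSet`.
#' @export
gen_ancestral_cds <- function(n_genes, n_codons, seed = 1) {
  if (n_codons < 2) stopf("n_codons must be >= 2")
  if (n_genes == 0)
    return(Biostrings::DNAStringSet(setNames(character(0), character(0))))
  seqs <- with_seed(seed, vapply(seq_len(n_genes), function(i)
    ancestral_cds_chr(n_codons), ""))
  names(seqs) <- vapply(seq_len(n_genes), function(i) fmt_id("anc", i), "")
  Biostrings::DNAStringSet(seqs)
}

# one random CDS as a string, uniform over sense codons, ATG first
ancestral_cds_chr <- function(n_codons) {
  tab <- codon_tables()
  sense <- which(!tab$is_stop)
  idx <- sample(sense, n_codons, replace = TRUE)
  idx[1] <- match("ATG", tab$codons)
  paste(tab$codons[idx], collapse = "")
}

#' Divergence schedule for the synthetic allotetraploid
#'
#' Target synonymous divergences (Ks) between lineage pairs: `AD` between the
#' At and Dt homoeologs (A-/D-genome split), `GbGh` between the two
#' allotetraploid species, and optional `A_diploid`/`D_diploid` between each
#' subgenome and its extant diploid relative.
#'
#' @param AD Ks target for At:Dt pairs (default 0.04).
#' @param GbGh Ks target between the Gb and Gh copies of a subgenome
#'   (default 0.005); NULL to skip the species split.
#' @param A_diploid,D_diploid Ks targets between a subgenome and the extant
#'   diploid (e.g. 0.011 for Dt vs the D-genome diploid); NULL to skip.
#' @return an object of class `divergence_schedule`.
#' @export
divergence_schedule <- function(AD = 0.04, GbGh = 0.005,
                                A_diploid = NULL, D_diploid = NULL) {
  for (v in list(AD, GbGh, A_diploid, D_diploid))
    if (!is.null(v) && (!is.numeric(v) || v < 0))
      stopf("Ks targets must be >= 0")
  if (!is.null(GbGh) && GbGh > AD)
    stopf("the species split (GbGh) must be younger than the A/D split")
  structure(list(AD = AD, GbGh = GbGh,
                 A_diploid = A_diploid, D_diploid = D_diploid),
            class = "divergence_schedule")
}

#' Generate a synthetic allopolyploid gene complement
#'
#' Each gene descends from a random ancestral CDS.  Synonymous divergence is
#' introduced by evolving third positions of fourfold-degenerate codons under
#' K80, with branch lengths calibrated (per gene, by root finding on the K80
#' mismatch curve) so that the *expected NG86 Ks* between each pair of tips
#' equals its schedule target.  If `omega > 0`, nonsynonymous divergence with
#' expected Ka = omega x Ks is added at second codon positions
#' (stop-creating changes are rejected).
#'
#' @param schedule a [divergence_schedule()].
#' @param n_genes number of homoeolog pairs to simulate.
#' @param n_codons codons per gene (default 400, a typical plant CDS; the
#'   Ks-peak recovery experiments use much longer sequences, see the
#'   vignette).
#' @param omega Ka/Ks ratio of the simulated genes (default 0: purely
#'   synonymous divergence).
#' @param kappa K80 transition/transversion rate ratio.
#' @param seed integer RNG seed.
#' @return a list with `sets` (named list of `DNAStringSet`: `At`, `Dt`, and
#'   `GhAt`, `GhDt`, `A`, `D` as scheduled) and `truth` (data.frame with the
#'   true homoeolog pairing and Ks targets).
#' @export
gen_allopolyploid <- function(schedule = divergence_schedule(), n_genes,
                              n_codons = 400, omega = 0, kappa = 2,
                              seed = 1) {
  stopifnot(inherits(schedule, "divergence_schedule"))
  set_names <- c("At", "Dt",
                 if (!is.null(schedule$GbGh)) c("GhAt", "GhDt"),
                 if (!is.null(schedule$A_diploid)) "A",
                 if (!is.null(schedule$D_diploid)) "D")
  if (n_genes == 0) {
    empty <- Biostrings::DNAStringSet(setNames(character(0), character(0)))
    return(list(sets = setNames(rep(list(empty), length(set_names)),
                                set_names),
                truth = data.frame(gene_a_id = character(0),
                                   gene_d_id = character(0),
                                   ks_target = numeric(0))))
  }
  tab <- codon_tables()
  out <- with_seed(seed, {
    sets <- lapply(set_names, function(nm) character(n_genes))
    names(sets) <- set_names
    for (g in seq_len(n_genes)) {
      anc <- ancestral_cds_chr(n_codons)
      codes <- seq_to_codes(anc)
      idx4 <- fourfold_third_positions(codes)
      cidx <- cds_codon_indices(anc)
      S_ng <- sum(tab$fS[cidx])
      N_ng <- 3 * n_codons - S_ng
      n4 <- length(idx4)
      pos2 <- seq(2, 3 * n_codons, 3)
      # total path length (per evolved site) for a pairwise Ks target
      d4_of <- function(ks) {
        if (is.null(ks) || ks == 0) return(0)
        calibrate_distance(ks, kappa, transform = function(q) {
          p <- q * n4 / S_ng
          if (p >= 0.75) return(10)        # out of range -> push root left
          -0.75 * log(1 - 4 * p / 3)
        })
      }
      d2_of <- function(ks) {
        ka <- omega * ks
        if (is.null(ks) || ka == 0) return(0)
        calibrate_distance(ka, kappa, transform = function(q) {
          p <- q * n_codons / N_ng
          if (p >= 0.75) return(10)
          -0.75 * log(1 - 4 * p / 3)
        })
      }
      D_AD <- c(d4_of(schedule$AD), d2_of(schedule$AD))
      D_sp <- if (is.null(schedule$GbGh)) c(0, 0)
        else c(d4_of(schedule$GbGh), d2_of(schedule$GbGh))
      stem <- (D_AD - D_sp) / 2   # ancestral-lineage share per subgenome
      tip <- D_sp / 2             # post-speciation share per tetraploid copy
      branch <- function(codes, d) {
        new <- codes
        new[idx4] <- evolve_base_codes(codes[idx4], d[1], kappa)
        if (d[2] > 0) {
          cand <- codes
          cand[pos2] <- evolve_base_codes(codes[pos2], d[2], kappa)
          # reject second-position changes that create a stop codon
          ci <- codon_index(cand[seq(1, 3 * n_codons, 3)], cand[pos2],
                            cand[pos2 + 1])
          bad <- which(tab$is_stop[ci])
          if (length(bad)) cand[pos2[bad]] <- codes[pos2[bad]]
          new[pos2] <- cand[pos2]
        }
        new
      }
      stemA <- branch(codes, stem)
      stemD <- branch(codes, stem)
      sets[["At"]][g] <- codes_to_seq(branch(stemA, tip))
      sets[["Dt"]][g] <- codes_to_seq(branch(stemD, tip))
      if ("GhAt" %in% set_names) {
        sets[["GhAt"]][g] <- codes_to_seq(branch(stemA, tip))
        sets[["GhDt"]][g] <- codes_to_seq(branch(stemD, tip))
      }
      if ("A" %in% set_names) {
        dA <- c(d4_of(schedule$A_diploid), d2_of(schedule$A_diploid)) - tip
        sets[["A"]][g] <- codes_to_seq(branch(stemA, pmax(dA, 0)))
      }
      if ("D" %in% set_names) {
        dD <- c(d4_of(schedule$D_diploid), d2_of(schedule$D_diploid)) - tip
        sets[["D"]][g] <- codes_to_seq(branch(stemD, pmax(dD, 0)))
      }
    }
    sets
  })
  sets <- lapply(set_names, function(nm) {
    s <- out[[nm]]
    names(s) <- vapply(seq_len(n_genes), function(i) fmt_id(nm, i), "")
    Biostrings::DNAStringSet(s)
  })
  names(sets) <- set_names
  truth <- data.frame(
    gene_a_id = vapply(seq_len(n_genes), function(i) fmt_id("At", i), ""),
    gene_d_id = vapply(seq_len(n_genes), function(i) fmt_id("Dt", i), ""),
    ks_target = schedule$AD)
  list(sets = sets, truth = truth, schedule = schedule)
}
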