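# Codon bookkeeping for NG86 counting.
#
# Codons are indexed 1..64 as (b1-1)*16 + (b2-1)*4 + b3 over the A,C,G,T
# base encoding.  The universal genetic code is taken from
# Biostrings::GENETIC_CODE (the code table is config-exposed through
# `genetic_code()` should an alternative ever be needed).

codon_index <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  # reorder into our A,C,G,T index order
  codons <- character(64)
  for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4)
    codons[codon_index(b1, b2, b3)] <-
      paste0(DNA_BASES[b1], DNA_BASES[b2], DNA_BASES[b3])
  aa <- unname(gc[codons])
  names(aa) <- codons
  aa
}

codon_tables <- function() {
  if (!is.null(.allodiv_cache$codon_tables)) return(.allodiv_cache$codon_tables)
  aa <- genetic_code()
  codons <- names(aa)
  is_stop <- aa == "*"
  base_of <- function(codon, pos) match(substr(codon, pos, pos), DNA_BASES)

  # neighbours: for codon i, position p, the 3 single-base alternatives
  neighbour <- function(i, p, b) {
    bs <- c(base_of(codons[i], 1), base_of(codons[i], 2), base_of(codons[i], 3))
    bs[p] <- b
    codon_index(bs[1], bs[2], bs[3])
  }

  # per-codon synonymous site count: at each position, the fraction of the
  # three possible changes that are synonymous (changes to stop codons count
  # as nonsynonymous, so every position contributes exactly one site)
  fS <- numeric(64)
  for (i in 1:64) {
    if (is_stop[i]) { fS[i] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      b0 <- base_of(codons[i], p)
      for (b in setdiff(1:4, b0)) {
        j <- neighbour(i, p, b)
        if (!is_stop[j] && aa[j] == aa[i]) s <- s + 1 / 3
      }
    }
    fS[i] <- s
  }

  # fourfold-degenerate third position?
  fourfold <- logical(64)
  for (i in 1:64) {
    if (is_stop[i]) next
    third <- vapply(1:4, function(b) aa[neighbour(i, 3, b)], "")
    fourfold[i] <- !any(third == "*") && length(unique(third)) == 1
  }

  # pathway-averaged synonymous/nonsynonymous difference counts for all
  # non-stop codon pairs: average over orderings of the single-base steps,
  # excluding pathways through stop codons (re-weighting the rest equally)
  Sd <- matrix(0, 64, 64)
  Nd <- matrix(0, 64, 64)
  step_counts <- function(path) {
    s <- 0; n <- 0
    for (k in seq_len(length(path) - 1)) {
      if (aa[path[k]] == aa[path[k + 1]]) s <- s + 1 else n <- n + 1
    }
    c(s, n)
  }
  for (i in 1:64) {
    if (is_stop[i]) next
    bi <- c(base_of(codons[i], 1), base_of(codons[i], 2), base_of(codons[i], 3))
    for (j in 1:64) {
      if (is_stop[j] || i == j) next
      bj <- c(base_of(codons[j], 1), base_of(codons[j], 2),
              base_of(codons[j], 3))
      diff_pos <- which(bi != bj)
      orders <- switch(length(diff_pos),
                       list(diff_pos),
                       list(diff_pos, rev(diff_pos)),
                       {
                         perms <- list()
                         for (a in 1:3) for (b in 1:3) for (cc in 1:3)
                           if (length(unique(c(a, b, cc))) == 3)
                             perms[[length(perms) + 1]] <-
                               diff_pos[c(a, b, cc)]
                         perms
                       })
      ok <- list(); blocked <- list()
      for (ord in orders) {
        path <- i; cur <- bi
        good <- TRUE
        for (p in ord) {
          cur[p] <- bj[p]
          nxt <- codon_index(cur[1], cur[2], cur[3])
          path <- c(path, nxt)
          if (is_stop[nxt] && nxt != j) good <- FALSE
        }
        if (good) ok[[length(ok) + 1]] <- path
        else blocked[[length(blocked) + 1]] <- path
      }
      use <- if (length(ok) > 0) ok else blocked
      counts <- vapply(use, step_counts, numeric(2))
      Sd[i, j] <- mean(counts[1, ])
      Nd[i, j] <- mean(counts[2, ])
    }
  }
  .allodiv_cache$codon_tables <-
    list(aa = aa, codons = codons, is_stop = is_stop, fS = fS,
         fourfold = fourfold, Sd = Sd, Nd = Nd)
  .allodiv_cache$codon_tables
}

# indices (within a base-code vector) of third positions of fourfold codons
fourfold_third_positions <- function(codes) {
  n <- length(codes) %/% 3
  if (n == 0) return(integer(0))
  tab <- codon_tables()
  idx <- codon_index(codes[seq(1, 3 * n, 3)], codes[seq(2, 3 * n, 3)],
                     codes[seq(3, 3 * n, 3)])
  which(tab$fourfold[idx]) * 3L
}

# split a gap-free CDS string into codon indices
cds_codon_indices <- function(s) {
  n <- nchar(s)
  if (n %% 3 != 0) stopf("CDS length %d is not a multiple of 3", n)
  codes <- seq_to_codes(s)
  codon_index(codes[seq(1, n, 3)], codes[seq(2, n, 3)], codes[seq(3, n, 3)])
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Expected NG86 Ks between a uniform-sense-codon ancestor and a copy evolved
# neutrally (all positions) under K80 for branch length d, with stop-codon
# descendants excluded (as divergence-to-parent estimation drops them).
# NG86 overestimates Ks under transition-biased neutral evolution, so the
# generator inverts this curve to hit estimator-scale targets.
expected_ng86_ks_neutral <- function(d, kappa = 2) {
  tab <- codon_tables()
  p <- k80_probs(d, kappa)
  P4 <- matrix(p["tv"], 4, 4)
  diag(P4) <- p["same"]
  P4[cbind(1:4, .TS_PARTNER)] <- p["ts"]
  P64 <- kronecker(P4, kronecker(P4, P4))
  sense <- !tab$is_stop
  W <- P64[sense, sense, drop = FALSE]      # ancestor x descendant
  W <- W / rowSums(W)                        # condition on sense descendant
  fS <- tab$fS[sense]
  S_mean <- mean((outer(fS, fS, "+") / 2 * W) %*% rep(1, sum(sense)))
  Sd_mean <- mean(rowSums(tab$Sd[sense, sense] * W))
  pS <- Sd_mean / S_mean
  if (pS >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * pS / 3)
}

# branch length whose expected NG86 Ks equals the target
calibrate_neutral_cds_distance <- function(ks_target, kappa = 2) {
  if (ks_target <= 0) return(0)
  uniroot(function(d) expected_ng86_ks_neutral(d, kappa) - ks_target,
          c(1e-9, 3), tol = 1e-10)$root
}

has_internal_stop <- function(s) {
  idx <- cds_codon_indices(s)
  tab <- codon_tables()
  any(tab$is_stop[idx[-length(idx)]]) || tab$is_stop[idx[1]]
}
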