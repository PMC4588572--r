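# Independent oracles used to cross-check the package implementations.
# These are deliberately written from first principles (recursive
# enumeration, direct formulas) and never call the code paths they check.

# ---- brute-force global alignment -----------------------------------------
# Enumerates every alignment (move sequences M / gap-in-b / gap-in-a) and
# scores it with affine gaps under the convention that a gap run of length L
# costs gap_open + L * gap_extend.  Exponential; only for short sequences.
oracle_global_score <- function(a, b, match = 1, mismatch = -2,
                                gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > n && j > m) { best <<- max(best, sc); return(invisible()) }
    if (i <= n && j <= m)
      rec(i + 1, j + 1, "M",
          sc + if (av[i] == bv[j]) match else mismatch)
    if (i <= n)
      rec(i + 1, j, "X",
          sc - gap_extend - if (last == "X") 0 else gap_open)
    if (j <= m)
      rec(i, j + 1, "Y",
          sc - gap_extend - if (last == "Y") 0 else gap_open)
  }
  rec(1, 1, "none", 0)
  best
}

# ---- NG86 pathway-enumeration oracle --------------------------------------
# Site counts from the single-site mutational neighbourhood (stop-codon
# changes count as nonsynonymous) and difference counts averaged over all
# stop-free orderings of single-base steps.
oracle_ng86_counts <- function(cod1, cod2) {
  GC <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    aa <- GC[[codon]]
    s <- 0
    for (p in 1:3) for (b in bases) {
      alt <- codon
      substr(alt, p, p) <- b
      if (alt == codon) next
      if (GC[[alt]] != "*" && GC[[alt]] == aa) s <- s + 1 / 3
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  pair_diffs <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(dp) == 0) return(c(0, 0))
    paths <- list()
    for (ord in perms(dp)) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (GC[[nxt]] == "*" && nxt != c2) { ok <- FALSE; break }
        if (GC[[nxt]] == GC[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) paths[[length(paths) + 1]] <- c(sd, nd)
    }
    if (length(paths) == 0) return(NULL)  # fully blocked (not expected)
    Reduce(`+`, paths) / length(paths)
  }
  S <- (sum(vapply(cod1, syn_sites, 0)) +
          sum(vapply(cod2, syn_sites, 0))) / 2
  d <- t(vapply(seq_along(cod1), function(i)
    pair_diffs(cod1[i], cod2[i]), numeric(2)))
  list(S = S, N = 3 * length(cod1) - S, Sd = sum(d[, 1]), Nd = sum(d[, 2]))
}

# ---- misc helpers ----------------------------------------------------------
split_codons <- function(s)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))

# translate a CDS set to a named protein character vector
prot_set <- function(seqs) {
  x <- if (inherits(seqs, "XStringSet")) as.character(seqs) else seqs
  p <- vapply(x, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, 1, nchar(s))))), "")
  names(p) <- names(x)
  p
}

# a random sense-codon CDS string (test-local, independent of the generator)
rand_cds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)),
        collapse = "")
}
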