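# Molecular divergence: codon alignment, NG86 Ka/Ks, K2P distance,
# Ks histograms/peaks, and molecular-clock dating.

#' Construct a codon alignment from already-aligned CDS
#'
#' Accepts two gap-containing aligned CDS of equal length (gaps in whole-codon
#' units, `-` characters).  Use [codon_align()] to align unaligned CDS.
#'
#' @param aln1,aln2 aligned CDS strings of equal length (multiple of 3).
#' @param ids length-2 character vector of source gene ids.
#' @return an object of class `codon_alignment`.
#' @export
as_codon_alignment <- function(aln1, aln2, ids = c("seq1", "seq2")) {
  aln1 <- as_aln_chr(aln1); aln2 <- as_aln_chr(aln2)
  if (nchar(aln1) != nchar(aln2)) stopf("aligned sequences differ in length")
  if (nchar(aln1) %% 3 != 0) stopf("alignment length is not a multiple of 3")
  structure(list(aln1 = aln1, aln2 = aln2, ids = ids),
            class = "codon_alignment")
}

as_aln_chr <- function(x)
  if (inherits(x, "XString")) as.character(x) else as.character(x)[1]

#' Codon-aware alignment of two coding sequences
#'
#' Translates both CDS, aligns the proteins globally (Needleman-Wunsch,
#' affine gaps, BLOSUM62) and back-propagates the protein alignment onto the
#' nucleotides, so gaps always fall in whole-codon units.
#'
#' @param cds1,cds2 unaligned CDS (character or `DNAString(Set)`), lengths
#'   multiples of 3, translatable without internal stop codons.  A trailing
#'   stop codon is trimmed before alignment.
#' @param ids ids recorded on the alignment.
#' @return a `codon_alignment` object.
#' @export
codon_align <- function(cds1, cds2, ids = c("seq1", "seq2")) {
  s1 <- prep_cds(cds1); s2 <- prep_cds(cds2)
  p1 <- translate_cds(s1); p2 <- translate_cds(s2)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  a1 <- as.character(Biostrings::alignedPattern(pa))
  a2 <- as.character(Biostrings::alignedSubject(pa))
  as_codon_alignment(backprop_codons(a1, s1), backprop_codons(a2, s2), ids)
}

prep_cds <- function(x) {
  s <- as_aln_chr(x)
  if (nchar(s) == 0 || nchar(s) %% 3 != 0)
    stopf("invalid CDS: length %d is not a positive multiple of 3", nchar(s))
  idx <- cds_codon_indices(s)
  tab <- codon_tables()
  if (tab$is_stop[idx[length(idx)]]) {  # trim trailing stop
    s <- substr(s, 1, nchar(s) - 3)
    idx <- idx[-length(idx)]
  }
  if (any(tab$is_stop[idx])) stopf("invalid CDS: internal stop codon")
  s
}

translate_cds <- function(s)
  as.character(Biostrings::translate(Biostrings::DNAString(s)))

backprop_codons <- function(aa_aln, cds) {
  chars <- strsplit(aa_aln, "", fixed = TRUE)[[1]]
  out <- character(length(chars))
  pos <- 0
  for (k in seq_along(chars)) {
    if (chars[k] == "-") out[k] <- "---"
    else { out[k] <- substr(cds, pos * 3 + 1, pos * 3 + 3); pos <- pos + 1 }
  }
  paste(out, collapse = "")
}

#' Nei-Gojobori (1986) Ka/Ks estimation
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon from the
#' single-site mutational neighbourhood (averaged over the two sequences;
#' changes to stop codons count as nonsynonymous so N + S = 3 x codons), and
#' synonymous/nonsynonymous differences by averaging over all orderings of
#' single-base steps for multi-difference codons, excluding pathways through
#' stop codons.  Proportions are Jukes-Cantor corrected,
#' d = -(3/4) log(1 - (4/3) p); p >= 3/4 sets `saturated`.
#'
#' @param aln a `codon_alignment` (from [codon_align()] or
#'   [as_codon_alignment()]).
#' @return a list of class `div_estimate` with fields `N, S, Nd, Sd, pN, pS,
#'   Ka, Ks, omega, saturated`.
#' @export
ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- codon_tables()
  n <- nchar(aln$aln1) %/% 3
  c1 <- substring(aln$aln1, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
  c2 <- substring(aln$aln2, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
  keep <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  c1 <- c1[keep]; c2 <- c2[keep]
  if (length(c1) == 0) stopf("no ungapped aligned codons")
  i1 <- match(c1, tab$codons); i2 <- match(c2, tab$codons)
  if (anyNA(i1) || anyNA(i2)) stopf("non-ACGT characters in aligned codons")
  if (any(tab$is_stop[i1]) || any(tab$is_stop[i2]))
    stopf("internal stop codon in aligned CDS")
  S <- (sum(tab$fS[i1]) + sum(tab$fS[i2])) / 2
  N <- 3 * length(c1) - S
  Sd <- sum(tab$Sd[cbind(i1, i2)])
  Nd <- sum(tab$Nd[cbind(i1, i2)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    if (p == 0) return(0)   # avoid -0 from log(1)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(ids = aln$ids, codons = length(c1), N = N, S = S,
                 Nd = Nd, Sd = Sd, pN = pN, pS = pS, Ka = Ka, Ks = Ks,
                 omega = omega, saturated = saturated),
            class = "div_estimate")
}

#' @export
print.div_estimate <- function(x, ...) {
  cat(sprintf("NG86 divergence (%s vs %s): %d codons\n",
              x$ids[1], x$ids[2], x$codons))
  cat(sprintf("  N = %.2f  S = %.2f  Nd = %.2f  Sd = %.2f\n",
              x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("  Ka = %s  Ks = %s  Ka/Ks = %s%s\n",
              fmt_num(x$Ka), fmt_num(x$Ks), fmt_num(x$omega),
              if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

fmt_num <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)

#' Kimura two-parameter distance
#'
#' K = -(1/2) log((1 - 2P - Q) sqrt(1 - 2Q)) with P and Q the transition and
#' transversion proportions over comparable columns.  Columns with gaps or
#' ambiguity codes are excluded from the denominators.
#'
#' @param a,b aligned DNA sequences of equal length (character or
#'   `DNAString`); gaps as `-`.
#' @return distance in substitutions per site, with attributes `P`, `Q` and
#'   `sites`.  Saturation ((1-2P-Q) <= 0 or (1-2Q) <= 0) raises an error of
#'   class `allodiv_saturated`.
#' @export
k2p_distance <- function(a, b) {
  a <- as_aln_chr(a); b <- as_aln_chr(b)
  if (nchar(a) != nchar(b)) stopf("sequences differ in length")
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- x %in% DNA_BASES & y %in% DNA_BASES
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stopf("no comparable (gap-free) columns")
  diff <- x != y
  ts_pairs <- (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  P <- sum(diff & ts_pairs) / length(x)
  Q <- sum(diff & !ts_pairs) / length(x)
  k2p_from_pq(P, Q, sites = length(x))
}

k2p_from_pq <- function(P, Q, sites = NA_integer_) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("allodiv_saturated", "error", "condition"),
                   list(message = sprintf(
                     "saturated K2P distance (P = %.3f, Q = %.3f)", P, Q),
                     call = NULL)))
  K <- -0.5 * log(w1 * sqrt(w2))
  structure(K, P = P, Q = Q, sites = sites)
}

#' Bin Ks values into a fixed-width histogram
#'
#' Left-closed, right-open bins from 0 at the figure-style bin widths
#' (0.001 for ortholog Ks, 0.01 for paralog Ks).  Non-finite values
#' (saturated or undefined estimates) are excluded and counted separately.
#'
#' @param values numeric Ks values (NA/NaN/Inf allowed, excluded).
#' @param bin_width positive bin width in Ks units.
#' @return a `ks_histogram`: data.frame with `bin_left`, `bin_mid`, `count`
#'   and attributes `bin_width`, `n`, `n_excluded`.
#' @export
ks_histogram <- function(values, bin_width = 0.001) {
  if (!is.numeric(bin_width) || bin_width <= 0) stopf("bin_width must be > 0")
  finite <- values[is.finite(values)]
  n_excl <- length(values) - length(finite)
  if (length(finite) == 0) {
    warning("no finite Ks values; empty histogram")
    h <- data.frame(bin_left = numeric(0), bin_mid = numeric(0),
                    count = integer(0))
  } else {
    bin <- floor(finite / bin_width)
    tab <- table(bin)
    lefts <- as.numeric(names(tab)) * bin_width
    full <- seq(0, max(lefts), by = bin_width)
    count <- integer(length(full))
    count[match(round(lefts / bin_width), round(full / bin_width))] <-
      as.integer(tab)
    h <- data.frame(bin_left = full, bin_mid = full + bin_width / 2,
                    count = count)
  }
  structure(h, bin_width = bin_width, n = length(finite),
            n_excluded = n_excl, class = c("ks_histogram", "data.frame"))
}

#' Modal Ks of a histogram
#'
#' Midpoint of the maximal-count bin; ties broken toward smaller Ks.
#'
#' @param hist a [ks_histogram()].
#' @return the peak Ks (bin midpoint).
#' @export
find_peak <- function(hist) {
  stopifnot(inherits(hist, "ks_histogram"))
  if (nrow(hist) == 0 || attr(hist, "n") == 0)
    stopf("cannot find a peak in an empty histogram")
  hist$bin_mid[which.max(hist$count)]
}

#' Molecular-clock conversion of a distance to years
#'
#' T = K / (2 r), with r the substitution rate per site per year
#' (default 2.6e-9, the cotton rate used throughout).
#'
#' @param K distance in substitutions per site (>= 0); vectorized.
#' @param r substitution rate per site per year (> 0).
#' @return time in years.
#' @export
clock_convert <- function(K, r = 2.6e-9) {
  if (!is.numeric(r) || r <= 0) stopf("rate r must be > 0")
  if (any(K < 0, na.rm = TRUE)) stopf("distance K must be >= 0")
  K / (2 * r)
}
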