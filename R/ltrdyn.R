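# LTR retroelement insertion-age dating, age-distribution burst detection,
# 80-80-80 family clustering, and gene-proximity annotation.

#' Construct an LTR element set
#'
#' @param meta data.frame with `element_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`; extra columns (e.g. `true_age_years`) are kept.
#' @param left,right `DNAStringSet`s of the left/right terminal repeats,
#'   parallel to `meta` rows.
#' @return an object of class `ltr_set`.
#' @export
ltr_set <- function(meta, left, right) {
  stopifnot(nrow(meta) == length(left), nrow(meta) == length(right))
  if (any(Biostrings::width(left) == 0) || any(Biostrings::width(right) == 0))
    stopf("LTR sequences must be non-empty")
  structure(list(meta = meta, left = left, right = right), class = "ltr_set")
}

#' @export
print.ltr_set <- function(x, ...) {
  cat(sprintf("ltr_set: %d elements, LTR widths %d-%d bp\n", nrow(x$meta),
              min(Biostrings::width(x$left)),
              max(Biostrings::width(x$left))))
  invisible(x)
}

#' Date LTR element insertions from inter-LTR divergence
#'
#' The two terminal repeats of an element are identical at insertion; their
#' divergence dates it.  Each pair is aligned globally, the K2P distance is
#' computed over gap-free columns, and T = K / (2 r).  Elements whose LTR
#' pair is unalignable (global identity <= 50%) or K2P-saturated are flagged
#' undated and excluded from distributions.
#'
#' @param elems an [ltr_set()].
#' @param r substitution rate per site per year (default 2.6e-9).
#' @param scoring DNA [scoring_scheme()].
#' @return data.frame: `element_id`, `k2p`, `age_years`, `dated`.
#' @export
ltr_ages <- function(elems, r = 2.6e-9, scoring = scoring_scheme("dna")) {
  stopifnot(inherits(elems, "ltr_set"))
  n <- nrow(elems$meta)
  k2p <- rep(NA_real_, n); age <- rep(NA_real_, n); dated <- logical(n)
  left <- as.character(elems$left); right <- as.character(elems$right)
  for (i in seq_len(n)) {
    ga <- global_align(left[i], right[i], scoring)
    if (ga$identity <= 0.5) next
    K <- tryCatch(k2p_distance(ga$aligned[1], ga$aligned[2]),
                  allodiv_saturated = function(e) NA_real_)
    if (is.na(K)) next
    k2p[i] <- as.numeric(K)
    age[i] <- clock_convert(as.numeric(K), r)
    dated[i] <- TRUE
  }
  data.frame(element_id = elems$meta$element_id, k2p = k2p,
             age_years = age, dated = dated)
}

#' Insertion-age distribution and burst detection
#'
#' Ages are binned from 0 (left-closed bins of `bin_years`), the counts are
#' smoothed with a centred 3-bin moving average to suppress Poisson jitter,
#' and bursts are local maxima of the smoothed curve whose height exceeds the
#' larger flanking minimum by at least `prominence` x the peak height
#' (histogram boundaries count as zero-valleys).
#'
#' @param ages numeric ages in years (NAs allowed, excluded).
#' @param bin_years bin width in years (default 1e6).
#' @param prominence minimum relative prominence of a burst (default 0.25).
#' @return list with `hist` (data.frame `bin_left`, `bin_mid`, `count`,
#'   `smoothed`) and `bursts` (data.frame `age_years`, `count`, sorted by
#'   age).
#' @export
age_distribution <- function(ages, bin_years = 1e6, prominence = 0.25) {
  ages <- ages[is.finite(ages)]
  if (length(ages) == 0) stopf("no dated elements")
  bin <- floor(ages / bin_years)
  count <- tabulate(bin + 1, nbins = max(bin) + 1)
  left <- (seq_along(count) - 1) * bin_years
  sm <- smooth3(count)
  peaks <- integer(0)
  nb <- length(sm)
  for (i in seq_len(nb)) {
    lo <- if (i > 1) sm[i - 1] else 0
    hi <- if (i < nb) sm[i + 1] else 0
    if (sm[i] > lo && sm[i] >= hi && sm[i] > 0) {
      # prominence: drop to the deepest within-range valley separating this
      # peak from higher ground (or the histogram edge) on each side
      vals <- c(valley_depth(sm, i, -1L), valley_depth(sm, i, +1L))
      vals <- vals[is.finite(vals)]
      ref <- if (length(vals)) max(vals) else 0
      if ((sm[i] - ref) / sm[i] >= prominence)
        peaks <- c(peaks, i)
    }
  }
  list(hist = data.frame(bin_left = left, bin_mid = left + bin_years / 2,
                         count = count, smoothed = sm),
       bursts = data.frame(age_years = left[peaks] + bin_years / 2,
                           count = count[peaks]))
}

smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(as.numeric(x))
  c(mean(x[1:2]), (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3,
    mean(x[(n - 1):n]))
}

# walk from peak i in direction dir; return the minimum encountered before
# ground higher than the peak or the histogram edge; NA if the peak sits at
# the edge (that side imposes no constraint)
valley_depth <- function(x, i, dir) {
  j <- i + dir
  if (j < 1 || j > length(x)) return(NA_real_)
  m <- Inf
  while (j >= 1 && j <= length(x) && x[j] <= x[i]) {
    m <- min(m, x[j])
    j <- j + dir
  }
  m
}

#' Cluster elements into families by the 80-80-80 rule
#'
#' Two elements belong to the same family if their terminal-repeat sequences
#' share >= 80% identity over >= 80% of the shorter sequence's length with an
#' alignment longer than 80 bp; families are the connected components of
#' this relation (single linkage).
#'
#' @param seqs named element sequences (terminal repeats), character or
#'   `DNAStringSet`.
#' @param scoring DNA [scoring_scheme()].
#' @param min_identity_pct,min_len_frac,min_aln_len the three 80s.
#' @return data.frame `element_id`, `family_id`, `singleton`, with attribute
#'   `singleton_ratio` (singleton families / total families).
#' @export
cluster_families_808080 <- function(seqs, scoring = scoring_scheme("dna"),
                                    min_identity_pct = 80,
                                    min_len_frac = 0.8, min_aln_len = 80) {
  seqs <- as_seq_chr(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  hits <- local_search(seqs, seqs, scoring, e_max = 10, min_shared = 2)
  hsps <- attr(hits, "hsps")
  if (nrow(hits)) {
    for (rix in seq_len(nrow(hits))) {
      i <- match(hits$query_id[rix], names(seqs))
      j <- match(hits$subject_id[rix], names(seqs))
      if (i >= j) next
      h <- hsps[hsps$query_id == hits$query_id[rix] &
                  hsps$subject_id == hits$subject_id[rix], , drop = FALSE]
      b <- h[which.max(h$score), , drop = FALSE]
      shorter <- min(nchar(seqs[i]), nchar(seqs[j]))
      if (100 * b$identities / b$aligned_len >= min_identity_pct &&
          b$aligned_len >= min_len_frac * shorter &&
          b$aligned_len > min_aln_len) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  fam <- match(root, sort(unique(root)))
  sizes <- table(fam)
  singleton <- as.integer(sizes[as.character(fam)]) == 1
  out <- data.frame(element_id = names(seqs),
                    family_id = sprintf("fam_%03d", fam),
                    singleton = singleton)
  attr(out, "singleton_ratio") <- sum(sizes == 1) / length(sizes)
  out
}

#' Flag genes with an LTR element inserted within an upstream window
#'
#' The window is the `window` bp immediately upstream of the start codon,
#' strand-aware (for minus-strand genes it extends toward larger
#' coordinates); a gene is flagged iff any element interval overlaps it.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive), or a `GRanges` with a `gene_id` column.
#' @param elems an [ltr_set()] or a data.frame with `chrom`, `start`, `end`.
#' @param window upstream window in bp (default 20000, the 20-kb rule).
#' @return named logical vector over gene ids.
#' @export
annotate_ltr_proximity <- function(genes, elems, window = 20000) {
  gdf <- if (inherits(genes, "GRanges")) {
    data.frame(gene_id = genes$gene_id,
               chrom = as.character(GenomicRanges::seqnames(genes)),
               start = GenomicRanges::start(genes),
               end = GenomicRanges::end(genes),
               strand = as.character(GenomicRanges::strand(genes)))
  } else genes
  if (any(!gdf$strand %in% c("+", "-")))
    stopf("every gene needs a '+' or '-' strand for upstream arithmetic")
  gr <- GenomicRanges::GRanges(gdf$chrom,
                               IRanges::IRanges(gdf$start, gdf$end),
                               strand = gdf$strand)
  win <- GenomicRanges::promoters(gr, upstream = window, downstream = 0)
  win <- GenomicRanges::trim(suppressWarnings(win))
  emeta <- if (inherits(elems, "ltr_set")) elems$meta else elems
  er <- GenomicRanges::GRanges(emeta$chrom,
                               IRanges::IRanges(emeta$start, emeta$end))
  flag <- IRanges::overlapsAny(win, er, ignore.strand = TRUE)
  setNames(flag, gdf$gene_id)
}
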