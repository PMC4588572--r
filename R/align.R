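# Pairwise alignment engine: global and local affine-gap alignment (dynamic
# programming via Biostrings), HSP bookkeeping, a k-mer prefilter, and
# ungapped Karlin-Altschul E-values.

#' Scoring scheme for pairwise alignment
#'
#' @param type "dna" (match/mismatch matrix) or "protein" (BLOSUM62).
#' @param match,mismatch DNA scores (defaults +1/-2).
#' @param gap_open,gap_extend gap penalties as positive numbers; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(type = c("dna", "protein"), match = 1,
                           mismatch = -2, gap_open = 5, gap_extend = 2) {
  type <- match.arg(type)
  if (gap_extend < 0 || gap_open < gap_extend)
    stopf("need gap_open >= gap_extend >= 0 (as penalties)")
  if (type == "dna") {
    if (match <= mismatch) stopf("match score must exceed mismatch score")
    letters <- c(DNA_BASES, "N")
    m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
    diag(m) <- match
    m["N", ] <- m[, "N"] <- -abs(mismatch) - 2  # masking character
    if (gap_open == 5 && gap_extend == 2 && match == 1 && mismatch == -2) {
      # conventional DNA defaults, nothing to adjust
    }
  } else {
    m <- blosum62()
    if (missing(gap_open)) gap_open <- 10
    if (missing(gap_extend)) gap_extend <- 0.5
  }
  structure(list(type = type, matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

blosum62 <- function() {
  if (is.null(.allodiv_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .allodiv_cache$BLOSUM62 <- e$BLOSUM62
  }
  .allodiv_cache$BLOSUM62
}

xstring <- function(s, type) {
  if (type == "dna") Biostrings::DNAString(s) else Biostrings::AAString(s)
}

#' Global (Needleman-Wunsch) alignment of two sequences
#'
#' @param a,b sequences (character or `XString`); same alphabet, non-empty.
#' @param scoring a [scoring_scheme()].
#' @return list with `score`, `identity` (matches / alignment columns) and
#'   `aligned` (length-2 character vector with gaps).
#' @export
global_align <- function(a, b, scoring = scoring_scheme("dna")) {
  a <- as_aln_chr(a); b <- as_aln_chr(b)
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    xstring(a, scoring$type), xstring(b, scoring$type),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  a1 <- as.character(Biostrings::alignedPattern(pa))
  a2 <- as.character(Biostrings::alignedSubject(pa))
  x <- strsplit(a1, "")[[1]]; y <- strsplit(a2, "")[[1]]
  list(score = Biostrings::score(pa),
       identity = sum(x == y & x != "-") / length(x),
       aligned = c(a1, a2))
}

# all k-mers of a string
kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

# Karlin-Altschul lambda for a scoring matrix under a uniform background
# over the residue alphabet: solve sum p_i p_j exp(lambda s_ij) = 1.
ka_lambda <- function(scoring) {
  key <- paste0("lambda_", scoring$type, "_",
                paste(range(scoring$matrix), collapse = "_"))
  if (!is.null(.allodiv_cache[[key]])) return(.allodiv_cache[[key]])
  m <- scoring$matrix
  letters <- if (scoring$type == "dna") DNA_BASES
    else setdiff(rownames(m), c("B", "Z", "X", "*"))
  s <- m[letters, letters]
  p <- 1 / length(letters)
  f <- function(lam) sum(p * p * exp(lam * s)) - 1
  lam <- uniroot(f, c(1e-4, 10), tol = 1e-10)$root
  .allodiv_cache[[key]] <- lam
  lam
}

KA_K <- 0.1  # conventional magnitude; only lambda is solved for

ka_evalue <- function(score, m, n, lambda) KA_K * m * n * exp(-lambda * score)

# One round of local (Smith-Waterman) alignment; returns an HSP row or NULL.
local_hsp_once <- function(q, s, scoring) {
  pa <- try(Biostrings::pairwiseAlignment(
    xstring(q, scoring$type), xstring(s, scoring$type),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "local"), silent = TRUE)
  if (inherits(pa, "try-error")) return(NULL)
  sc <- Biostrings::score(pa)
  if (!is.finite(sc) || sc <= 0) return(NULL)
  pat <- Biostrings::pattern(pa); sub <- Biostrings::subject(pa)
  aligned_len <- nchar(as.character(pat))
  data.frame(q_start = Biostrings::start(pat) - 1L,
             q_end = Biostrings::end(pat),
             s_start = Biostrings::start(sub) - 1L,
             s_end = Biostrings::end(sub),
             score = sc,
             identities = Biostrings::nmatch(pa),
             aligned_len = aligned_len)
}

mask_region <- function(s, start0, end, type) {
  fill <- if (type == "dna") "N" else "X"
  paste0(substr(s, 1, start0), strrep(fill, end - start0),
         substr(s, end + 1, nchar(s)))
}

# All HSPs for a query/subject pair: iterated local alignment, masking each
# found segment on both axes (greedy, highest score first).
local_hsps <- function(q, s, scoring, lambda, e_max, max_hsps = 4) {
  hsps <- NULL
  m <- nchar(q); n <- nchar(s)
  for (i in seq_len(max_hsps)) {
    h <- local_hsp_once(q, s, scoring)
    if (is.null(h)) break
    if (ka_evalue(h$score, m, n, lambda) > e_max) break
    hsps <- rbind(hsps, h)
    q <- mask_region(q, h$q_start, h$q_end, scoring$type)
    s <- mask_region(s, h$s_start, h$s_end, scoring$type)
  }
  hsps
}

interval_union_len <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) { tot <- tot + cur_e - cur_s
      cur_s <- starts[i]; cur_e <- ends[i]
    } else cur_e <- max(cur_e, ends[i])
  }
  tot + cur_e - cur_s
}

# For long DNA subjects, narrow the search to the best k-mer-seeded window.
seed_window <- function(q, s, k = 12, margin = NULL) {
  if (is.null(margin)) margin <- nchar(q)
  qk <- substring(q, 1:(nchar(q) - k + 1), k:nchar(q))
  pd <- try(Biostrings::matchPDict(
    Biostrings::PDict(Biostrings::DNAStringSet(qk)),
    Biostrings::DNAString(s)), silent = TRUE)
  if (inherits(pd, "try-error")) return(NULL)
  sl <- Biostrings::startIndex(pd)
  hit_q <- rep(seq_along(sl), lengths(sl))
  if (length(hit_q) == 0) return(NULL)
  hit_s <- unlist(sl, use.names = FALSE)
  diag <- hit_s - hit_q
  dmode <- as.numeric(names(which.max(table(round(diag / 50)))))
  keep <- abs(diag / 50 - dmode) <= 2
  lo <- max(1, min(hit_s[keep]) - margin)
  hi <- min(nchar(s), max(hit_s[keep]) + k + margin)
  list(start0 = lo - 1L, seq = substr(s, lo, hi))
}

#' Local similarity search of query sequences against subject sequences
#'
#' Smith-Waterman HSPs per qualifying query/subject pair (a shared k-mer
#' prefilter skips unrelated pairs), with ungapped Karlin-Altschul E-values;
#' hits with E-value above `e_max` are dropped.  Hits are ordered per query by
#' descending best score, ties broken by subject id.
#'
#' @param queries,subjects named character vectors or `XStringSet`s.
#' @param scoring a [scoring_scheme()].
#' @param e_max E-value cutoff (> 0), default 1e-3.
#' @param k k-mer length of the prefilter (default 5 for protein, 12 for
#'   DNA); `min_shared` shared k-mers are required to attempt an alignment.
#' @param min_shared minimum shared k-mers (default 1).
#' @param max_hsps maximum HSPs recorded per pair.
#' @return data.frame of hits (`query_id`, `subject_id`, `best_score`,
#'   `identity_pct`, `q_coverage`, `s_coverage`, `e_value`, `n_hsps`) with
#'   attribute `"hsps"`: per-HSP table in 0-based half-open coordinates.
#' @export
local_search <- function(queries, subjects, scoring = scoring_scheme("dna"),
                         e_max = 1e-3, k = NULL, min_shared = 1,
                         max_hsps = 4) {
  if (e_max <= 0) stopf("e_max must be > 0")
  queries <- as_seq_chr(queries); subjects <- as_seq_chr(subjects)
  if (length(queries) == 0 || length(subjects) == 0)
    stopf("query and subject sets must be non-empty")
  if (is.null(k)) k <- if (scoring$type == "dna") 12 else 5
  lambda <- ka_lambda(scoring)
  subj_kmers <- lapply(subjects, kmers, k = k)
  sk_pool <- unlist(subj_kmers, use.names = FALSE)
  sk_owner <- rep(seq_along(subjects), lengths(subj_kmers))
  hits <- list(); hsp_rows <- list()
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]; qid <- seq_ids(queries)[qi]
    qk <- kmers(q, k)
    shared <- tabulate(sk_owner[sk_pool %in% qk],
                       nbins = length(subjects))
    cand <- which(shared >= min_shared)
    rows <- list()
    for (si in cand) {
      s <- subjects[[si]]; sid <- seq_ids(subjects)[si]
      s_off <- 0L; s_use <- s
      if (scoring$type == "dna" && nchar(s) > 20000) {
        w <- seed_window(q, s, k = k)
        if (is.null(w)) next
        s_off <- w$start0; s_use <- w$seq
      }
      h <- local_hsps(q, s_use, scoring, lambda, e_max, max_hsps)
      if (is.null(h)) next
      h$s_start <- h$s_start + s_off; h$s_end <- h$s_end + s_off
      best <- which.max(h$score)
      rows[[length(rows) + 1]] <- data.frame(
        query_id = qid, subject_id = sid,
        best_score = h$score[best],
        identity_pct = 100 * h$identities[best] / h$aligned_len[best],
        q_coverage = interval_union_len(h$q_start, h$q_end) / nchar(q),
        s_coverage = interval_union_len(h$s_start, h$s_end) / nchar(s),
        e_value = ka_evalue(h$score[best], nchar(q), nchar(s), lambda),
        n_hsps = nrow(h))
      h$query_id <- qid; h$subject_id <- sid
      hsp_rows[[length(hsp_rows) + 1]] <- h
    }
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      tab <- tab[order(-tab$best_score, tab$subject_id), , drop = FALSE]
      hits[[length(hits) + 1]] <- tab
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(0), subject_id = character(0),
               best_score = numeric(0), identity_pct = numeric(0),
               q_coverage = numeric(0), s_coverage = numeric(0),
               e_value = numeric(0), n_hsps = integer(0))
  rownames(out) <- NULL
  attr(out, "hsps") <- if (length(hsp_rows)) do.call(rbind, hsp_rows) else NULL
  out
}
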