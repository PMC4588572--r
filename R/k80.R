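# Kimura (1980) two-parameter substitution process.
#
# Rates are scaled so that one unit of branch length d equals one expected
# substitution per site: transition rate alpha = kappa / (kappa + 2), each
# transversion rate beta = 1 / (kappa + 2), alpha + 2 beta = 1.

#' Parameters of the K80 evolution process
#'
#' @param d_target expected substitutions per site along the branch (>= 0).
#' @param kappa transition/transversion rate ratio (> 0), default 2.
#' @param coding_constraint if TRUE the sequence is treated as coding and only
#'   third positions of fourfold-degenerate codons are evolved (purely
#'   synonymous proposals); `d_target` then applies to those sites.
#' @param seed integer RNG seed or NULL to use the current stream.
#' @return an object of class `evolve_params`.
#' @export
evolve_params <- function(d_target, kappa = 2, coding_constraint = FALSE,
                          seed = NULL) {
  if (!is.numeric(kappa) || kappa <= 0) stopf("kappa must be > 0")
  if (!is.numeric(d_target) || d_target < 0) stopf("d_target must be >= 0")
  structure(list(d_target = d_target, kappa = kappa,
                 coding_constraint = coding_constraint, seed = seed),
            class = "evolve_params")
}

# Per-site substitution probabilities after branch length d:
# same / transition / each transversion.  Closed-form K80 transition matrix.
k80_probs <- function(d, kappa = 2) {
  beta <- 1 / (kappa + 2)
  e1 <- exp(-4 * beta * d)           # 4*beta = 4/(kappa+2)
  e2 <- exp(-2 * (1 + kappa) * beta * d)  # 2*(alpha+beta)
  p_tv <- 0.25 - 0.25 * e1           # each of the two transversions
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

# Expected proportion of mismatched sites between two ends of a path of total
# K80 length d (used to calibrate generator branch lengths).
k80_mismatch <- function(d, kappa = 2) {
  p <- k80_probs(d, kappa)
  unname(p["ts"] + 2 * p["tv"])
}

# transition partner for base index in A,C,G,T encoding: A<->G, C<->T
.TS_PARTNER <- c(3L, 4L, 1L, 2L)
.TV_PARTNERS <- matrix(c(2L, 4L,   # A -> C,T
                         1L, 3L,   # C -> A,G
                         2L, 4L,   # G -> C,T
                         1L, 3L),  # T -> A,G
                       nrow = 4, byrow = TRUE)

# Core sampler on integer base codes (1=A,2=C,3=G,4=T); vectorized per site.
evolve_base_codes <- function(codes, d, kappa = 2) {
  if (d == 0 || length(codes) == 0) return(codes)
  p <- k80_probs(d, kappa)
  u <- runif(length(codes))
  ts <- u < p["ts"]
  tv1 <- !ts & u < p["ts"] + p["tv"]
  tv2 <- !ts & !tv1 & u < p["ts"] + 2 * p["tv"]
  out <- codes
  if (any(ts))  out[ts]  <- .TS_PARTNER[codes[ts]]
  if (any(tv1)) out[tv1] <- .TV_PARTNERS[cbind(codes[tv1], 1L)]
  if (any(tv2)) out[tv2] <- .TV_PARTNERS[cbind(codes[tv2], 2L)]
  out
}

seq_to_codes <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
codes_to_seq <- function(codes) paste(DNA_BASES[codes], collapse = "")

#' Evolve a DNA sequence under the K80 model
#'
#' Each site's end state is drawn from the exact K80 transition-probability
#' matrix at branch length `d_target`, so multiple hits per site are implicit
#' and the K2P estimator applied to (ancestor, descendant) pairs is consistent
#' for `d_target`.
#'
#' @param seq a single DNA string (or length-1 `DNAStringSet`/`DNAString`).
#' @param params an [evolve_params()] object.
#' @return the mutated sequence as a character string, with attribute
#'   `"events"` holding realized transition/transversion counts.
#' @export
evolve_sequence <- function(seq, params) {
  stopifnot(inherits(params, "evolve_params"))
  s <- if (inherits(seq, "XString")) as.character(seq) else as_seq_chr(seq)[1]
  if (!nzchar(s)) stopf("sequence must be non-empty")
  codes <- seq_to_codes(s)
  if (anyNA(codes)) stopf("sequence must be plain A/C/G/T DNA")
  run <- function() {
    if (params$coding_constraint) {
      idx <- fourfold_third_positions(codes)
      new_codes <- codes
      new_codes[idx] <- evolve_base_codes(codes[idx], params$d_target,
                                          params$kappa)
    } else {
      new_codes <- evolve_base_codes(codes, params$d_target, params$kappa)
    }
    new_codes
  }
  new_codes <- if (is.null(params$seed)) run() else with_seed(params$seed, run())
  changed <- which(new_codes != codes)
  is_ts <- .TS_PARTNER[codes[changed]] == new_codes[changed]
  out <- codes_to_seq(new_codes)
  attr(out, "events") <- c(transitions = sum(is_ts),
                           transversions = sum(!is_ts))
  out
}

# Solve for the total path length (substitutions per evolved site) whose
# expected corrected estimate equals `target`.  `correct` maps an expected
# mismatch proportion to the estimator's output (e.g. Jukes-Cantor).
calibrate_distance <- function(target, kappa = 2,
                               transform = function(q) q,
                               upper = 5) {
  if (target <= 0) return(0)
  f <- function(d) transform(k80_mismatch(d, kappa)) - target
  uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}
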