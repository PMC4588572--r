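#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's RNG stream. All randomness in the package flows through this.
#'
#' @param seed integer seed (< 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a deterministic sub-seed from (seed, entity tag) so that generator
# internals do not depend on the order entities are drawn in.
sub_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(paste0(tag))) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

DNA_BASES <- c("A", "C", "G", "T")

# random DNA as a single string
random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# coerce DNAStringSet / named character to named character vector
as_seq_chr <- function(x) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else if (is.character(x)) x
  else stopf("expected a character vector or XStringSet, got %s", class(x)[1])
}

seq_ids <- function(x) {
  nm <- names(x)
  if (is.null(nm)) stopf("sequence set must be named")
  nm
}

fmt_id <- function(prefix, i) sprintf("%s_g%04d", prefix, i)
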