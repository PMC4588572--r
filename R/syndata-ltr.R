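# Synthetic LTR retroelements with known insertion ages.

#' Generate LTR elements of known age
#'
#' Each element starts from a random ancestral LTR; the left and right copies
#' are identical at insertion and each evolves independently under K80 for
#' the element's age at rate `r`, so the expected inter-LTR distance is
#' 2 r x age.  Ages are drawn from the supplied mixture.  Elements are laid
#' head-to-tail along one synthetic chromosome (an `internal_len` spacer
#' between the repeats mimics the element body).
#'
#' @param n number of elements.
#' @param age_mix data.frame with `age_years` and `weight` (weights are
#'   normalized); all ages >= 0.
#' @param r substitution rate per site per year (> 0), default 2.6e-9.
#' @param ltr_len LTR length in bp (>= 50; shorter repeats make the distance
#'   estimate unstable).
#' @param internal_len internal-region length in bp (default 5000).
#' @param kappa K80 transition/transversion ratio.
#' @param seed integer RNG seed.
#' @return an [ltr_set()] whose `meta` carries `true_age_years`.
#' @export
gen_ltr_elements <- function(n, age_mix, r = 2.6e-9, ltr_len = 2000,
                             internal_len = 5000, kappa = 2, seed = 1) {
  if (ltr_len < 50) stopf("ltr_len must be >= 50")
  if (!is.numeric(r) || r <= 0) stopf("rate r must be > 0")
  if (any(age_mix$age_years < 0)) stopf("ages must be >= 0")
  if (any(age_mix$weight < 0) || sum(age_mix$weight) <= 0)
    stopf("mixture weights must be non-negative and sum > 0")
  res <- with_seed(seed, {
    ages <- age_mix$age_years[sample.int(nrow(age_mix), n, replace = TRUE,
                                         prob = age_mix$weight)]
    left <- character(n); right <- character(n)
    for (i in seq_len(n)) {
      anc <- random_dna(ltr_len)
      d <- r * ages[i]
      left[i] <- as.character(evolve_sequence(anc, evolve_params(d, kappa)))
      right[i] <- as.character(evolve_sequence(anc, evolve_params(d, kappa)))
    }
    list(ages = ages, left = left, right = right)
  })
  span <- 2 * ltr_len + internal_len
  starts <- (seq_len(n) - 1) * (span + 1000) + 1
  ids <- sprintf("ltr_%04d", seq_len(n))
  meta <- data.frame(element_id = ids, chrom = "chrV", start = starts,
                     end = starts + span - 1, strand = "+",
                     true_age_years = res$ages)
  ltr_set(meta,
          Biostrings::DNAStringSet(setNames(res$left, ids)),
          Biostrings::DNAStringSet(setNames(res$right, ids)))
}
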