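# Parameter-recovery experiments: each runs a generator with known ground
# truth through the corresponding analysis stage and measures how well the
# truth is recovered.  These back the package's validation suite and the
# acceptance report; sizes default to the calibration conditions described
# in the methods vignette.

#' Ks-peak recovery experiment
#'
#' Simulates an allotetraploid gene complement with species and subgenome
#' divergences at the target Ks values, estimates per-pair Ks with NG86 and
#' locates the modal 0.001-wide bin of each distribution.  Sequence length
#' defaults to 15,000 codons so that the per-pair sampling error
#' (SD ~ sqrt(Ks/S)) is small against the bin width; see the vignette.
#'
#' @param n_pairs homoeolog pairs to simulate (default 500).
#' @param n_codons codons per gene.
#' @param ks_ad,ks_species Ks targets for the subgenome (At:Dt) and species
#'   (Gb:Gh) splits.
#' @param bin_width histogram bin width (default 0.001).
#' @param seed RNG seed.
#' @return list: `peak_ad`, `peak_species` (modal bin midpoints), `ks_ad`,
#'   `ks_species` (per-pair estimates).
#' @export
exp_ks_peak_recovery <- function(n_pairs = 500, n_codons = 15000,
                                 ks_ad = 0.04, ks_species = 0.005,
                                 bin_width = 0.001, seed = 1) {
  sim <- gen_allopolyploid(
    divergence_schedule(AD = ks_ad, GbGh = ks_species),
    n_genes = n_pairs, n_codons = n_codons, seed = seed)
  at <- as.character(sim$sets$At)
  dt <- as.character(sim$sets$Dt)
  gh <- as.character(sim$sets$GhAt)
  ks1 <- vapply(seq_len(n_pairs), function(i)
    ng86(as_codon_alignment(at[i], dt[i]))$Ks, 0)
  ks2 <- vapply(seq_len(n_pairs), function(i)
    ng86(as_codon_alignment(at[i], gh[i]))$Ks, 0)
  list(peak_ad = find_peak(ks_histogram(ks1, bin_width)),
       peak_species = find_peak(ks_histogram(ks2, bin_width)),
       ks_ad = ks1, ks_species = ks2)
}

#' LTR insertion-age recovery experiment
#'
#' Simulates elements at the given true ages (equal mixture), dates each
#' from its inter-LTR K2P divergence and detects bursts in the pooled age
#' distribution.
#'
#' @param ages_years true insertion ages (default 1, 5 and 12 Myr).
#' @param n_per_age elements per age component (default 200).
#' @param ltr_len LTR length in bp (default 2000).
#' @param r substitution rate per site per year.
#' @param bin_years age-histogram bin width.
#' @param seed RNG seed.
#' @return list: `mean_age` (named by true age, years), `rel_error`,
#'   `bursts` (data.frame), `ages` (per-element table with truth).
#' @export
exp_ltr_age_recovery <- function(ages_years = c(1e6, 5e6, 12e6),
                                 n_per_age = 200, ltr_len = 2000,
                                 r = 2.6e-9, bin_years = 1e6, seed = 1) {
  el <- gen_ltr_elements(
    n = n_per_age * length(ages_years),
    age_mix = data.frame(age_years = ages_years,
                         weight = rep(1, length(ages_years))),
    r = r, ltr_len = ltr_len, seed = seed)
  ages <- ltr_ages(el, r = r)
  ages$true_age <- el$meta$true_age_years
  mean_age <- tapply(ages$age_years[ages$dated],
                     ages$true_age[ages$dated], mean)
  dist <- age_distribution(ages$age_years[ages$dated],
                           bin_years = bin_years)
  list(mean_age = mean_age,
       rel_error = abs(mean_age - as.numeric(names(mean_age))) /
         as.numeric(names(mean_age)),
       bursts = dist$bursts, ages = ages)
}

#' Pseudogene classification recovery experiment
#'
#' Generates pseudogene loci in the three categories (equal mixture),
#' detects them in their intergenic regions, classifies each against its
#' assigned parent and scores category accuracy against the truth.
#'
#' @param n pseudogene loci (default 300).
#' @param n_parents parent genes in the synthetic gene set.
#' @param ks divergence of the copies to their parents.
#' @param seed RNG seed.
#' @return list: `accuracy` (fraction of detected loci with the true
#'   category), `detected` (fraction detected), `table` (truth x called),
#'   `calls`.
#' @export
exp_pseudo_class_recovery <- function(n = 300, n_parents = 40, ks = 0.08,
                                      seed = 1) {
  models <- gen_gene_models(n_parents, n_exons_range = c(2, 4),
                            seed = sub_seed(seed, "models"))
  ps <- gen_pseudogenes(models, n, ks = ks, seed = sub_seed(seed, "loci"))
  cands <- detect_pseudogenes(ps$intergenic, models$cds)
  cands$category <- vapply(seq_len(nrow(cands)), function(i)
    as.character(classify_pseudogene(
      as.character(ps$intergenic)[[cands$region_id[i]]],
      exon_cds_segments(models, cands$parent_gene_id[i]))), "")
  truth <- ps$truth$category[match(cands$region_id, ps$truth$region_id)]
  list(accuracy = mean(cands$category == truth),
       detected = nrow(cands) / n,
       table = table(truth = truth, called = cands$category),
       calls = cands)
}

#' BBH homoeolog recovery experiment
#'
#' Simulates homoeolog pairs at the subgenome divergence, runs the BBH
#' identification on the translated proteins under the 30%/30% rules and
#' scores recovery of the true pairing.
#'
#' @param n_pairs homoeolog pairs (default 500).
#' @param n_codons codons per gene (default 400).
#' @param ks_ad Ks of the subgenome split (default 0.04).
#' @param omega Ka/Ks of the simulated genes (default 0.2).
#' @param seed RNG seed.
#' @return list: `recovery` (fraction of true pairs recovered), `pairs`,
#'   `truth`.
#' @export
exp_bbh_recovery <- function(n_pairs = 500, n_codons = 400, ks_ad = 0.04,
                             omega = 0.2, seed = 1) {
  sim <- gen_allopolyploid(divergence_schedule(AD = ks_ad, GbGh = NULL),
                           n_genes = n_pairs, n_codons = n_codons,
                           omega = omega, seed = seed)
  prot <- function(s) {
    x <- as.character(s)
    p <- vapply(x, function(z) translate_cds(prep_cds(z)), "")
    names(p) <- names(x)
    p
  }
  pairs <- bbh_pairs(prot(sim$sets$At), prot(sim$sets$Dt))
  found <- paste(pairs$gene_a_id, pairs$gene_d_id)
  truth <- paste(sim$truth$gene_a_id, sim$truth$gene_d_id)
  list(recovery = mean(truth %in% found), pairs = pairs,
       truth = sim$truth)
}

#' Differential-expression error-control and power experiment
#'
#' Null run: all fold changes 1; the empirical FDR among significant calls
#' must respect the nominal 0.001 (every call would be false).  Power run:
#' a block of genes at the given fold change and adequate depth must be
#' recovered.
#'
#' @param n_genes genes in each run (default 2000 null, with `n_de` true
#'   positives in the power run).
#' @param n_de DE genes in the power run.
#' @param fold fold change of the DE genes (default 4).
#' @param seed RNG seed.
#' @return list: `null_calls`, `null_fdr`, `power`.
#' @export
exp_de_error_control <- function(n_genes = 2000, n_de = 200, fold = 4,
                                 seed = 1) {
  a <- paste0("fiber_r", 1:3); b <- paste0("leaf_r", 1:3)
  nullsim <- gen_counts(n_genes, fold_change = 1, dispersion = 0,
                        seed = sub_seed(seed, "null"))
  de0 <- call_de(nullsim$mat, a, b)
  n_called <- sum(de0$significant)
  pw <- gen_counts(n_genes,
                   fold_change = c(rep(fold, n_de),
                                   rep(1, n_genes - n_de)),
                   base_mean_range = c(50, 300), dispersion = 0,
                   seed = sub_seed(seed, "power"))
  de1 <- call_de(pw$mat, a, b)
  list(null_calls = n_called,
       null_fdr = if (n_called == 0) 0 else 1,
       power = mean(de1$significant[seq_len(n_de)]))
}
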