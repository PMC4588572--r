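# RPKM, exact-binomial DE calling, preferential genes, bias, contrasts.

mk_mat <- function(counts, len = NULL, lib = NULL, meta = NULL) {
  if (is.null(len)) len <- setNames(rep(1000, nrow(counts)),
                                    rownames(counts))
  expression_matrix(counts, len, lib, meta)
}

test_that("rpkm implements the definition and its linearity", {
  m <- expression_matrix(
    matrix(c(10, 0), 1, 2, dimnames = list("g1", c("s1", "s2"))),
    c(g1 = 2000), lib_size = c(1e6, 1e6))
  expect_equal(rpkm(m)[1, ], c(s1 = 5, s2 = 0))
  m2 <- expression_matrix(
    matrix(c(10, 0), 1, 2, dimnames = list("g1", c("s1", "s2"))),
    c(g1 = 2000), lib_size = c(2e6, 2e6))
  expect_equal(rpkm(m2), rpkm(m) / 2)
  expect_error(expression_matrix(
    matrix(5, 1, 1, dimnames = list("g", "s")), c(g = 100),
    lib_size = 0), "lib_size")
})

test_that("call_de matches the exact binomial oracle", {
  counts <- matrix(c(100, 50, 0, 50), 2, 2,
                   dimnames = list(c("gDE", "gEq"), c("a1", "b1")))
  m <- mk_mat(counts, lib = c(1e5, 1e5))
  de <- call_de(m, "a1", "b1")
  # (100, 0) at equal libraries: two-sided doubling of (1/2)^100
  expect_equal(de$p_value[de$gene_id == "gDE"], 2 * 0.5^100)
  expect_true(de$significant[de$gene_id == "gDE"])
  expect_equal(de$p_value[de$gene_id == "gEq"], 1)
  expect_false(de$significant[de$gene_id == "gEq"])
  # equal counts, equal libraries: zero log ratio
  expect_equal(de$log2_ratio[de$gene_id == "gEq"], 0)
  # all-zero gene is defined, not an error
  z <- mk_mat(matrix(0, 1, 2, dimnames = list("g0", c("a1", "b1"))),
              lib = c(1e5, 1e5))
  dz <- call_de(z, "a1", "b1")
  expect_equal(dz$p_value, 1)
  expect_equal(dz$log2_ratio, 0)
  expect_error(call_de(m, character(0), "b1"), "non-empty")
})

test_that("lowering fdr_max never adds significant genes", {
  g <- gen_counts(400, fold_change = sample(c(1, 4), 400, replace = TRUE),
                  dispersion = 0, seed = 81)
  a <- paste0("fiber_r", 1:3); b <- paste0("leaf_r", 1:3)
  loose <- call_de(g$mat, a, b, fdr_max = 0.01)
  strict <- call_de(g$mat, a, b, fdr_max = 0.0001)
  expect_true(all(loose$significant[strict$significant]))
})

test_that("null simulation controls the empirical FDR", {
  g <- gen_counts(2000, fold_change = 1, dispersion = 0, seed = 82)
  de <- call_de(g$mat, paste0("fiber_r", 1:3), paste0("leaf_r", 1:3))
  n_called <- sum(de$significant)
  # every gene is null, so any call is a false discovery
  fdr_obs <- if (n_called == 0) 0 else 1
  se <- sqrt(0.001 * 0.999 / 2000)
  expect_lte(fdr_obs, 0.001 + 3 * se)
})

test_that("preferential genes need both significance and the maximum", {
  set.seed(83)
  counts <- rbind(
    gFib = c(500, 480, 5, 6, 4, 6),     # high in fiber only
    gFlat = c(100, 110, 95, 105, 100, 98),
    gOv  = c(5, 6, 700, 680, 4, 5))     # high in ovule
  colnames(counts) <- c("fiber_r1", "fiber_r2", "ovule_r1", "ovule_r2",
                        "leaf_r1", "leaf_r2")
  meta <- data.frame(sample = colnames(counts),
                     tissue = rep(c("fiber", "ovule", "leaf"), each = 2))
  m <- mk_mat(counts, meta = meta)
  pref <- preferential_genes(m, "fiber")
  expect_true("gFib" %in% pref)
  expect_false("gFlat" %in% pref)
  expect_false("gOv" %in% pref)   # highest in ovule, tested for fiber
  one_tissue <- mk_mat(counts[, 1:2, drop = FALSE],
                       meta = meta[1:2, , drop = FALSE])
  expect_error(preferential_genes(one_tissue, "fiber"), "tissues")
})

test_that("homoeolog bias calls reflect the simulated ratio", {
  counts <- rbind(at1 = c(500, 520), dt1 = c(10, 9),
                  at2 = c(100, 104), dt2 = c(98, 102))
  colnames(counts) <- c("s1", "s2")
  m <- mk_mat(counts)
  pairs <- data.frame(gene_a_id = c("at1", "at2"),
                      gene_d_id = c("dt1", "dt2"))
  hb <- homoeolog_bias(pairs, m)
  expect_equal(hb$bias, c("At_biased", "balanced"))
  # missing member: skipped with a warning
  pairs2 <- rbind(pairs, data.frame(gene_a_id = "atX", gene_d_id = "dtX"))
  expect_warning(hb2 <- homoeolog_bias(pairs2, m), "skipped")
  expect_equal(nrow(hb2), 2)
})

test_that("bias truth recovery on simulated biased pairs", {
  set.seed(84)
  n <- 60; biased <- seq_len(18)   # 30% of pairs At-biased (4-fold)
  base <- exp(runif(n, log(50), log(300)))
  at <- t(vapply(seq_len(n), function(i)
    rpois(4, base[i] * if (i %in% biased) 4 else 1), numeric(4)))
  dt <- t(vapply(seq_len(n), function(i) rpois(4, base[i]), numeric(4)))
  counts <- rbind(at, dt)
  rownames(counts) <- c(sprintf("At_%03d", 1:n), sprintf("Dt_%03d", 1:n))
  colnames(counts) <- paste0("s", 1:4)
  m <- mk_mat(counts)
  pairs <- data.frame(gene_a_id = sprintf("At_%03d", 1:n),
                      gene_d_id = sprintf("Dt_%03d", 1:n))
  hb <- homoeolog_bias(pairs, m)
  truth <- ifelse(seq_len(n) %in% biased, "At_biased", "balanced")
  expect_gte(mean(hb$bias == truth), 0.90)
})

test_that("ltr expression contrast detects a constructed suppression", {
  set.seed(85)
  n <- 300
  flagged <- rep(c(TRUE, FALSE), each = n / 2)
  mu <- ifelse(flagged, 40, 80)
  counts <- cbind(rpois(n, mu), rpois(n, mu))
  rownames(counts) <- sprintf("g%03d", 1:n)
  colnames(counts) <- c("s1", "s2")
  m <- mk_mat(counts)
  ct <- ltr_expression_contrast(m, setNames(flagged, rownames(counts)),
                                n_perm = 2000, seed = 86)
  expect_lt(ct$mean_flagged, ct$mean_unflagged)
  expect_lt(ct$p_value, 0.05)
  expect_error(ltr_expression_contrast(
    m, setNames(rep(FALSE, n), rownames(counts))), "strata")
})
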