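test_that("RPKM follows the formula and a spreadsheet-style recomputation", {
  counts <- matrix(c(10, 0, 5, 20, 2, 8), 2, 3)
  rownames(counts) <- c("g1", "g2")
  # count 10, length 2000 bp, libsize 1e6 -> RPKM 5
  expect_equal(rpkm(matrix(10, 1, 1), 2000, 1e6)[1, 1], 5.0)
  expect_equal(rpkm(matrix(0, 1, 1), 500, 1e6)[1, 1], 0)

  set.seed(6)
  cm <- matrix(rpois(15, 40), 5, 3)
  len <- c(500, 1000, 1500, 2000, 2500)
  lib <- c(1e6, 2e6, 4e6)
  got <- rpkm(cm, len, lib)
  for (i in 1:5) for (j in 1:3) {
    expect_equal(got[i, j], cm[i, j] / ((len[i] / 1000) * (lib[j] / 1e6)))
  }
  expect_error(rpkm(cm, len, c(0, 1, 1)), "library")
})

test_that("expression filtering applies a strict threshold on group means", {
  r <- rbind(a = c(1.2, 1.2, 0.3, 0.3),
             b = c(0.9, 0.9, 0.9, 0.9),
             c = c(1.0, 1.0, 1.0, 1.0),
             d = c(0.1, 0.1, 5.0, 5.0))
  groups <- c("RS-F", "RS-F", "C-F", "C-F")
  kept <- filter_expressed(r, groups, c("RS-F", "C-F"), threshold = 1)
  expect_setequal(kept, c("a", "d")) # (1.2, 0.3) kept; (0.9, 0.9) and exact 1.0 dropped
  expect_error(filter_expressed(r, groups, c("RS-F", "RS-NF")), "no samples")
})

test_that("unpaired DE keeps direction bookkeeping honest and handles flat genes", {
  cfg <- count_sim_config(n_genes = 400, responder_fraction = 1, seed = 31)
  sim <- simulate_counts(cfg)
  groups <- sim$sample_meta$group
  counts <- sim$counts
  counts["gene_00001", ] <- 0 # all-zero gene convention
  tab <- de_unpaired(counts, groups, gene_lengths = sim$gene_lengths)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$log2fc[tab$direction == "up"] > 0))
  expect_true(all(tab$log2fc[tab$direction == "down"] < 0))
  z <- tab[tab$gene == "gene_00001", ]
  expect_equal(z$p, 1)
  expect_equal(z$log2fc, 0)
  # swapping the contrast flips every sign (to GLM solver tolerance)
  tab_sw <- de_unpaired(counts, groups, numerator = "C-F", denominator = "RS-F")
  expect_equal(tab$log2fc, -tab_sw$log2fc, tolerance = 1e-4)
  expect_error(de_unpaired(counts[, 1:2], groups[1:2]), "two samples")
})

test_that("planted strong effects are recovered by the unpaired test", {
  cfg <- count_sim_config(n_genes = 600, responder_fraction = 1, seed = 32)
  sim <- simulate_counts(cfg)
  tab <- de_unpaired(sim$counts, sim$sample_meta$group)
  truth_up <- sim$truth$degs_criteria_i_up
  sub <- tab[tab$gene %in% truth_up, ]
  expect_gt(mean(sub$p < 0.05 & sub$direction == "up"), 0.85)
})

test_that("paired DE needs pairs, rejects ambiguity, and sees identical pairs as null", {
  cfg <- count_sim_config(n_genes = 120, seed = 33)
  sim <- simulate_counts(cfg)
  meta <- sim$sample_meta
  expect_error(
    de_paired(sim$counts[, 1:6], rep(c("RS-F", "RS-NF"), 3),
              c("f1", "f1", "f2", "f2", "f3", "f4")),
    "three complete pairs"
  )
  expect_error(
    de_paired(sim$counts[, 1:4], rep(c("RS-F", "RS-NF"), each = 2),
              rep("f1", 4)),
    "ambiguous"
  )
  # identical RS-F and RS-NF columns: exact null, nothing at FDR < 0.1
  base <- sim$counts[, meta$group == "C-F"][, 1:4]
  counts <- cbind(base, base)
  colnames(counts) <- paste0("s", 1:8)
  tab <- suppressWarnings(
    de_paired(counts, rep(c("RS-F", "RS-NF"), each = 4), rep(paste0("f", 1:4), 2))
  )
  expect_equal(sum(tab$fdr < 0.1), 0)
})

test_that("overlap and concordance match manual set arithmetic", {
  mk <- function(genes, lfc, p, fdr, criteria) {
    tibble::tibble(gene = genes, log2fc = lfc, p = p, fdr = fdr,
                   direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
                   criteria = criteria)
  }
  genes <- paste0("g", 1:10)
  lfc_i <- c(2, 2, -2, -2, 0.5, 0, 1, -1, 3, -3)
  p_i <- c(0.01, 0.2, 0.01, 0.01, 0.01, 0.9, 0.04, 0.6, 0.001, 0.03)
  t_i <- mk(genes, lfc_i, p_i, p.adjust(p_i, "BH"), "i")
  lfc_ii <- c(1.5, 1, -1, 2, 1, 0, 2, -2, 2.5, -2.5)
  fdr_ii <- c(0.05, 0.05, 0.05, 0.5, 0.5, 0.9, 0.05, 0.05, 0.01, 0.01)
  t_ii <- mk(genes, lfc_ii, p_i, fdr_ii, "ii")
  ov <- overlap_and_concordance(t_i, t_ii)
  # common up (p_i < 0.05, fdr_ii < 0.1, both up): g1, g7, g9; down: g3, g10
  expect_equal(ov$common_up, 3)
  expect_equal(ov$common_down, 2)
  union_sel <- (p_i < 0.05) | (fdr_ii < 0.1)
  expect_equal(ov$r, cor(lfc_i[union_sel], lfc_ii[union_sel]))

  self <- overlap_and_concordance(t_i, mk(genes, lfc_i, p_i, p_i, "ii"))
  expect_equal(self$r, 1)
  disj <- overlap_and_concordance(
    mk(genes[1:5], rep(2, 5), rep(0.01, 5), rep(0.01, 5), "i"),
    mk(genes[1:5], rep(2, 5), rep(0.9, 5), rep(0.9, 5), "ii")
  )
  expect_equal(disj$common_up, 0)
  expect_equal(disj$common_down, 0)
})

test_that("BH adjustment is monotone in p-rank in every DEG table", {
  cfg <- count_sim_config(n_genes = 300, seed = 35)
  sim <- simulate_counts(cfg)
  tab <- de_unpaired(sim$counts, sim$sample_meta$group)
  ord <- order(tab$p)
  expect_true(all(diff(tab$fdr[ord]) >= -1e-12))
})

test_that("responder heterogeneity degrades criteria-(i) sensitivity monotonically", {
  sens <- vapply(c(1, 0.5, 0.25), function(rf) {
    cfg <- count_sim_config(n_genes = 500, responder_fraction = rf, seed = 404)
    sim <- simulate_counts(cfg)
    tab <- de_unpaired(sim$counts, sim$sample_meta$group)
    truth <- c(sim$truth$degs_criteria_i_up, sim$truth$degs_criteria_i_down)
    mean(truth %in% tab$gene[tab$p < 0.05])
  }, numeric(1))
  expect_true(all(diff(sens) < 0))
})

test_that("expression PCA decomposes variance and flags rank-1 structure", {
  set.seed(41)
  base <- matrix(2^rnorm(200, 5), 50, 4)
  r <- base
  pca <- pca_expression(r, c("RS-F", "RS-F", "C-F", "C-F"))
  expect_equal(sum(pca$var_frac), 1)
  expect_true(all(pca$var_frac >= 0))
  expect_equal(nrow(pca$scores), 4)

  # rank-1 matrix: PC1 carries everything
  v <- rnorm(30); w <- abs(rnorm(6)) * 4
  r1 <- 2^(outer(v, w)) # log2 scale rank-1 (plus the +1 offset distortion)
  pca1 <- pca_expression(r1, rep(c("a", "b"), 3))
  expect_gt(pca1$var_frac[1], 0.95)
  expect_error(pca_expression(matrix(1, 5, 3), c("a", "a", "b")), "constant")
})

test_that("hypergeometric enrichment matches exact enumeration and saturates correctly", {
  universe <- paste0("g", 1:20)
  deg <- universe[1:8]
  sets <- list(hit = universe[c(1:4, 10)], miss = universe[15:19])
  res <- enrichment_hypergeometric(deg, sets, universe)
  # exact tail enumeration for the 'hit' set: overlap 4 of set 5, draws 8 of 20
  p_exact <- sum(vapply(4:5, function(k) {
    choose(5, k) * choose(15, 8 - k) / choose(20, 8)
  }, numeric(1)))
  expect_equal(res$p[res$set == "hit"], p_exact, tolerance = 1e-12)

  sat <- enrichment_hypergeometric(universe, sets, universe)
  expect_true(all(sat$p == 1))
  expect_equal(sat$overlap, sat$set_size)
  expect_error(enrichment_hypergeometric(deg, sets, character()), "universe")
})

test_that("planted truth sets rank first in enrichment recovery", {
  set.seed(55)
  wins <- 0L
  for (rep in 1:20) {
    universe <- paste0("g", 1:200)
    planted <- sample(universe, 20)
    deg <- unique(c(sample(planted, 16), sample(setdiff(universe, planted), 10)))
    sets <- c(list(planted = planted),
              purrr::map(1:5, ~ sample(universe, 20)))
    names(sets) <- c("planted", paste0("rand", 1:5))
    res <- enrichment_hypergeometric(deg, sets, universe)
    wins <- wins + (res$set[1] == "planted")
  }
  expect_gte(wins, 19)
})
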