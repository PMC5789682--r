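test_that("fold-change classification follows the ratio contract", {
  m <- matrix(c(10, 10, 10, 10,   # equal means -> fc 1, unchanged
                40, 40, 5, 5,     # 8x under in alt
                2, 2, 16, 16),    # 8x over in alt
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Eq", "Und", "Ovr"), paste0("s", 1:4)))
  em <- ExpressionMatrix(m, groups = c("R", "R", "A", "A"), unit = "FPKM")
  de <- foldChangeDE(em, "R", "A", fc_cutoff = 2, pseudocount = 0)
  expect_equal(de$fc[de$gene == "Eq"], 1)
  expect_equal(de$direction[de$gene == "Eq"], "unchanged")
  expect_equal(de$direction[de$gene == "Und"], "under_in_alt")
  expect_equal(de$direction[de$gene == "Ovr"], "over_in_alt")
  expect_error(foldChangeDE(em, "R", "missing", 2), "missing")
})

test_that("noise-free planted matrix classifies exactly the planted genes", {
  set.seed(7)
  base <- 10^runif(100, 0, 2)
  mu_ref <- base; mu_alt <- base
  under <- 1:10; over <- 11:20
  mu_alt[under] <- base[under] / 4
  mu_alt[over] <- base[over] * 4
  vals <- cbind(mu_ref, mu_ref, mu_alt, mu_alt)
  dimnames(vals) <- list(sprintf("g%03d", 1:100), c("r1", "r2", "a1", "a2"))
  em <- ExpressionMatrix(vals, groups = c("R", "R", "A", "A"), unit = "FPKM")
  pc <- 0.1
  de <- foldChangeDE(em, "R", "A", fc_cutoff = 1.5, pseudocount = pc)
  expect_setequal(de$gene[de$direction != "unchanged"], sprintf("g%03d", 1:20))
  # fc agrees with the direct per-gene arithmetic oracle
  oracle <- (mu_ref + pc) / (mu_alt + pc)
  expect_equal(de$fc, unname(oracle), tolerance = 1e-12)
})

test_that("zero denominators with no pseudocount flag as undefined", {
  vals <- matrix(c(5, 5, 0, 0), 1, dimnames = list("g1", paste0("s", 1:4)))
  em <- ExpressionMatrix(vals, groups = c("R", "R", "A", "A"), unit = "FPKM")
  de <- foldChangeDE(em, "R", "A", fc_cutoff = 2, pseudocount = 0)
  expect_equal(de$direction, "undefined")
  expect_true(is.na(de$fc))
})

test_that("swapping the groups inverts fold changes and direction labels", {
  set.seed(21)
  for (i in 1:10) {
    vals <- matrix(10^runif(40, -1, 2), 10, 4,
                   dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4)))
    em <- ExpressionMatrix(vals, groups = c("R", "R", "A", "A"), unit = "FPKM")
    fwd <- foldChangeDE(em, "R", "A", fc_cutoff = 1.5)
    rev <- foldChangeDE(em, "A", "R", fc_cutoff = 1.5)
    expect_equal(fwd$fc, 1 / rev$fc, tolerance = 1e-12)
    swap <- c(under_in_alt = "over_in_alt", over_in_alt = "under_in_alt",
              unchanged = "unchanged", undefined = "undefined")
    expect_equal(unname(swap[fwd$direction]), rev$direction)
  }
})

test_that("cutoff escalation re-classifies and only ever shrinks the DE set", {
  de <- data.frame(gene = c("a", "b", "c"), mean_ref = 1, mean_alt = 1,
                   fc = c(1.6, 1.9, 2.4), direction = "under_in_alt",
                   p_adj = NA_real_, stringsAsFactors = FALSE)
  attr(de, "fc_cutoff") <- 1.5
  up <- escalateCutoff(de, 2)
  expect_equal(up$gene[up$direction == "under_in_alt"], "c")
  same <- escalateCutoff(de, 1.5)
  expect_equal(same$direction, de$direction)
  expect_error(escalateCutoff(de, 0.9), ">= 1")
  expect_error(escalateCutoff(de, 1.2), "below the active cutoff")
  # subset property on random records
  set.seed(33)
  for (i in 1:20) {
    fc <- 10^runif(30, -1.2, 1.2)
    d0 <- data.frame(gene = sprintf("g%02d", 1:30), fc = fc,
                     direction = crossprio:::classifyDirection(fc, 1.5),
                     stringsAsFactors = FALSE)
    attr(d0, "fc_cutoff") <- 1.5
    d1 <- escalateCutoff(d0, runif(1, 1.5, 4))
    expect_true(all(d1$gene[d1$direction != "unchanged"] %in%
                    d0$gene[d0$direction != "unchanged"]))
  }
})

test_that("TMM factors are 1 under pure depth scaling and match the hand oracle", {
  # B = 2 x A gene-wise: all M-values zero
  cnt <- matrix(c(100L, 200L, 300L, 200L, 400L, 600L), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
  em <- ExpressionMatrix(cnt, groups = c("x", "y"), unit = "counts")
  expect_equal(unname(normFactors(tmmNormalize(em))), c(1, 1))
  # identical samples
  cnt2 <- cbind(a = c(5L, 9L, 14L), b = c(5L, 9L, 14L))
  rownames(cnt2) <- paste0("g", 1:3)
  em2 <- ExpressionMatrix(cnt2, groups = c("x", "y"), unit = "counts")
  expect_equal(unname(normFactors(tmmNormalize(em2))), c(1, 1))
  # 3-gene toy against the precomputed weighted-trimmed-mean hand computation
  # (A = 10,20,80 as reference; B = 30,25,50; no gene trimmed at n = 3)
  toy <- matrix(c(10L, 20L, 80L, 30L, 25L, 50L), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
  emt <- ExpressionMatrix(toy, groups = c("x", "y"), unit = "counts")
  f <- normFactors(tmmNormalize(emt, ref_sample = "a"))
  expect_equal(unname(f["a"]), 1.092357527716488, tolerance = 1e-9)
  expect_equal(unname(f["b"]), 0.915451191232640, tolerance = 1e-9)
  expect_equal(prod(f), 1, tolerance = 1e-12)
  # a sample of all zeros is named in the error
  z <- matrix(c(1L, 2L, 0L, 0L), ncol = 2,
              dimnames = list(c("g1", "g2"), c("ok", "dead")))
  emz <- ExpressionMatrix(z, groups = c("x", "y"), unit = "counts")
  expect_error(tmmNormalize(emz), "dead")
})

test_that("in-package TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(17)
  for (i in 1:5) {
    cnt <- matrix(rnbinom(200 * 4, mu = 10^runif(800, 0.5, 3), size = 8),
                  200, 4, dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
    em <- ExpressionMatrix(cnt, groups = rep(c("x", "y"), 2), unit = "counts")
    mine <- normFactors(tmmNormalize(em, ref_sample = "s1"))
    ref <- edgeR::calcNormFactors(cnt, method = "TMM", refColumn = 1L)
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
  }
})

test_that("TMM factor ratios track a pure depth change in one sample", {
  set.seed(19)
  cnt <- matrix(rnbinom(300, mu = 150, size = 10), 100, 3,
                dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  em1 <- ExpressionMatrix(cnt, groups = c("x", "y", "y"), unit = "counts")
  cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 5L
  em2 <- ExpressionMatrix(cnt2, groups = c("x", "y", "y"), unit = "counts")
  f1 <- normFactors(tmmNormalize(em1, ref_sample = "a"))
  f2 <- normFactors(tmmNormalize(em2, ref_sample = "a"))
  # depth is absorbed by the library size; the composition factors move only
  # through the depth-dependent precision weights (sub-percent effect here)
  expect_equal(unname(f1 / f2), rep(1, 3), tolerance = 0.02)
})

test_that("replicate-based testing flags a strong planted shift and not a null", {
  G <- 800L; dep <- 1:6
  runs <- 5L; hit <- 0L
  for (s in seq_len(runs)) {
    set.seed(400 + s)
    mu <- 10^runif(G, log10(50), log10(2000))
    mu_ko <- mu; mu_ko[dep] <- mu[dep] / 6
    cnt <- cbind(matrix(rnbinom(G * 3, mu = mu, size = 1 / 0.05), G),
                 matrix(rnbinom(G * 3, mu = mu_ko, size = 1 / 0.05), G))
    storage.mode(cnt) <- "integer"
    dimnames(cnt) <- list(sprintf("g%03d", 1:G), paste0("s", 1:6))
    em <- ExpressionMatrix(cnt, groups = rep(c("wt", "ko"), each = 3),
                           unit = "counts")
    res <- deTestAdjusted(em, "wt", "ko", alpha = 0.05)
    hit <- hit + sum(res$significant[dep] & res$direction[dep] == "under_in_alt")
    # BH is monotone: adjusted ordering preserves raw ordering
    ord <- order(res$p)
    expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
    expect_true(all(res$p_adj >= res$p - 1e-12, na.rm = TRUE))
  }
  expect_gte(hit / (runs * length(dep)), 0.95)
  # null data: nothing survives adjustment
  set.seed(900)
  mu <- rep(300, G)
  cnt0 <- matrix(rnbinom(G * 6, mu = mu, size = 1 / 0.05), G, 6,
                 dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:6)))
  storage.mode(cnt0) <- "integer"
  em0 <- ExpressionMatrix(cnt0, groups = rep(c("wt", "ko"), each = 3),
                          unit = "counts")
  res0 <- deTestAdjusted(em0, "wt", "ko")
  expect_lte(sum(res0$significant), 2L)
})

test_that("the welch engine guards zero variance and needs replicates", {
  cnt <- matrix(c(7L, 7L, 7L, 7L, 7L, 7L), 1,
                dimnames = list("flat", paste0("s", 1:6)))
  em <- ExpressionMatrix(cnt, groups = rep(c("wt", "ko"), each = 3),
                         unit = "counts")
  res <- deTestAdjusted(em, "wt", "ko", method = "welch")
  expect_true(is.na(res$p))
  expect_false(res$significant)
  em1 <- ExpressionMatrix(cnt[, 1:3, drop = FALSE],
                          groups = c("wt", "wt", "ko"), unit = "counts")
  expect_error(deTestAdjusted(em1, "wt", "ko"), "replicates")
  # with generous replication the welch engine recovers a planted shift
  set.seed(55)
  G <- 200L
  mu <- rep(500, G); mu_ko <- mu; mu_ko[1:4] <- mu[1:4] / 6
  cnt2 <- cbind(matrix(rnbinom(G * 10, mu = mu, size = 1 / 0.01), G),
                matrix(rnbinom(G * 10, mu = mu_ko, size = 1 / 0.01), G))
  storage.mode(cnt2) <- "integer"
  dimnames(cnt2) <- list(sprintf("g%03d", 1:G), paste0("s", 1:20))
  em2 <- ExpressionMatrix(cnt2, groups = rep(c("wt", "ko"), each = 10),
                          unit = "counts")
  res2 <- deTestAdjusted(em2, "wt", "ko", method = "welch")
  expect_true(all(res2$significant[1:4]))
  expect_true(all(res2$direction[1:4] == "under_in_alt"))
})
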