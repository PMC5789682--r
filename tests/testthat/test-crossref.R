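mkCohort <- function(df, cutoff = 1) filterVus(df, cutoff)

oneVariant <- function(gene, patient = "P1", maf = 0) {
  data.frame(patient_id = patient, gene = gene, zygosity = "het",
             hgvs_c = "c.1A>G", hgvs_p = "p.M1V", maf_percent = maf,
             stringsAsFactors = FALSE)
}

deRow <- function(gene, fc, cutoff = 2) {
  d <- data.frame(gene = gene, mean_ref = fc, mean_alt = 1, fc = fc,
                  direction = crossprio:::classifyDirection(fc, cutoff),
                  p_adj = NA_real_, stringsAsFactors = FALSE)
  attr(d, "fc_cutoff") <- cutoff
  d
}

test_that("crossref admits genes only via a direction-matching ortholog", {
  coh <- mkCohort(oneVariant("SOX9"))
  map <- OrthologMap("SOX9", "Sox9")
  pool <- crossRef(coh, deRow("Sox9", 3), map, "under")
  expect_equal(poolGenes(pool)$human_gene, "SOX9")
  expect_equal(poolGenes(pool)$fc, 3)
  # overexpressed ortholog under an under-only policy: empty pool
  pool2 <- crossRef(coh, deRow("Sox9", 1 / 3), map, "under")
  expect_equal(nrow(poolGenes(pool2)), 0L)
  expect_equal(nrow(poolGenes(crossRef(coh, deRow("Sox9", 1 / 3), map, "over"))), 1L)
  # unmapped query genes are reported, not dropped
  coh2 <- mkCohort(rbind(oneVariant("SOX9"), oneVariant("WT1", "P2")))
  pool3 <- crossRef(coh2, deRow("Sox9", 3), map, "under")
  expect_equal(unmappedGenes(pool3), "WT1")
  expect_error(crossRef(coh, deRow("Sox9", 3), OrthologMap(character(), character())),
               "empty ortholog map")
})

test_that("one-to-many orthology qualifies via any ortholog, best fc reported", {
  coh <- mkCohort(oneVariant("NR5A1"))
  map <- OrthologMap(c("NR5A1", "NR5A1"), c("Nr5a1", "Nr6a1"))
  de <- rbind(deRow("Nr5a1", 2.5), deRow("Nr6a1", 6))
  attr(de, "fc_cutoff") <- 2
  expect_message(pool <- crossRef(coh, de, map, "under"), "2 orthologs")
  expect_equal(poolGenes(pool)$mouse_gene, "Nr6a1")
  expect_equal(poolGenes(pool)$n_orthologs_matched, 2L)
})

test_that("crossref equals brute-force set logic on random small instances", {
  set.seed(91)
  for (i in 1:30) {
    nh <- sample(10:50, 1)
    hg <- sprintf("H%03d", seq_len(nh))
    mg <- sprintf("M%03d", seq_len(nh))
    # random partial map, occasionally shuffled (decoy pairs)
    keep <- runif(nh) < 0.8
    map <- OrthologMap(hg[keep], mg[keep])
    vus_genes <- sample(hg, sample(3:nh, 1))
    vdf <- do.call(rbind, lapply(vus_genes, oneVariant))
    fc <- 10^runif(nh, -1, 1)
    de <- data.frame(gene = mg, fc = fc,
                     direction = crossprio:::classifyDirection(fc, 2),
                     stringsAsFactors = FALSE)
    attr(de, "fc_cutoff") <- 2
    pool <- crossRef(mkCohort(vdf), de, map, "under")
    # exhaustive enumeration of the (VUS and mapped and under-DE) condition
    expected <- Filter(function(h) {
      mm <- map@pairs$mouse[map@pairs$human == h]
      length(mm) && any(de$direction[match(mm, de$gene)] == "under_in_alt",
                        na.rm = TRUE)
    }, vus_genes)
    expect_setequal(poolGenes(pool)$human_gene, expected)
  }
})

test_that("a fully saturated candidate scores 1 on all but conservation", {
  v <- oneVariant("SOX9", "P1", maf = 0)
  v <- rbind(v, oneVariant("SOX9", "P2", 0), oneVariant("SOX9", "P3", 0))
  v$pred_SIFT <- "damaging"; v$pred_PolyPhen <- "probably_damaging"
  coh <- mkCohort(v)
  pool <- crossRef(coh, deRow("Sox9", 8), OrthologMap("SOX9", "Sox9"), "under")
  cand <- scoreCandidates(pool, coh,
                          cell_type_annotation = data.frame(gene = "SOX9",
                                                            expressed = TRUE))
  comps <- unlist(cand[1, grep("^score_", colnames(cand))])
  expect_equal(unname(comps["score_conservation"]), 0.5)
  expect_equal(unname(comps[setdiff(names(comps), "score_conservation")]),
               rep(1, 5))
  expect_equal(cand$priority_score, (5 + 0.5) / 6)
})

test_that("recurrence breaks otherwise identical candidates", {
  v3 <- do.call(rbind, lapply(c("P1", "P2", "P3"), function(p)
    oneVariant("AAAA", p, 0)))
  v1 <- oneVariant("BBBB", "P1", 0)
  coh <- mkCohort(rbind(v3, v1))
  de <- rbind(deRow("Aaaa", 4), deRow("Bbbb", 4))
  attr(de, "fc_cutoff") <- 2
  map <- OrthologMap(c("AAAA", "BBBB"), c("Aaaa", "Bbbb"))
  cand <- scoreCandidates(crossRef(coh, de, map, "under"), coh)
  expect_equal(cand$human_gene, c("AAAA", "BBBB"))
  expect_lt(cand$priority_score[2], cand$priority_score[1])
})

test_that("the printed variant table plus a planted DE screen ranks the recurrent trio first", {
  coh <- filterVus(table2Variants(), 1)
  map <- table2Orthologs()
  fpkm <- plantedFpkm(map@pairs$mouse, fc = 4)
  de <- escalateCutoff(foldChangeDE(fpkm, "B6", "POS", 1.5), 2)
  cand <- scoreCandidates(crossRef(coh, de, map, "under"), coh)
  expect_equal(nrow(cand), 15L)
  expect_setequal(cand$human_gene[1:3], c("ADAMTS16", "MYBL1", "LGR5"))
  expect_true(all(cand$n_patients[1:3] == 3L))
})

test_that("the priority score is monotone in each component", {
  mk <- function(maf = 0.5, npat = 1, fc = 2.5, sift = "tolerated",
                 expressed = NULL) {
    v <- do.call(rbind, lapply(sprintf("P%d", seq_len(npat)), function(p)
      oneVariant("SOX9", p, maf)))
    v$pred_SIFT <- sift; v$pred_PolyPhen <- "benign"
    coh <- mkCohort(v)
    pool <- crossRef(coh, deRow("Sox9", fc), OrthologMap("SOX9", "Sox9"), "under")
    cta <- if (is.null(expressed)) NULL else data.frame(gene = "SOX9",
                                                        expressed = expressed)
    scoreCandidates(pool, coh, cell_type_annotation = cta)$priority_score
  }
  base <- mk()
  expect_gt(mk(maf = 0.05), base)          # rarer variant
  expect_gt(mk(npat = 3), base)            # more recurrent
  expect_gt(mk(fc = 6), base)              # stronger underexpression
  expect_gt(mk(sift = "damaging"), base)   # deleterious call
  expect_gt(mk(expressed = TRUE), base)    # supporting-lineage expression
  expect_lt(mk(expressed = FALSE), base)
})

test_that("weights are validated and conservation input is used", {
  expect_error(priorityConfig(weights = c(rarity = 1, conservation = 1,
                                          recurrence = 1, insilico = 1,
                                          cell_type = 1, fc_magnitude = 1)),
               "sum to 1")
  expect_error(priorityConfig(weights = c(rarity = 0.5, bogus = 0.5)), "named")
  v <- oneVariant("SOX9")
  coh <- mkCohort(v)
  pool <- crossRef(coh, deRow("Sox9", 4), OrthologMap("SOX9", "Sox9"), "under")
  hi <- scoreCandidates(pool, coh,
                        conservation_table = data.frame(gene = "SOX9", score = 1))
  lo <- scoreCandidates(pool, coh,
                        conservation_table = data.frame(gene = "SOX9", score = 0.1))
  expect_gt(hi$priority_score, lo$priority_score)
})

test_that("knockout dependence classifies significant, same-direction, untested", {
  coh <- mkCohort(rbind(oneVariant("AAAA"), oneVariant("BBBB", "P2"),
                        oneVariant("CCCC", "P3"), oneVariant("DDDD", "P4")))
  map <- OrthologMap(c("AAAA", "BBBB", "CCCC", "DDDD"),
                     c("Aaaa", "Bbbb", "Cccc", "Dddd"))
  de <- do.call(rbind, lapply(c("Aaaa", "Bbbb", "Cccc", "Dddd"),
                              function(g) deRow(g, 4)))
  attr(de, "fc_cutoff") <- 2
  cand <- scoreCandidates(crossRef(coh, de, map, "under"), coh)
  ko <- data.frame(gene = c("Aaaa", "Bbbb", "Cccc"),
                   fc = c(5, 2, 0.4), p_adj = c(0.01, 0.4, 0.2),
                   stringsAsFactors = FALSE)
  out <- annotateKoDependence(cand, ko, map, alpha = 0.05)
  got <- setNames(out$ko_dependent, out$human_gene)
  expect_equal(unname(got[c("AAAA", "BBBB", "CCCC", "DDDD")]),
               c("significant", "same_direction_ns", "not_supported", "untested"))
})

test_that("planted knockout truth is flagged exactly on a handcrafted table", {
  genes <- sprintf("KA%02d", 1:15)
  mgenes <- sprintf("Ka%02d", 1:15)
  coh <- mkCohort(do.call(rbind, Map(oneVariant, genes,
                                     sprintf("P%02d", 1:15))))
  map <- OrthologMap(genes, mgenes)
  de <- do.call(rbind, lapply(mgenes, function(g) deRow(g, 4)))
  attr(de, "fc_cutoff") <- 2
  cand <- scoreCandidates(crossRef(coh, de, map, "under"), coh)
  dep <- mgenes[1:7]
  ko <- data.frame(gene = mgenes,
                   fc = c(rep(6, 7), rep(1.3, 8)),
                   p_adj = c(rep(0.001, 7), rep(0.5, 8)),
                   stringsAsFactors = FALSE)
  out <- annotateKoDependence(cand, ko, map)
  expect_setequal(out$human_gene[out$ko_dependent == "significant"], genes[1:7])
  expect_equal(sum(out$ko_dependent == "same_direction_ns"), 8L)
})

test_that("reports assemble, write, and keep funnel bookkeeping", {
  rep0 <- buildReport(crossprio:::emptyCandidateFrame(),
                      list(variant_records_in = 10L, records_pass_maf = 4L,
                           pool_escalated_cutoff = 0L, candidates_scored = 0L))
  expect_equal(nrow(candidates(rep0)), 0L)
  expect_equal(funnel(rep0)$variant_records_in, 10L)
  d <- withr::local_tempdir()
  writeReport(rep0, d)
  expect_true(file.exists(file.path(d, "candidates.tsv")))
  expect_true(file.exists(file.path(d, "funnel.json")))
})
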