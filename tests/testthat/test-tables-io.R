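test_that("the candidate-variant fixture parses to the printed cohort content", {
  v <- table2Variants()
  expect_equal(nrow(v), 27L)
  expect_equal(length(unique(v$gene)), 15L)
  # spot row from the printed table
  row <- v[v$gene == "ADAMTS16" & v$patient_id == "RDSD013", ]
  expect_equal(row$maf_percent, 0.8)
  expect_equal(row$hgvs_p, "p.Val734Ile")
  expect_equal(row$zygosity, "het")
  # compound-het rows keep the cmpd_het zygosity on each component row
  expect_equal(sum(v$zygosity == "cmpd_het"), 3L)
  expect_true(all(v$maf_percent >= 0 & v$maf_percent <= 100))
  # MAF printed as "0" parses to exact 0
  expect_identical(v$maf_percent[v$hgvs_p == "p.Thr846Asn"], 0)
})

test_that("variant reader enforces its schema and row-level validity", {
  d <- withr::local_tempdir()
  # empty file with a valid header -> empty collection
  f <- file.path(d, "empty.tsv")
  writeLines("patient_id\tgene\tzygosity\thgvs_c\thgvs_p\tmaf_percent", f)
  expect_equal(nrow(readVariantTable(f)), 0L)
  # missing mandatory column named in the error
  f2 <- file.path(d, "noschema.tsv")
  writeLines(c("patient_id\tgene\thgvs_c\thgvs_p\tmaf_percent",
               "P1\tSOX9\tc.1A>G\tp.M1V\t0"), f2)
  expect_error(readVariantTable(f2), "zygosity")
  # non-numeric MAF reported with its row index
  f3 <- file.path(d, "badmaf.tsv")
  writeLines(c("patient_id\tgene\tzygosity\thgvs_c\thgvs_p\tmaf_percent",
               "P1\tSOX9\thet\tc.1A>G\tp.M1V\t0.1",
               "P2\tSRY\thet\tc.2A>G\tp.K2R\tlow"), f3)
  expect_error(readVariantTable(f3), "row 2")
  # unknown zygosity token is a row-level error
  f4 <- file.path(d, "badzyg.tsv")
  writeLines(c("patient_id\tgene\tzygosity\thgvs_c\thgvs_p\tmaf_percent",
               "P1\tSOX9\ttriploid\tc.1A>G\tp.M1V\t0"), f4)
  expect_error(readVariantTable(f4), "zygosity token")
})

test_that("variant TSV write-read-write round-trips byte-identically", {
  d <- withr::local_tempdir()
  v <- table2Variants()
  p1 <- file.path(d, "a.tsv"); p2 <- file.path(d, "b.tsv")
  writeVariantTable(v, p1)
  writeVariantTable(readVariantTable(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("patient table parses all cohort rows and validates categories", {
  p <- readPatientTable(fixturePath("table1_patients.tsv"))
  expect_equal(nrow(p), 32L)
  expect_true(all(p$category %in% 1:4))
  expect_true(all(p$karyotype == "46,XY"))
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tsv")
  writeLines(c("patient_id\tcategory", "P1\t5"), f)
  expect_error(readPatientTable(f), "category")
})

test_that("expression matrix reader validates shape, sign and unit", {
  d <- withr::local_tempdir()
  f <- file.path(d, "z.tsv")
  writeLines(c("gene\ts1|a\ts2|b", "Sox9\t0\t0", "Actb\t0\t0"), f)
  m <- readExpressionMatrix(f, unit = "FPKM")
  expect_true(all(exprValues(m) == 0))
  expect_equal(unname(sampleGroups(m)), c("a", "b"))
  # fractional value under the counts unit violates the integer invariant
  f2 <- file.path(d, "frac.tsv")
  writeLines(c("gene\ts1|a\ts2|b", "Sox9\t3.5\t1"), f2)
  expect_error(readExpressionMatrix(f2, unit = "counts"), "integer")
  # negative value reported with coordinates
  f3 <- file.path(d, "neg.tsv")
  writeLines(c("gene\ts1|a\ts2|b", "Sox9\t-1\t1"), f3)
  expect_error(readExpressionMatrix(f3, unit = "FPKM"), "Sox9")
  # ragged rows are a format error
  f4 <- file.path(d, "ragged.tsv")
  writeLines(c("gene\ts1|a\ts2|b", "Sox9\t1\t2", "Actb\t1"), f4)
  expect_error(readExpressionMatrix(f4, unit = "FPKM"), "ragged")
  # duplicate gene rows error by default, collapse when asked
  f5 <- file.path(d, "dup.tsv")
  writeLines(c("gene\ts1|a\ts2|b", "Sox9\t1\t2", "SOX9\t3\t4"), f5)
  expect_error(readExpressionMatrix(f5, unit = "FPKM", species = "mouse"), "duplicate")
  ms <- readExpressionMatrix(f5, unit = "FPKM", species = "mouse", dup_action = "sum")
  expect_equal(unname(exprValues(ms)["Sox9", ]), c(4, 6))
})

test_that("a 515-gene synthetic matrix round-trips write-read bit-identically", {
  set.seed(42)
  g <- 515L
  vals <- matrix(round(10^runif(g * 4, -1, 3), 4), g, 4,
                 dimnames = list(sprintf("Gene%04d", seq_len(g)),
                                 c("B6_1", "B6_2", "POS_1", "POS_2")))
  em <- ExpressionMatrix(vals, groups = c("B6", "B6", "POS", "POS"),
                         unit = "FPKM", species = "mouse")
  d <- withr::local_tempdir()
  p1 <- file.path(d, "m1.tsv"); p2 <- file.path(d, "m2.tsv")
  writeExpressionMatrix(em, p1)
  writeExpressionMatrix(readExpressionMatrix(p1, unit = "FPKM"), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("gene sets canonicalize, deduplicate with a warning, tolerate emptiness", {
  d <- withr::local_tempdir()
  f <- file.path(d, "gs.txt")
  writeLines(c("SRY", "SOX9", "sox9"), f)
  expect_warning(gs <- readGeneSet(f, species = "human"), "duplicate")
  expect_setequal(geneSymbols(gs), c("SRY", "SOX9"))
  f2 <- file.path(d, "empty.txt")
  writeLines(character(), f2)
  expect_warning(gs2 <- readGeneSet(f2, species = "human"), "empty")
  expect_length(geneSymbols(gs2), 0L)
})

test_that("ortholog map supports both directions, one-to-many, explicit misses", {
  d <- withr::local_tempdir()
  f <- file.path(d, "map.tsv")
  writeLines(c("SOX9\tSox9", "NR5A1\tNr5a1", "NR5A1\tNr6a1"), f)
  map <- readOrthologMap(f)
  expect_equal(mouseOrthologs(map, "SOX9")$SOX9, "Sox9")
  expect_equal(humanOrthologs(map, "Sox9")$Sox9, "SOX9")
  expect_setequal(mouseOrthologs(map, "NR5A1")$NR5A1, c("Nr5a1", "Nr6a1"))
  # unmapped lookups are explicit empty matches, not dropped entries
  miss <- mouseOrthologs(map, c("SOX9", "WT1"))
  expect_named(miss, c("SOX9", "WT1"))
  expect_length(miss$WT1, 0L)
  f2 <- file.path(d, "dup.tsv")
  writeLines(c("SOX9\tSox9", "SOX9\tSox9"), f2)
  expect_warning(readOrthologMap(f2), "duplicate")
})

test_that("the VCF-subset dialect yields per-sample records on the percent scale", {
  d <- withr::local_tempdir()
  f <- file.path(d, "mini.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2",
    "1\t100\t.\tA\tG\t50\tPASS\tGENE=SOX9;AF=0.004\tGT\t0/1\t0/0",
    "2\t200\t.\tC\tT\t50\tPASS\tGENE=WT1;AF=0.0001\tGT\t1/1\t0/1"), f)
  v <- readVariantTable(f, dialect = "vcf_subset")
  expect_equal(nrow(v), 3L)
  p1 <- v[v$patient_id == "P1", ]
  expect_setequal(p1$gene, c("SOX9", "WT1"))
  expect_equal(p1$zygosity[p1$gene == "WT1"], "hom")
  expect_equal(p1$maf_percent[p1$gene == "SOX9"], 0.4)
  expect_equal(v$zygosity[v$patient_id == "P2"], "het")
})
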