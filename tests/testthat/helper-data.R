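# Shared fixture builders; everything is generated in code.

fixturePath <- function(name) {
  system.file("extdata", name, package = "crossprio", mustWork = TRUE)
}

table2Variants <- function() readVariantTable(fixturePath("table2_vus.tsv"))

table2Orthologs <- function() readOrthologMap(fixturePath("table2_orthologs.tsv"))

# Two-group FPKM matrix in which every listed mouse gene is planted
# underexpressed in the alternate group at `fc` (noise-free), padded with
# unchanged decoy genes.
plantedFpkm <- function(mouse_genes, fc = 4, n_decoys = 10, base = 50,
                        ref = "B6", alt = "POS", reps = 2) {
  decoys <- sprintf("Dec%03d", seq_len(n_decoys))
  genes <- c(mouse_genes, decoys)
  mu_ref <- rep(base, length(genes))
  mu_alt <- c(rep(base / fc, length(mouse_genes)), rep(base, n_decoys))
  vals <- cbind(matrix(rep(mu_ref, reps), ncol = reps),
                matrix(rep(mu_alt, reps), ncol = reps))
  dimnames(vals) <- list(genes, c(paste0(ref, "_", seq_len(reps)),
                                  paste0(alt, "_", seq_len(reps))))
  ExpressionMatrix(vals, groups = rep(c(ref, alt), each = reps), unit = "FPKM",
                   species = "mouse")
}

# Random small variant frame for property tests.
randomVariantFrame <- function(n, n_genes = 12, n_patients = 5) {
  data.frame(
    patient_id = sample(sprintf("P%02d", seq_len(n_patients)), n, replace = TRUE),
    gene = sample(sprintf("G%03d", seq_len(n_genes)), n, replace = TRUE),
    zygosity = sample(c("het", "hom", "cmpd_het"), n, replace = TRUE,
                      prob = c(0.8, 0.1, 0.1)),
    hgvs_c = sprintf("c.%dA>G", seq_len(n)),
    hgvs_p = sprintf("p.Ala%dVal", seq_len(n)),
    maf_percent = ifelse(runif(n) < 0.2, 0, 10^runif(n, -4, 0.5)),
    stringsAsFactors = FALSE)
}

# Exhaustive hypergeometric upper tail by enumerating all size-n subsets of a
# universe of size N: the independent oracle for the enrichment test.
enumUpperTail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # first K elements form the term
  mean(hits >= k)
}

tinyConfig <- function(seed = 1, nCausal = 5, ...) {
  simulationConfig(seed = seed, nPatients = 5, nGenesHuman = 300,
                   nGenesMouse = 310, vusGenesRange = c(10, 50),
                   nCausal = nCausal, nDeDecoys = 16, ...)
}
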