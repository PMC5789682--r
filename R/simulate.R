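#' @title Synthetic study generator
#' @description Generates every input the pipeline consumes — cohort variant
#' table, two-group FPKM matrix, knockout count matrix, ortholog map — with
#' the statistical structure the analysis assumes and a full planted-truth
#' record, so the end-to-end procedure is testable without external data.
#' @name synthetic-data
NULL

# Deterministic gene-universe partition shared by the cohort and expression
# generators: causal genes (variant + expression signal), DE-only decoys
# (expression signal, human ortholog never receives a variant), VUS-only
# decoys (everything else samplable), unmapped human genes, one-to-many
# ortholog entries, and the knockout-dependent causal subset.
simulateUniverse <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  hg <- sprintf("GENE%05d", seq_len(config@nGenesHuman))
  mg_base <- sprintf("Gene%05d", seq_len(config@nGenesHuman))
  n_extra <- max(config@nGenesMouse - config@nGenesHuman, 0L)
  mg_extra <- if (n_extra) sprintf("Gdup%05d", seq_len(n_extra)) else character()

  n_unmapped <- round(config@unmappedFraction * config@nGenesHuman)
  unmapped <- sort(sample(hg, n_unmapped))
  mapped <- setdiff(hg, unmapped)

  causal <- sort(sample(mapped, config@nCausal))
  n_dep <- round(config@nCausal * config@koDependentFraction)
  ko_dep <- sort(sample(causal, n_dep))
  rest <- setdiff(mapped, causal)
  decoys <- sort(sample(rest, min(config@nDeDecoys, length(rest))))
  half <- ceiling(length(decoys) / 2)
  de_under <- decoys[seq_len(half)]
  de_over <- setdiff(decoys, de_under)

  pairs_h <- mapped
  pairs_m <- mg_base[match(mapped, hg)]
  # one-to-many: a few mapped (non-causal, non-decoy) genes get a second
  # mouse symbol drawn from the extra pool
  n_multi <- min(10L, n_extra, length(setdiff(mapped, c(causal, decoys))))
  multi_h <- if (n_multi)
    sort(sample(setdiff(mapped, c(causal, decoys)), n_multi)) else character()
  if (n_multi) {
    pairs_h <- c(pairs_h, multi_h)
    pairs_m <- c(pairs_m, mg_extra[seq_len(n_multi)])
  }
  list(human = hg, mouse = c(mg_base, mg_extra),
       map = OrthologMap(pairs_h, pairs_m, provenance = "synthetic"),
       causal = causal, causal_mouse = mg_base[match(causal, hg)],
       ko_dep = ko_dep, ko_dep_mouse = mg_base[match(ko_dep, hg)],
       de_under = de_under, de_under_mouse = mg_base[match(de_under, hg)],
       de_over = de_over, de_over_mouse = mg_base[match(de_over, hg)],
       unmapped = unmapped, one_to_many = multi_h,
       vus_pool = setdiff(hg, decoys))
}

#' Simulate the rare-disease cohort variant table
#'
#' Generates the patient table and per-patient variant records: each patient
#' carries a number of VUS-bearing genes drawn uniformly from the configured
#' range (default 30-1100), with decoy MAFs from a zero-inflated log-uniform
#' mixture on the percent scale. Every planted causal gene receives at least
#' one variant with MAF at or below `causalMafMax` (default 0.1%) and
#' deleterious calls from both predictors, in 1-3 patients. One compound-het
#' event is always planted. DE-only decoy genes never receive a variant, so
#' the cross-species intersection has an exact planted truth.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `variants` (data.frame in [readVariantTable()] layout),
#'   `patients` (data.frame), and `truth` (planted-gene record).
#' @examples
#' cfg <- simulationConfig(seed = 3, nPatients = 4, nGenesHuman = 300,
#'                         nGenesMouse = 310, vusGenesRange = c(10, 40),
#'                         nCausal = 5, nDeDecoys = 10)
#' sim <- simulateCohort(cfg)
#' head(sim$variants)
#' @export
simulateCohort <- function(config) {
  uni <- simulateUniverse(config)
  set.seed(config@seed + 1L)
  patients <- sprintf("P%03d", seq_len(config@nPatients))
  pat_tab <- data.frame(patient_id = patients,
                        category = sample(1:4, config@nPatients, replace = TRUE),
                        karyotype = "46,XY", stringsAsFactors = FALSE)

  # plant causal variants: each causal gene in 1-3 distinct patients
  causal_rows <- list()
  causal_pat <- stats::setNames(vector("list", length(uni$causal)), uni$causal)
  for (g in uni$causal) {
    k <- sample(1:3, 1L)
    who <- sample(patients, k)
    causal_pat[[g]] <- who
    maf <- ifelse(stats::runif(k) < 0.3, 0,
                  10^stats::runif(k, log10(config@mafLogRange[1L]),
                                  log10(config@causalMafMax)))
    causal_rows[[g]] <- data.frame(
      patient_id = who, gene = g, zygosity = "het",
      hgvs_c = sprintf("c.%dG>A", sample(100:5000, k)),
      hgvs_p = sprintf("p.Gly%dSer", sample(30:900, k)),
      maf_percent = maf, conservation = NA_real_,
      pred_SIFT = "damaging", pred_PolyPhen = "probably_damaging",
      stringsAsFactors = FALSE)
  }
  causal_df <- do.call(rbind, causal_rows)

  n_causal_by_pat <- table(factor(causal_df$patient_id, levels = patients))
  decoy_pool <- setdiff(uni$vus_pool, uni$causal)
  decoy_rows <- list()
  for (i in seq_along(patients)) {
    n_total <- sample(seq(config@vusGenesRange[1L], config@vusGenesRange[2L]), 1L)
    n_decoy <- max(0L, n_total - as.integer(n_causal_by_pat[i]))
    if (!n_decoy) next
    genes <- sample(decoy_pool, n_decoy)
    m <- length(genes)
    maf <- ifelse(stats::runif(m) < config@mafZeroProb, 0,
                  10^stats::runif(m, log10(config@mafLogRange[1L]),
                                  log10(config@mafLogRange[2L])))
    decoy_rows[[i]] <- data.frame(
      patient_id = patients[i], gene = genes,
      zygosity = sample(c("het", "hom"), m, replace = TRUE, prob = c(0.95, 0.05)),
      hgvs_c = sprintf("c.%dC>T", sample(100:5000, m, replace = TRUE)),
      hgvs_p = sprintf("p.Arg%dTrp", sample(30:900, m, replace = TRUE)),
      maf_percent = maf, conservation = NA_real_,
      pred_SIFT = sample(c("damaging", "tolerated", "."), m, replace = TRUE,
                         prob = c(0.25, 0.60, 0.15)),
      pred_PolyPhen = sample(c("probably_damaging", "possibly_damaging",
                               "benign", "."), m, replace = TRUE,
                             prob = c(0.12, 0.13, 0.60, 0.15)),
      stringsAsFactors = FALSE)
  }
  variants <- rbind(causal_df, do.call(rbind, decoy_rows))

  # one planted compound-het event (two het-class variants in one gene of one
  # patient); reuses a gene that patient already carries so per-patient gene
  # counts stay inside the configured range
  ip <- which(!vapply(decoy_rows, is.null, logical(1)))[1L]
  ch_pat <- patients[ip]
  ch_gene <- sample(decoy_rows[[ip]]$gene, 1L)
  ch <- data.frame(patient_id = ch_pat, gene = ch_gene,
                   zygosity = "cmpd_het",
                   hgvs_c = sprintf("c.%dA>G", c(211L, 1744L)),
                   hgvs_p = sprintf("p.Met%dVal", c(71L, 582L)),
                   maf_percent = c(0, 0.01), conservation = NA_real_,
                   pred_SIFT = "damaging", pred_PolyPhen = "benign",
                   stringsAsFactors = FALSE)
  variants <- rbind(variants, ch)
  variants <- variants[order(variants$patient_id, variants$gene,
                             variants$hgvs_c), , drop = FALSE]
  rownames(variants) <- NULL

  list(variants = variants, patients = pat_tab,
       truth = list(causal_genes = uni$causal,
                    causal_mouse = uni$causal_mouse,
                    causal_patients = causal_pat,
                    ko_dependent = uni$ko_dep,
                    ko_dependent_mouse = uni$ko_dep_mouse,
                    de_decoys_under = uni$de_under,
                    de_decoys_over = uni$de_over,
                    unmapped = uni$unmapped,
                    cmpd_het = list(patient = ch_pat, gene = ch_gene)))
}

#' Simulate the expression inputs and ortholog map
#'
#' Generates (i) a two-group gonadal FPKM matrix in which planted causal mouse
#' orthologs are underexpressed in the alternate group at the configured fold
#' change with multiplicative log-normal noise, and DE-only decoys are planted
#' under- or over-expressed at fold changes spanning the escalation window;
#' (ii) a wild-type vs knockout negative-binomial count matrix (3 vs 3 by
#' default) with the knockout-dependent causal subset shifted by `koFc`; and
#' (iii) the human-mouse ortholog map linking causal pairs plus decoy pairs,
#' one-to-many entries, and deliberately unmapped genes.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `fpkm` and `koCounts` ([ExpressionMatrix-class]),
#'   `orthologMap` ([OrthologMap-class]) and `truth`.
#' @export
simulateExpression <- function(config) {
  uni <- simulateUniverse(config)
  set.seed(config@seed + 2L)
  mg <- uni$mouse
  G <- length(mg)
  mu <- 10^stats::runif(G, log10(0.5), log10(500))
  names(mu) <- mg
  # planted genes kept well-expressed so the ratio screen sees them
  planted <- c(uni$causal_mouse, uni$de_under_mouse, uni$de_over_mouse)
  mu[planted] <- 10^stats::runif(length(planted), log10(20), log10(500))

  mu_alt <- mu
  mu_alt[uni$causal_mouse] <- mu[uni$causal_mouse] / config@causalFc
  dfc_u <- stats::runif(length(uni$de_under_mouse), config@decoyFcRange[1L],
                        config@decoyFcRange[2L])
  mu_alt[uni$de_under_mouse] <- mu[uni$de_under_mouse] / dfc_u
  dfc_o <- stats::runif(length(uni$de_over_mouse), config@decoyFcRange[1L],
                        config@decoyFcRange[2L])
  mu_alt[uni$de_over_mouse] <- mu[uni$de_over_mouse] * dfc_o

  nr <- config@nRefSamples; na <- config@nAltSamples
  noise <- function(n, m) m * exp(stats::rnorm(n * length(m), 0, config@fpkmSigma))
  fpkm <- cbind(matrix(noise(nr, mu), G, nr),
                matrix(noise(na, mu_alt), G, na))
  dimnames(fpkm) <- list(mg, c(sprintf("B6_%d", seq_len(nr)),
                               sprintf("POS_%d", seq_len(na))))
  fpkm_mat <- ExpressionMatrix(fpkm, groups = rep(c("B6", "POS"), c(nr, na)),
                               unit = "FPKM", species = "mouse")

  # knockout design: NB counts, dependent subset shifted down in the knockout
  mu_ko <- 10^stats::runif(G, log10(20), log10(2000))
  names(mu_ko) <- mg
  mu_ko_alt <- mu_ko
  mu_ko_alt[uni$ko_dep_mouse] <- mu_ko[uni$ko_dep_mouse] / config@koFc
  reps <- config@koReps
  rcnt <- function(m) {
    if (config@koDispersion > 0)
      stats::rnbinom(length(m), mu = m, size = 1 / config@koDispersion)
    else stats::rpois(length(m), m)
  }
  ko <- cbind(matrix(vapply(seq_len(reps), function(i) rcnt(mu_ko),
                            numeric(G)), G, reps),
              matrix(vapply(seq_len(reps), function(i) rcnt(mu_ko_alt),
                            numeric(G)), G, reps))
  storage.mode(ko) <- "integer"
  dimnames(ko) <- list(mg, c(sprintf("wt_%d", seq_len(reps)),
                             sprintf("ko_%d", seq_len(reps))))
  ko_mat <- ExpressionMatrix(ko, groups = rep(c("XY_wt", "XY_ko"), each = reps),
                             unit = "counts", species = "mouse")

  list(fpkm = fpkm_mat, koCounts = ko_mat, orthologMap = uni$map,
       truth = list(causal_genes = uni$causal, causal_mouse = uni$causal_mouse,
                    ko_dependent = uni$ko_dep,
                    ko_dependent_mouse = uni$ko_dep_mouse,
                    de_decoys_under_mouse = uni$de_under_mouse,
                    de_decoys_over_mouse = uni$de_over_mouse,
                    planted_fc = config@causalFc, ko_fc = config@koFc))
}

#' Simulate the full study and optionally write it to disk
#'
#' Convenience wrapper running [simulateCohort()] and [simulateExpression()]
#' with one config. When `dir` is given, writes `variants.tsv`,
#' `patients.tsv`, `fpkm.tsv`, `ko_counts.tsv`, `ortholog_map.tsv` and
#' `truth.json` there.
#'
#' @param config a [SimulationConfig-class].
#' @param dir optional output directory.
#' @return list with `variants`, `patients`, `fpkm`, `koCounts`,
#'   `orthologMap`, `truth`.
#' @export
simulateStudy <- function(config, dir = NULL) {
  coh <- simulateCohort(config)
  expr <- simulateExpression(config)
  out <- list(variants = coh$variants, patients = coh$patients,
              fpkm = expr$fpkm, koCounts = expr$koCounts,
              orthologMap = expr$orthologMap,
              truth = utils::modifyList(coh$truth, expr$truth))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeVariantTable(out$variants, file.path(dir, "variants.tsv"))
    utils::write.table(out$patients, file.path(dir, "patients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeExpressionMatrix(out$fpkm, file.path(dir, "fpkm.tsv"))
    writeExpressionMatrix(out$koCounts, file.path(dir, "ko_counts.tsv"))
    utils::write.table(out$orthologMap@pairs, file.path(dir, "ortholog_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
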