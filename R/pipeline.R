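#' Build a pipeline configuration
#'
#' One validated document driving [runPipeline()]. Inputs may be in-memory
#' objects (data.frames / package S4 classes) or file paths resolved through
#' the package readers at run time.
#'
#' @param variants variant table (data.frame) or TSV path.
#' @param fpkm two-group FPKM [ExpressionMatrix-class] or TSV path.
#' @param orthologMap [OrthologMap-class] or two-column TSV path.
#' @param koCounts optional knockout counts [ExpressionMatrix-class] or path.
#' @param knownGenes optional [GeneSet-class] or gene-list path (known disease
#'   genes routed away from novel-candidate discovery).
#' @param cellTypeAnnotation optional data.frame (`gene`, `expressed`) or path.
#' @param conservation optional data.frame (`gene`, `score`) or path.
#' @param mafCutoff strict MAF cutoff in percent (default 1).
#' @param fcInitial,fcEscalated fold-change cutoffs (defaults 1.5, 2).
#' @param directionPolicy `"under"` (default), `"over"`, or `"both"`.
#' @param weights priority-score weights (see [priorityConfig()]).
#' @param alpha adjusted-p threshold for knockout dependence (default 0.05).
#' @param pseudocount FPKM pseudocount (default 0.1).
#' @param refGroup,altGroup group labels of the FPKM matrix (defaults `B6`,
#'   `POS`).
#' @param koRefGroup,koAltGroup group labels of the knockout matrix (defaults
#'   `XY_wt`, `XY_ko`).
#' @param seed integer seed recorded with the run (analysis stages are
#'   deterministic; the seed governs any simulated inputs upstream).
#' @return A validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(variants, fpkm, orthologMap, koCounts = NULL,
                           knownGenes = NULL, cellTypeAnnotation = NULL,
                           conservation = NULL, mafCutoff = 1,
                           fcInitial = 1.5, fcEscalated = 2,
                           directionPolicy = c("under", "over", "both"),
                           weights = c(rarity = 1, conservation = 1,
                                       recurrence = 1, insilico = 1,
                                       cell_type = 1, fc_magnitude = 1) / 6,
                           alpha = 0.05, pseudocount = 0.1,
                           refGroup = "B6", altGroup = "POS",
                           koRefGroup = "XY_wt", koAltGroup = "XY_ko",
                           seed = 1L) {
  directionPolicy <- match.arg(directionPolicy)
  inputs <- list(variants = variants, fpkm = fpkm, orthologMap = orthologMap,
                 koCounts = koCounts, knownGenes = knownGenes,
                 cellTypeAnnotation = cellTypeAnnotation,
                 conservation = conservation)
  for (nm in c("variants", "fpkm", "orthologMap"))
    if (is.null(inputs[[nm]])) stop("input '", nm, "' is mandatory")
  for (nm in names(inputs))
    if (is.character(inputs[[nm]]) && !file.exists(inputs[[nm]]))
      stop(sprintf("input file for '%s' does not exist: %s", nm, inputs[[nm]]))
  new("PipelineConfig", inputs = inputs, mafCutoff = mafCutoff,
      fcInitial = fcInitial, fcEscalated = fcEscalated,
      directionPolicy = directionPolicy, weights = weights, alpha = alpha,
      pseudocount = pseudocount, refGroup = refGroup, altGroup = altGroup,
      koRefGroup = koRefGroup, koAltGroup = koAltGroup,
      seed = as.integer(seed))
}

#' Read a pipeline configuration from a YAML or JSON document
#'
#' File-path inputs are resolved relative to the config file's directory.
#' Recognized keys mirror the arguments of [pipelineConfig()] in snake_case
#' (`maf_cutoff`, `fc_initial`, `fc_escalated`, `direction_policy`, `weights`,
#' `alpha`, `pseudocount`, `ref_group`, `alt_group`, `ko_ref_group`,
#' `ko_alt_group`, `seed`) plus the input paths `variants`, `fpkm`,
#' `ko_counts`, `ortholog_map`, `known_genes`, `cell_type_annotation`,
#' `conservation`.
#'
#' @param path YAML (default) or `.json` config file.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  args <- list(
    variants = rel(doc$variants), fpkm = rel(doc$fpkm),
    orthologMap = rel(doc$ortholog_map), koCounts = rel(doc$ko_counts),
    knownGenes = rel(doc$known_genes),
    cellTypeAnnotation = rel(doc$cell_type_annotation),
    conservation = rel(doc$conservation))
  opt <- list(mafCutoff = doc$maf_cutoff, fcInitial = doc$fc_initial,
              fcEscalated = doc$fc_escalated,
              directionPolicy = doc$direction_policy,
              weights = if (!is.null(doc$weights)) unlist(doc$weights),
              alpha = doc$alpha, pseudocount = doc$pseudocount,
              refGroup = doc$ref_group, altGroup = doc$alt_group,
              koRefGroup = doc$ko_ref_group, koAltGroup = doc$ko_alt_group,
              seed = doc$seed)
  do.call(pipelineConfig, c(args[!vapply(args, is.null, logical(1))],
                            opt[!vapply(opt, is.null, logical(1))]))
}

resolveInput <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full cross-species prioritization pipeline
#'
#' Executes, in order: MAF filtering of the variant table ([filterVus()]),
#' fold-change classification of the FPKM matrix at the initial cutoff
#' ([foldChangeDE()]), ortholog-mediated cross-referencing under the direction
#' policy ([crossRef()]), cutoff escalation and re-intersection
#' ([escalateCutoff()]), multi-criteria scoring ([scoreCandidates()]), and,
#' when a knockout count matrix is configured, knockout-dependence annotation
#' ([deTestAdjusted()] + [annotateKoDependence()]). Every stage's in/out
#' counts are recorded in the report funnel; a failing stage aborts with the
#' stage name and cause.
#'
#' @param config a [PipelineConfig-class].
#' @return A [CandidateReport-class].
#' @examples
#' sim <- simulateStudy(simulationConfig(seed = 11, nPatients = 6,
#'     nGenesHuman = 400, nGenesMouse = 410, vusGenesRange = c(10, 60),
#'     nCausal = 6, nDeDecoys = 20))
#' rep <- runPipeline(pipelineConfig(variants = sim$variants, fpkm = sim$fpkm,
#'     orthologMap = sim$orthologMap, koCounts = sim$koCounts))
#' candidates(rep)$human_gene
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  inp <- config@inputs
  variants <- stage("read_variants", resolveInput(inp$variants, readVariantTable))
  fpkm <- stage("read_fpkm", resolveInput(
    inp$fpkm, function(p) readExpressionMatrix(p, unit = "FPKM")))
  map <- stage("read_ortholog_map", resolveInput(inp$orthologMap, readOrthologMap))
  known <- stage("read_known_genes", resolveInput(
    inp$knownGenes, function(p) readGeneSet(p, species = "human")))
  ctype <- stage("read_cell_type", resolveInput(
    inp$cellTypeAnnotation,
    function(p) utils::read.delim(p, stringsAsFactors = FALSE)))
  consv <- stage("read_conservation", resolveInput(
    inp$conservation,
    function(p) utils::read.delim(p, stringsAsFactors = FALSE)))

  funnel <- list(variant_records_in = nrow(variants))
  cohort <- stage("filter_vus",
                  filterVus(variants, config@mafCutoff, known_gene_set = known))
  funnel$records_pass_maf <- nrow(records(cohort))
  funnel$records_known_gene <- nrow(cohort@inList)
  funnel$vus_genes_novel <- length(unique(cohort@outOfList$gene))

  de <- stage("fold_change_de",
              foldChangeDE(fpkm, config@refGroup, config@altGroup,
                           fc_cutoff = config@fcInitial,
                           pseudocount = config@pseudocount))
  funnel$de_genes_initial <- sum(de$direction != "unchanged")
  pool1 <- stage("crossref", crossRef(cohort, de, map, config@directionPolicy))
  funnel$pool_initial_cutoff <- nrow(poolGenes(pool1))
  funnel$unmapped_vus_genes <- length(unmappedGenes(pool1))

  de2 <- stage("escalate_cutoff", escalateCutoff(de, config@fcEscalated))
  pool2 <- stage("crossref_escalated",
                 crossRef(cohort, de2, map, config@directionPolicy))
  funnel$pool_escalated_cutoff <- nrow(poolGenes(pool2))

  pcfg <- stage("priority_config", priorityConfig(weights = config@weights))
  cand <- stage("score_candidates",
                scoreCandidates(pool2, cohort, pcfg,
                                cell_type_annotation = ctype,
                                conservation_table = consv))
  funnel$candidates_scored <- nrow(cand)

  if (!is.null(inp$koCounts)) {
    ko <- stage("read_ko_counts", resolveInput(
      inp$koCounts, function(p) readExpressionMatrix(p, unit = "counts")))
    koDe <- stage("de_test_adjusted",
                  deTestAdjusted(ko, config@koRefGroup, config@koAltGroup,
                                 alpha = config@alpha))
    cand <- stage("annotate_ko_dependence",
                  annotateKoDependence(cand, koDe, map, alpha = config@alpha))
    funnel$ko_significant <- sum(cand$ko_dependent == "significant")
  }
  buildReport(cand, funnel,
              parameters = list(maf_cutoff = config@mafCutoff,
                                fc_initial = config@fcInitial,
                                fc_escalated = config@fcEscalated,
                                direction_policy = config@directionPolicy,
                                weights = as.list(config@weights),
                                alpha = config@alpha,
                                pseudocount = config@pseudocount,
                                seed = config@seed,
                                unmapped_genes = unmappedGenes(pool2)))
}
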