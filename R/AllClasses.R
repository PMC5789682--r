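#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' ExpressionMatrix: a genes x samples expression assay with group labels
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' declared expression unit (`"FPKM"` or `"counts"`) and a mandatory per-sample
#' `group` label in `colData`. Values must be non-negative; the `counts` unit
#' additionally requires integer values.
#'
#' @slot unit character, one of `"FPKM"` or `"counts"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  msgs <- character()
  if (length(object@unit) != 1L || !object@unit %in% c("FPKM", "counts"))
    msgs <- c(msgs, "unit must be one of 'FPKM', 'counts'")
  v <- SummarizedExperiment::assay(object)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "gene symbols (rownames) must be present and unique")
  if (any(is.na(v)))
    msgs <- c(msgs, "expression values must not be NA")
  else {
    if (any(v < 0)) {
      bad <- which(v < 0, arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf("negative value at gene %s, sample %s",
                              rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
    }
    if (identical(object@unit, "counts") && any(v != round(v))) {
      bad <- which(v != round(v), arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf("counts unit requires integers; %.3f at gene %s, sample %s",
                              v[bad[1L], bad[2L]], rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
    }
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must contain a 'group' column")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns (colnames = sample IDs).
#' @param groups character vector of group labels, one per sample.
#' @param unit `"FPKM"` or `"counts"`.
#' @param species optional species tag stored in metadata.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(10, 2, 10, 2, 5, 5, 5, 5), nrow = 2,
#'             dimnames = list(c("Sox9", "Actb"), paste0("s", 1:4)))
#' ExpressionMatrix(m, groups = c("ref", "ref", "alt", "alt"), unit = "FPKM")
#' @export
ExpressionMatrix <- function(values, groups, unit = c("FPKM", "counts"),
                             species = NA_character_) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (length(groups) != ncol(values))
    stop("'groups' must have one label per sample column")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample%02d", seq_len(ncol(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(exprs = values),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(values)))
  obj <- new("ExpressionMatrix", se, unit = unit)
  S4Vectors::metadata(obj)$species <- species
  validObject(obj)
  obj
}

#' GeneSet: a named set of gene symbols for one species
#'
#' Symbols are canonicalized on construction: human symbols uppercased, mouse
#' symbols title-cased (e.g. `Sox9`). Duplicates after canonicalization are
#' removed with a warning.
#'
#' @slot name character scalar.
#' @slot symbols character vector of canonical symbols.
#' @slot species `"human"` or `"mouse"`.
#' @export
setClass("GeneSet",
  representation(name = "character", symbols = "character", species = "character"))

setValidity("GeneSet", function(object) {
  msgs <- character()
  if (!object@species %in% c("human", "mouse"))
    msgs <- c(msgs, "species must be 'human' or 'mouse'")
  if (anyDuplicated(object@symbols))
    msgs <- c(msgs, "symbols must be unique after canonicalization")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSet
#'
#' @param symbols character vector of gene symbols (canonicalized internally).
#' @param species `"human"` or `"mouse"`.
#' @param name set name.
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(symbols, species = c("human", "mouse"), name = "gene_set") {
  species <- match.arg(species)
  canon <- canonicalizeSymbols(symbols, species)
  if (anyDuplicated(canon)) {
    dup <- unique(canon[duplicated(canon)])
    warning(sprintf("%d duplicate symbol(s) removed after canonicalization: %s",
                    length(dup), paste(utils::head(dup, 5L), collapse = ", ")))
    canon <- unique(canon)
  }
  new("GeneSet", name = name, symbols = canon, species = species)
}

#' OrthologMap: human-mouse gene symbol correspondence
#'
#' The relation may be partial and one-to-many in either direction. Lookups on
#' unmapped symbols return an explicit empty match (see [mouseOrthologs()]),
#' never silently drop the query.
#'
#' @slot pairs data.frame with columns `human`, `mouse` (canonical symbols).
#' @slot provenance free-text note on where the map came from.
#' @export
setClass("OrthologMap",
  representation(pairs = "data.frame", provenance = "character"))

setValidity("OrthologMap", function(object) {
  msgs <- character()
  if (!all(c("human", "mouse") %in% colnames(object@pairs)))
    msgs <- c(msgs, "pairs must have columns 'human' and 'mouse'")
  else if (anyDuplicated(object@pairs[, c("human", "mouse")]))
    msgs <- c(msgs, "duplicate human/mouse pairs")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OrthologMap from paired symbol vectors
#'
#' @param human,mouse parallel character vectors of symbols (canonicalized).
#' @param provenance free-text provenance note.
#' @return An [OrthologMap-class] object.
#' @export
OrthologMap <- function(human, mouse, provenance = "unspecified") {
  stopifnot(length(human) == length(mouse))
  pairs <- unique(data.frame(human = canonicalizeSymbols(human, "human"),
                             mouse = canonicalizeSymbols(mouse, "mouse"),
                             stringsAsFactors = FALSE))
  new("OrthologMap", pairs = pairs, provenance = provenance)
}

#' VusCohort: the surviving variant records of a cohort after MAF triage
#'
#' Produced by [filterVus()]. Holds the surviving records, the per-patient gene
#' sets, cohort-level gene recurrence, phase-naive compound-heterozygous calls,
#' and (when a known-gene list was supplied) the partition of survivors into
#' known-gene hits and novel-gene hits.
#'
#' @slot records data.frame of surviving variant records.
#' @slot perPatientGenes named list, patient -> character vector of genes.
#' @slot recurrence data.frame with columns `gene`, `n_patients`, `n_variants`.
#' @slot cmpdHetGenes data.frame with columns `patient_id`, `gene`.
#' @slot inList,outOfList data.frames partitioning `records` by the known-gene
#'   list (empty `inList` and `outOfList == records` when no list was given).
#' @slot mafCutoff the percent-scale cutoff applied.
#' @export
setClass("VusCohort",
  representation(records = "data.frame", perPatientGenes = "list",
                 recurrence = "data.frame", cmpdHetGenes = "data.frame",
                 inList = "data.frame", outOfList = "data.frame",
                 mafCutoff = "numeric"))

#' TMMFactors: per-sample TMM normalization factors
#'
#' Factors are re-centered so their geometric mean is 1.
#'
#' @slot factors named numeric vector, one per sample, all positive.
#' @slot refSample the reference sample ID.
#' @slot trimM,trimA the two-sided trim fractions applied to M- and A-values.
#' @export
setClass("TMMFactors",
  representation(factors = "numeric", refSample = "character",
                 trimM = "numeric", trimA = "numeric"))

setValidity("TMMFactors", function(object) {
  msgs <- character()
  if (any(object@factors <= 0)) msgs <- c(msgs, "factors must be > 0")
  if (abs(exp(mean(log(object@factors))) - 1) > 1e-8)
    msgs <- c(msgs, "factors must have geometric mean 1")
  if (length(msgs)) msgs else TRUE
})

#' StandardCurve: qPCR dilution-series calibration line
#'
#' Ordinary least squares of Ct (y) on cDNA input amount (x): y = m x + b.
#'
#' @slot slope m, in Ct per unit input.
#' @slot intercept b, in Ct.
#' @slot r.squared coefficient of determination of the fit.
#' @slot logAxis whether x was log-transformed input amount.
#' @export
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric",
                 r.squared = "numeric", logAxis = "logical"))

setValidity("StandardCurve", function(object) {
  if (object@slope == 0) "slope must be nonzero" else TRUE
})

#' CandidatePool: human genes passing the cross-species intersection
#'
#' @slot pool data.frame with one row per qualifying human gene: `human_gene`,
#'   `mouse_gene` (best ortholog by |log2 fc|), `fc`, `direction`,
#'   `n_orthologs_matched`.
#' @slot unmapped character vector of queried human genes with no ortholog.
#' @slot directionPolicy the policy applied (`under`, `over`, or `both`).
#' @slot fcCutoff the fold-change cutoff of the DE classification in force.
#' @export
setClass("CandidatePool",
  representation(pool = "data.frame", unmapped = "character",
                 directionPolicy = "character", fcCutoff = "numeric"))

#' CandidateReport: the ranked candidate-gene report with funnel counts
#'
#' @slot candidates ranked data.frame, one row per candidate gene, with score
#'   components, priority score and knockout-dependence class.
#' @slot funnel named list of per-stage in/out counts.
#' @slot parameters named list of the parameters used.
#' @export
setClass("CandidateReport",
  representation(candidates = "data.frame", funnel = "list", parameters = "list"))

#' TermAnnotation: gene-set annotation for over-representation testing
#'
#' @slot terms named list, term ID -> character vector of annotated genes.
#' @slot universe character vector of all annotated genes.
#' @export
setClass("TermAnnotation",
  representation(terms = "list", universe = "character"))

setValidity("TermAnnotation", function(object) {
  ok <- vapply(object@terms, function(g) all(g %in% object@universe), logical(1))
  if (!all(ok))
    sprintf("term(s) with genes outside the universe: %s",
            paste(utils::head(names(object@terms)[!ok], 3L), collapse = ", "))
  else TRUE
})

#' Construct a TermAnnotation
#'
#' @param terms named list of character vectors (term -> genes), or a
#'   two-column data.frame (`term`, `gene`).
#' @param universe optional explicit universe; defaults to the union of all
#'   annotated genes.
#' @return A [TermAnnotation-class] object.
#' @export
TermAnnotation <- function(terms, universe = NULL) {
  if (is.data.frame(terms)) {
    stopifnot(ncol(terms) >= 2L)
    terms <- split(as.character(terms[[2L]]), as.character(terms[[1L]]))
  }
  terms <- lapply(terms, unique)
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  new("TermAnnotation", terms = terms, universe = unique(universe))
}

#' SimulationConfig: parameters of the synthetic study generator
#'
#' Defaults emulate the study design the pipeline targets: a 32-patient rare
#' disease cohort with 30-1100 variant-bearing genes per patient, a two-group
#' gonadal FPKM matrix with planted under/over-expressed genes, and a 3 vs 3
#' knockout count design with a planted dependent-gene subset.
#'
#' @slot seed integer seed; fixes every generated artifact.
#' @slot nPatients cohort size (default 32).
#' @slot nGenesHuman,nGenesMouse gene-universe sizes.
#' @slot vusGenesRange per-patient range of VUS-bearing gene counts (30-1100).
#' @slot mafZeroProb point mass at MAF 0 in the decoy MAF mixture.
#' @slot mafLogRange percent-scale support of the log-uniform MAF component.
#' @slot nCausal number of planted causal genes (default 20).
#' @slot causalFc planted expression fold change of causal genes (default 4).
#' @slot causalMafMax upper MAF bound (percent) for planted causal variants.
#' @slot fpkmSigma log-normal noise sd (natural log) on FPKM values.
#' @slot nRefSamples,nAltSamples FPKM samples per group.
#' @slot nDeDecoys number of DE-only decoy mouse genes (half under, half over).
#' @slot decoyFcRange fold-change range of DE-only decoys.
#' @slot koReps replicates per genotype in the knockout design (default 3).
#' @slot koDispersion negative-binomial dispersion of knockout counts.
#' @slot koFc planted knockout fold change for dependent genes (default 6).
#' @slot koDependentFraction fraction of causal genes knockout-dependent (7/15).
#' @slot unmappedFraction fraction of human genes left out of the ortholog map.
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nPatients = "integer",
                 nGenesHuman = "integer", nGenesMouse = "integer",
                 vusGenesRange = "integer", mafZeroProb = "numeric",
                 mafLogRange = "numeric", nCausal = "integer",
                 causalFc = "numeric", causalMafMax = "numeric",
                 fpkmSigma = "numeric", nRefSamples = "integer",
                 nAltSamples = "integer", nDeDecoys = "integer",
                 decoyFcRange = "numeric", koReps = "integer",
                 koDispersion = "numeric", koFc = "numeric",
                 koDependentFraction = "numeric", unmappedFraction = "numeric"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nCausal > min(object@nGenesHuman, object@nGenesMouse))
    msgs <- c(msgs, "nCausal must not exceed the gene-universe sizes")
  if (object@vusGenesRange[1L] < 1L ||
      object@vusGenesRange[2L] < object@vusGenesRange[1L])
    msgs <- c(msgs, "vusGenesRange must be an increasing positive range")
  if (object@vusGenesRange[2L] + object@nDeDecoys + object@nCausal >
      object@nGenesHuman)
    msgs <- c(msgs, "gene universe too small for vusGenesRange plus planted genes")
  if (object@mafZeroProb < 0 || object@mafZeroProb > 1)
    msgs <- c(msgs, "mafZeroProb must be in [0,1]")
  if (object@causalFc <= 1) msgs <- c(msgs, "causalFc must exceed 1")
  if (object@koDependentFraction < 0 || object@koDependentFraction > 1)
    msgs <- c(msgs, "koDependentFraction must be in [0,1]")
  if (object@koReps < 2L) msgs <- c(msgs, "koReps must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed integer seed.
#' @param nPatients,nGenesHuman,nGenesMouse,vusGenesRange,mafZeroProb,mafLogRange
#'   cohort-generator parameters; see [SimulationConfig-class].
#' @param nCausal,causalFc,causalMafMax planted-signal parameters.
#' @param fpkmSigma,nRefSamples,nAltSamples,nDeDecoys,decoyFcRange expression
#'   generator parameters.
#' @param koReps,koDispersion,koFc,koDependentFraction knockout design.
#' @param unmappedFraction fraction of human genes absent from the ortholog map.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 7, nPatients = 4, nGenesHuman = 200,
#'                         nGenesMouse = 210, vusGenesRange = c(10, 40),
#'                         nCausal = 5, nDeDecoys = 10)
#' @export
simulationConfig <- function(seed = 1L, nPatients = 32L,
                             nGenesHuman = 4000L, nGenesMouse = 4100L,
                             vusGenesRange = c(30L, 1100L),
                             mafZeroProb = 0.2, mafLogRange = c(1e-4, 1),
                             nCausal = 20L, causalFc = 4, causalMafMax = 0.1,
                             fpkmSigma = 0.15, nRefSamples = 3L, nAltSamples = 3L,
                             nDeDecoys = 80L, decoyFcRange = c(1.6, 3),
                             koReps = 3L, koDispersion = 0.05, koFc = 6,
                             koDependentFraction = 7 / 15,
                             unmappedFraction = 0.05) {
  new("SimulationConfig", seed = as.integer(seed),
      nPatients = as.integer(nPatients),
      nGenesHuman = as.integer(nGenesHuman), nGenesMouse = as.integer(nGenesMouse),
      vusGenesRange = as.integer(vusGenesRange), mafZeroProb = mafZeroProb,
      mafLogRange = as.numeric(mafLogRange), nCausal = as.integer(nCausal),
      causalFc = causalFc, causalMafMax = causalMafMax, fpkmSigma = fpkmSigma,
      nRefSamples = as.integer(nRefSamples), nAltSamples = as.integer(nAltSamples),
      nDeDecoys = as.integer(nDeDecoys), decoyFcRange = as.numeric(decoyFcRange),
      koReps = as.integer(koReps), koDispersion = koDispersion, koFc = koFc,
      koDependentFraction = koDependentFraction,
      unmappedFraction = unmappedFraction)
}

#' PipelineConfig: one document driving the end-to-end pipeline
#'
#' Inputs may be given as in-memory objects or as file paths (resolved through
#' the package readers at run time).
#'
#' @slot inputs named list: `variants`, `fpkm`, `koCounts`, `orthologMap`, and
#'   optionally `knownGenes`, `cellTypeAnnotation`, `conservation`.
#' @slot mafCutoff percent-scale MAF cutoff (default 1).
#' @slot fcInitial,fcEscalated initial and escalated fold-change cutoffs
#'   (defaults 1.5 and 2).
#' @slot directionPolicy `under` (default), `over`, or `both`.
#' @slot weights named priority-score weights summing to 1.
#' @slot alpha adjusted-p threshold for knockout dependence (default 0.05).
#' @slot pseudocount FPKM pseudocount for fold-change ratios (default 0.1).
#' @slot refGroup,altGroup,koRefGroup,koAltGroup group labels in the matrices.
#' @slot seed integer seed recorded with the run.
#' @export
setClass("PipelineConfig",
  representation(inputs = "list", mafCutoff = "numeric", fcInitial = "numeric",
                 fcEscalated = "numeric", directionPolicy = "character",
                 weights = "numeric", alpha = "numeric", pseudocount = "numeric",
                 refGroup = "character", altGroup = "character",
                 koRefGroup = "character", koAltGroup = "character",
                 seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (object@fcEscalated < object@fcInitial)
    msgs <- c(msgs, "fcEscalated must be >= fcInitial")
  if (object@fcInitial <= 1) msgs <- c(msgs, "fcInitial must exceed 1")
  if (object@mafCutoff <= 0) msgs <- c(msgs, "mafCutoff must be positive")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msgs <- c(msgs, "priority-score weights must sum to 1")
  if (!object@directionPolicy %in% c("under", "over", "both"))
    msgs <- c(msgs, "directionPolicy must be 'under', 'over' or 'both'")
  if (length(msgs)) msgs else TRUE
})
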