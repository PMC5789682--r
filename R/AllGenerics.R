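#' @include AllClasses.R
NULL

#' Accessors for crossprio containers
#'
#' Small accessor generics for the package's S4 containers; use these rather
#' than reaching into slots.
#'
#' @param object a crossprio S4 object.
#' @return `exprUnit`: the declared expression unit. `sampleGroups`: named
#'   character vector of group labels. `exprValues`: the numeric assay matrix.
#'   `records`: the variant record data.frame. `recurrence`: the per-gene
#'   recurrence table. `perPatientGenes`: named list of per-patient gene sets.
#'   `cmpdHetGenes`: data.frame of phase-naive compound-het (patient, gene)
#'   pairs. `normFactors`: named numeric TMM factors. `candidates`: the ranked
#'   candidate data.frame. `funnel`: named list of stage counts. `poolGenes`:
#'   the crossref pool data.frame. `unmappedGenes`: character vector of human
#'   genes with no ortholog.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprUnit", function(object) standardGeneric("exprUnit"))
#' @rdname accessors
#' @export
setMethod("exprUnit", "ExpressionMatrix", function(object) object@unit)

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExpressionMatrix", function(object) {
  g <- SummarizedExperiment::colData(object)$group
  names(g) <- colnames(object)
  g
})

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(object) SummarizedExperiment::assay(object, "exprs"))

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "VusCohort", function(object) object@records)

#' @rdname accessors
#' @export
setGeneric("recurrence", function(object) standardGeneric("recurrence"))
#' @rdname accessors
#' @export
setMethod("recurrence", "VusCohort", function(object) object@recurrence)

#' @rdname accessors
#' @export
setGeneric("perPatientGenes", function(object) standardGeneric("perPatientGenes"))
#' @rdname accessors
#' @export
setMethod("perPatientGenes", "VusCohort", function(object) object@perPatientGenes)

#' @rdname accessors
#' @export
setGeneric("cmpdHetGenes", function(object) standardGeneric("cmpdHetGenes"))
#' @rdname accessors
#' @export
setMethod("cmpdHetGenes", "VusCohort", function(object) object@cmpdHetGenes)

#' @rdname accessors
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))
#' @rdname accessors
#' @export
setMethod("normFactors", "TMMFactors", function(object) object@factors)

#' @rdname accessors
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setMethod("candidates", "CandidateReport", function(object) object@candidates)

#' @rdname accessors
#' @export
setGeneric("funnel", function(object) standardGeneric("funnel"))
#' @rdname accessors
#' @export
setMethod("funnel", "CandidateReport", function(object) object@funnel)

#' @rdname accessors
#' @export
setGeneric("poolGenes", function(object) standardGeneric("poolGenes"))
#' @rdname accessors
#' @export
setMethod("poolGenes", "CandidatePool", function(object) object@pool)

#' @rdname accessors
#' @export
setGeneric("unmappedGenes", function(object) standardGeneric("unmappedGenes"))
#' @rdname accessors
#' @export
setMethod("unmappedGenes", "CandidatePool", function(object) object@unmapped)

#' Gene symbols held by an object
#'
#' @param object a [GeneSet-class] or [TermAnnotation-class].
#' @return character vector of symbols (for `TermAnnotation`, the universe).
#' @export
setGeneric("geneSymbols", function(object) standardGeneric("geneSymbols"))
#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "GeneSet", function(object) object@symbols)
#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "TermAnnotation", function(object) object@universe)

setMethod("show", "ExpressionMatrix", function(object) {
  grp <- table(sampleGroups(object))
  cat(sprintf("ExpressionMatrix (%s): %d genes x %d samples\n",
              object@unit, nrow(object), ncol(object)))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "), "\n")
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%s): %d symbols\n",
              object@name, object@species, length(object@symbols)))
})

setMethod("show", "OrthologMap", function(object) {
  cat(sprintf("OrthologMap: %d pairs, %d human, %d mouse symbols\n",
              nrow(object@pairs), length(unique(object@pairs$human)),
              length(unique(object@pairs$mouse))))
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "VusCohort", function(object) {
  cat(sprintf("VusCohort: %d surviving records, %d patients, %d genes (MAF < %g%%)\n",
              nrow(object@records), length(object@perPatientGenes),
              nrow(object@recurrence), object@mafCutoff))
  if (nrow(object@inList))
    cat(sprintf("  known-gene hits routed aside: %d records\n", nrow(object@inList)))
  if (nrow(object@cmpdHetGenes))
    cat(sprintf("  compound-het (patient, gene) pairs: %d\n", nrow(object@cmpdHetGenes)))
})

setMethod("show", "TMMFactors", function(object) {
  cat(sprintf("TMMFactors: %d samples (ref %s, trim M=%g A=%g)\n",
              length(object@factors), object@refSample, object@trimM, object@trimA))
  print(round(object@factors, 4))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: Ct = %.4g * x + %.4g (R^2 = %.4f, %s axis)\n",
              object@slope, object@intercept, object@r.squared,
              if (object@logAxis) "log" else "linear"))
})

setMethod("show", "CandidatePool", function(object) {
  cat(sprintf("CandidatePool: %d genes (policy '%s', fc cutoff %g); %d unmapped query genes\n",
              nrow(object@pool), object@directionPolicy, object@fcCutoff,
              length(object@unmapped)))
})

setMethod("show", "CandidateReport", function(object) {
  cat(sprintf("CandidateReport: %d candidate genes\n", nrow(object@candidates)))
  if (nrow(object@candidates)) {
    top <- utils::head(object@candidates, 5L)
    cat("  top:", paste(sprintf("%s (%.3f)", top$human_gene, top$priority_score),
                        collapse = ", "), "\n")
  }
  cat("  funnel:", paste(sprintf("%s=%s", names(object@funnel),
                                 unlist(object@funnel)), collapse = " "), "\n")
})

setMethod("show", "TermAnnotation", function(object) {
  cat(sprintf("TermAnnotation: %d terms over a universe of %d genes\n",
              length(object@terms), length(object@universe)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: seed %d; %d patients; %d/%d human/mouse genes; ",
                     "%d causal (fc %g); ko %d vs %d (fc %g, disp %g)\n"),
              object@seed, object@nPatients, object@nGenesHuman, object@nGenesMouse,
              object@nCausal, object@causalFc, object@koReps, object@koReps,
              object@koFc, object@koDispersion))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: MAF < %g%%, fc %g -> %g, policy '%s', alpha %g\n",
              object@mafCutoff, object@fcInitial, object@fcEscalated,
              object@directionPolicy, object@alpha))
})
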