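#' Filter a cohort variant table down to variants of unknown significance
#'
#' Applies the rare-variant triage of an uninformative-exome cohort: keep
#' variants with MAF strictly below `maf_cutoff_percent` (default 1%), and,
#' when a curated known-gene list is supplied, partition survivors into
#' known-gene hits (routed to clinical review, away from novel-candidate
#' discovery) and novel-gene hits. Missing MAF values are treated as 0
#' (rare until proven common) with a message. Also builds the per-patient gene
#' index, the cohort-level gene recurrence table, and phase-naive compound-het
#' calls (>= 2 surviving het-class variants in one gene in one patient).
#'
#' @param variants data.frame of variant records ([readVariantTable()] layout).
#' @param maf_cutoff_percent strict upper MAF bound on the percent scale
#'   (default 1, i.e. MAF < 1%).
#' @param known_gene_set optional [GeneSet-class] (or character vector of human
#'   symbols) of established disease genes.
#' @return A [VusCohort-class].
#' @examples
#' tsv <- system.file("extdata", "table2_vus.tsv", package = "crossprio")
#' cohort <- filterVus(readVariantTable(tsv), maf_cutoff_percent = 1)
#' nrow(records(cohort))       # all 27 records survive (max MAF 0.8%)
#' @export
filterVus <- function(variants, maf_cutoff_percent = 1, known_gene_set = NULL) {
  stopifnot(is.data.frame(variants), maf_cutoff_percent > 0)
  need <- c("patient_id", "gene", "zygosity", "maf_percent")
  if (!all(need %in% colnames(variants)))
    stop("variants must carry columns: ", paste(need, collapse = ", "))
  maf <- variants$maf_percent
  if (anyNA(maf)) {
    message(sprintf("%d record(s) with missing MAF treated as 0", sum(is.na(maf))))
    maf[is.na(maf)] <- 0
  }
  surv <- variants[maf < maf_cutoff_percent, , drop = FALSE]
  rownames(surv) <- NULL

  known <- if (is.null(known_gene_set)) character()
           else if (is(known_gene_set, "GeneSet")) geneSymbols(known_gene_set)
           else canonicalizeSymbols(known_gene_set, "human")
  in_list <- surv[surv$gene %in% known, , drop = FALSE]
  out_list <- surv[!surv$gene %in% known, , drop = FALSE]

  ppg <- lapply(split(surv$gene, surv$patient_id), function(g) sort(unique(g)))
  rec <- recurrenceTable(surv)
  het <- surv[surv$zygosity %in% c("het", "cmpd_het"), , drop = FALSE]
  pg <- paste(het$patient_id, het$gene, sep = "\r")
  multi <- unique(pg[duplicated(pg)])
  ch <- if (length(multi)) {
    parts <- strsplit(multi, "\r", fixed = TRUE)
    data.frame(patient_id = vapply(parts, `[[`, character(1), 1L),
               gene = vapply(parts, `[[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else data.frame(patient_id = character(), gene = character(),
                    stringsAsFactors = FALSE)

  new("VusCohort", records = surv, perPatientGenes = ppg, recurrence = rec,
      cmpdHetGenes = ch, inList = in_list, outOfList = out_list,
      mafCutoff = maf_cutoff_percent)
}

recurrenceTable <- function(surv) {
  if (!nrow(surv))
    return(data.frame(gene = character(), n_patients = integer(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  np <- vapply(split(surv$patient_id, surv$gene),
               function(p) length(unique(p)), integer(1))
  nv <- vapply(split(surv$patient_id, surv$gene), length, integer(1))
  out <- data.frame(gene = names(np), n_patients = unname(np),
                    n_variants = unname(nv), stringsAsFactors = FALSE)
  out[order(-out$n_patients, -out$n_variants, out$gene), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Harmonize in-silico pathogenicity predictions
#'
#' Maps raw predictor tokens (e.g. SIFT `"damaging"`, PolyPhen
#' `"probably_damaging"`) to the three-level call `deleterious` / `tolerated` /
#' `unknown`, one harmonized `call_<predictor>` column per predictor, and adds
#' a per-record `deleterious_count`.
#'
#' @param variants data.frame with raw `pred_<predictor>` columns (records
#'   without such columns get `deleterious_count = 0` and calls `unknown`).
#' @param rules named list, predictor -> named character map from lowercased
#'   raw token to harmonized call. Defaults cover SIFT and PolyPhen vocabulary.
#' @param strict if `TRUE`, an unmapped token is an error; otherwise it becomes
#'   `unknown`.
#' @return the input data.frame with `call_*` columns and `deleterious_count`.
#' @examples
#' v <- data.frame(patient_id = "P1", gene = "SOX9", zygosity = "het",
#'                 maf_percent = 0, pred_SIFT = "damaging",
#'                 pred_PolyPhen = "probably_damaging")
#' tagInsilico(v)$deleterious_count  # 2
#' @export
tagInsilico <- function(variants, rules = defaultPredictionRules(),
                        strict = FALSE) {
  stopifnot(is.data.frame(variants))
  predcols <- grep("^pred_", colnames(variants), value = TRUE)
  preds <- sub("^pred_", "", predcols)
  ndel <- integer(nrow(variants))
  for (i in seq_along(preds)) {
    p <- preds[i]
    rule <- rules[[p]]
    if (is.null(rule) && strict)
      stop("no harmonization rule for predictor: ", p)
    raw <- tolower(trimws(as.character(variants[[predcols[i]]])))
    call <- rep("unknown", length(raw))
    if (!is.null(rule)) {
      hit <- raw %in% names(rule)
      call[hit] <- unname(rule[raw[hit]])
      bad <- !hit & nzchar(raw) & !raw %in% c(".", "na", "-")
      if (any(bad) && strict)
        stop(sprintf("unknown %s token '%s' at row %d",
                     p, raw[which(bad)[1L]], which(bad)[1L]))
    }
    variants[[paste0("call_", p)]] <- call
    ndel <- ndel + (call == "deleterious")
  }
  variants$deleterious_count <- ndel
  variants$n_predictors <- length(preds)
  variants
}

#' Default token-harmonization rules for SIFT and PolyPhen
#'
#' @return named list of predictor token maps, suitable for [tagInsilico()].
#' @export
defaultPredictionRules <- function() {
  list(
    SIFT = c(damaging = "deleterious", deleterious = "deleterious",
             tolerated = "tolerated", benign = "tolerated"),
    PolyPhen = c(probably_damaging = "deleterious",
                 "probably damaging" = "deleterious",
                 possibly_damaging = "deleterious",
                 "possibly damaging" = "deleterious",
                 damaging = "deleterious",
                 benign = "tolerated", tolerated = "tolerated"))
}

#' Cohort-level gene recurrence
#'
#' Number of distinct patients and total variant rows per gene among the
#' surviving records of a [VusCohort-class].
#'
#' @param cohort a [VusCohort-class].
#' @return data.frame with columns `gene`, `n_patients`, `n_variants`, sorted
#'   by decreasing recurrence.
#' @examples
#' tsv <- system.file("extdata", "table2_vus.tsv", package = "crossprio")
#' rec <- geneRecurrence(filterVus(readVariantTable(tsv)))
#' rec[rec$gene == "ADAMTS16", ]  # 3 patients, 3 variants
#' @export
geneRecurrence <- function(cohort) {
  stopifnot(is(cohort, "VusCohort"))
  cohort@recurrence
}
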