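#' Cross-reference human VUS genes with model-organism DE genes
#'
#' The central intersection of the discovery strategy: a human VUS-bearing
#' gene enters the candidate pool if at least one of its mapped mouse
#' orthologs is differentially expressed in the direction the policy demands
#' (default `"under"`: underexpressed in the affected/alternate group, the
#' direction in which higher wild-type expression correlates with normal
#' development). When a known-gene list was supplied to [filterVus()], only
#' novel-gene (out-of-list) hits are queried. Unmapped human genes are
#' reported explicitly, never silently dropped.
#'
#' With one-to-many orthology, any passing ortholog qualifies the gene and the
#' ortholog with the largest absolute log2 fold change supplies the recorded
#' fc; the number of matching orthologs is recorded.
#'
#' @param vus_cohort a [VusCohort-class].
#' @param de_records classified DE table ([foldChangeDE()], possibly after
#'   [escalateCutoff()]).
#' @param ortholog_map an [OrthologMap-class]; must be non-empty.
#' @param direction_policy `"under"` (default), `"over"`, or `"both"`.
#' @return A [CandidatePool-class].
#' @export
crossRef <- function(vus_cohort, de_records, ortholog_map,
                     direction_policy = c("under", "over", "both")) {
  direction_policy <- match.arg(direction_policy)
  stopifnot(is(vus_cohort, "VusCohort"), is(ortholog_map, "OrthologMap"),
            is.data.frame(de_records))
  if (!nrow(ortholog_map@pairs)) stop("empty ortholog map")
  wanted <- switch(direction_policy,
                   under = "under_in_alt", over = "over_in_alt",
                   both = c("under_in_alt", "over_in_alt"))
  qgenes <- sort(unique(vus_cohort@outOfList$gene))
  orth <- mouseOrthologs(ortholog_map, qgenes)
  unmapped <- qgenes[lengths(orth) == 0L]

  de_idx <- match(unlist(orth, use.names = FALSE), de_records$gene)
  rows <- vector("list", length(qgenes))
  for (i in seq_along(qgenes)) {
    mm <- orth[[i]]
    if (!length(mm)) next
    j <- match(mm, de_records$gene)
    ok <- !is.na(j) & de_records$direction[j] %in% wanted
    if (!any(ok)) next
    jj <- j[ok]
    best <- jj[which.max(abs(log2(de_records$fc[jj])))]
    if (sum(ok) > 1L)
      message(sprintf("gene %s: %d orthologs pass; using %s (largest |log2 fc|)",
                      qgenes[i], sum(ok), de_records$gene[best]))
    rows[[i]] <- data.frame(human_gene = qgenes[i],
                            mouse_gene = de_records$gene[best],
                            fc = de_records$fc[best],
                            direction = de_records$direction[best],
                            n_orthologs_matched = sum(ok),
                            stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pool))
    pool <- data.frame(human_gene = character(), mouse_gene = character(),
                       fc = numeric(), direction = character(),
                       n_orthologs_matched = integer(), stringsAsFactors = FALSE)
  rownames(pool) <- NULL
  fcc <- attr(de_records, "fc_cutoff")
  new("CandidatePool", pool = pool, unmapped = unmapped,
      directionPolicy = direction_policy,
      fcCutoff = if (is.null(fcc)) NA_real_ else fcc)
}

#' Default multi-criteria prioritization configuration
#'
#' The qualitative triage criteria of the discovery procedure (variant rarity,
#' residue conservation, cohort recurrence, in-silico pathogenicity calls,
#' gonadal cell-type expressivity, fold-change magnitude) are formalized as a
#' weighted additive score with equal default weights of 1/6. A
#' literature-availability criterion is not computable and carries weight 0;
#' its mass is absorbed by the equal renormalization over the six computable
#' criteria.
#'
#' @param weights named non-negative weights over
#'   `rarity, conservation, recurrence, insilico, cell_type, fc_magnitude`;
#'   must sum to 1.
#' @param rarity_knee MAF (percent) at and below which the rarity component
#'   saturates at 1 (default 0.1%); above it the component decays linearly to
#'   0 at the VUS cutoff.
#' @param fc_saturation fold change at which the fc-magnitude component
#'   saturates (default 4).
#' @param recurrence_cap patient count at which recurrence saturates (default 3).
#' @return a validated list, suitable for [scoreCandidates()].
#' @export
priorityConfig <- function(weights = c(rarity = 1, conservation = 1,
                                       recurrence = 1, insilico = 1,
                                       cell_type = 1, fc_magnitude = 1) / 6,
                           rarity_knee = 0.1, fc_saturation = 4,
                           recurrence_cap = 3) {
  need <- c("rarity", "conservation", "recurrence", "insilico",
            "cell_type", "fc_magnitude")
  if (!setequal(names(weights), need))
    stop("weights must be named exactly: ", paste(need, collapse = ", "))
  weights <- weights[need]
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (fc_saturation <= 1) stop("fc_saturation must exceed 1")
  list(weights = weights, rarity_knee = rarity_knee,
       fc_saturation = fc_saturation, recurrence_cap = recurrence_cap)
}

#' Score and rank the candidate pool
#'
#' Computes the six score components on \[0,1\] for each pool gene and ranks
#' by the weighted sum:
#' \describe{
#'   \item{rarity}{1 when the best supporting MAF is at or below the knee
#'     (default 0.1%), decaying linearly to 0 at the VUS MAF cutoff.}
#'   \item{conservation}{normalized provided score; 0.5 (neutral) when no
#'     conservation table covers the gene.}
#'   \item{recurrence}{`min(n_patients, cap)/cap`, cap = 3.}
#'   \item{insilico}{best supporting variant's `deleterious_count` over the
#'     number of predictors (records are run through [tagInsilico()] if not
#'     already tagged).}
#'   \item{cell_type}{1 if annotated expressed in the male supporting lineage,
#'     0 if annotated not expressed, 0.5 when unknown.}
#'   \item{fc_magnitude}{`min(log2(fc)/log2(saturation), 1)`.}
#' }
#' Ties are broken by higher recurrence, then lower best MAF, then symbol.
#'
#' @param pool a [CandidatePool-class] from [crossRef()].
#' @param vus_cohort the [VusCohort-class] supplying the variant evidence.
#' @param config list from [priorityConfig()].
#' @param cell_type_annotation optional data.frame with columns `gene` (human
#'   symbol) and `expressed` (logical: expressed in the male supporting
#'   lineage).
#' @param conservation_table optional data.frame with columns `gene` and
#'   `score` (non-negative; normalized by its maximum when > 1).
#' @return ranked data.frame of candidates with evidence and score columns.
#' @export
scoreCandidates <- function(pool, vus_cohort, config = priorityConfig(),
                            cell_type_annotation = NULL,
                            conservation_table = NULL) {
  stopifnot(is(pool, "CandidatePool"), is(vus_cohort, "VusCohort"))
  pl <- poolGenes(pool)
  if (!nrow(pl)) return(emptyCandidateFrame())
  recs <- vus_cohort@outOfList
  if (!"deleterious_count" %in% colnames(recs)) recs <- tagInsilico(recs)
  rec <- recurrenceTable(recs)
  cutoff <- vus_cohort@mafCutoff

  consv <- NULL
  if (!is.null(conservation_table)) {
    s <- conservation_table$score
    if (max(s, na.rm = TRUE) > 1) s <- s / max(s, na.rm = TRUE)
    consv <- stats::setNames(pmin(pmax(s, 0), 1),
                             canonicalizeSymbols(conservation_table$gene, "human"))
  }
  ctype <- NULL
  if (!is.null(cell_type_annotation))
    ctype <- stats::setNames(cell_type_annotation$expressed,
                             canonicalizeSymbols(cell_type_annotation$gene, "human"))

  n <- nrow(pl)
  comp <- matrix(NA_real_, n, 6,
                 dimnames = list(NULL, c("rarity", "conservation", "recurrence",
                                         "insilico", "cell_type", "fc_magnitude")))
  best_maf <- n_pat <- n_var <- numeric(n)
  for (i in seq_len(n)) {
    g <- pl$human_gene[i]
    sup <- recs[recs$gene == g, , drop = FALSE]
    if (!nrow(sup)) stop("pool gene without supporting variants: ", g)
    maf <- sup$maf_percent; maf[is.na(maf)] <- 0
    best_maf[i] <- min(maf)
    ri <- rec[rec$gene == g, ]
    n_pat[i] <- ri$n_patients; n_var[i] <- ri$n_variants

    comp[i, "rarity"] <-
      if (best_maf[i] <= config$rarity_knee) 1
      else max(0, (cutoff - best_maf[i]) / (cutoff - config$rarity_knee))
    comp[i, "conservation"] <-
      if (!is.null(consv) && g %in% names(consv) && !is.na(consv[g])) consv[[g]]
      else 0.5
    comp[i, "recurrence"] <-
      min(n_pat[i], config$recurrence_cap) / config$recurrence_cap
    comp[i, "insilico"] <-
      if (all(sup$n_predictors == 0)) 0
      else max(sup$deleterious_count / pmax(sup$n_predictors, 1L))
    comp[i, "cell_type"] <-
      if (!is.null(ctype) && g %in% names(ctype) && !is.na(ctype[g]))
        as.numeric(ctype[[g]])
      else 0.5
    comp[i, "fc_magnitude"] <-
      min(log2(pl$fc[i]) / log2(config$fc_saturation), 1)
  }
  score <- as.numeric(comp %*% config$weights)
  out <- data.frame(pl, n_variants = n_var, n_patients = n_pat,
                    best_maf = best_maf,
                    stats::setNames(as.data.frame(comp),
                                    paste0("score_", colnames(comp))),
                    priority_score = score, stringsAsFactors = FALSE)
  ord <- order(-out$priority_score, -out$n_patients, out$best_maf,
               out$human_gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

emptyCandidateFrame <- function() {
  data.frame(human_gene = character(), mouse_gene = character(), fc = numeric(),
             direction = character(), n_orthologs_matched = integer(),
             n_variants = integer(), n_patients = integer(), best_maf = numeric(),
             score_rarity = numeric(), score_conservation = numeric(),
             score_recurrence = numeric(), score_insilico = numeric(),
             score_cell_type = numeric(), score_fc_magnitude = numeric(),
             priority_score = numeric(), rank = integer(),
             stringsAsFactors = FALSE)
}

#' Annotate candidates with knockout dependence
#'
#' Checks each candidate's mouse ortholog(s) in a replicate-based knockout DE
#' table ([deTestAdjusted()]): `significant` when some ortholog is
#' underexpressed in the knockout with `p_adj < alpha`; `same_direction_ns`
#' when underexpressed without significance; `not_supported` when tested but
#' not underexpressed; `untested` when absent from the knockout matrix.
#'
#' @param candidates ranked data.frame from [scoreCandidates()].
#' @param ko_de_records data.frame from [deTestAdjusted()].
#' @param ortholog_map an [OrthologMap-class].
#' @param alpha adjusted-p threshold (default 0.05).
#' @return `candidates` with added columns `ko_dependent`, `ko_fc`, `ko_p_adj`.
#' @export
annotateKoDependence <- function(candidates, ko_de_records, ortholog_map,
                                 alpha = 0.05) {
  stopifnot(is.data.frame(candidates), is.data.frame(ko_de_records),
            is(ortholog_map, "OrthologMap"))
  n <- nrow(candidates)
  status <- rep("untested", n)
  kofc <- kop <- rep(NA_real_, n)
  if (n) {
    orth <- mouseOrthologs(ortholog_map, candidates$human_gene)
    for (i in seq_len(n)) {
      mm <- unique(c(candidates$mouse_gene[i], orth[[candidates$human_gene[i]]]))
      j <- match(mm, ko_de_records$gene)
      j <- j[!is.na(j)]
      if (!length(j)) next
      under <- ko_de_records$fc[j] > 1
      sig <- under & !is.na(ko_de_records$p_adj[j]) &
        ko_de_records$p_adj[j] < alpha
      pick <- if (any(sig)) j[sig][which.min(ko_de_records$p_adj[j[sig]])]
              else if (any(under)) j[under][which.max(ko_de_records$fc[j[under]])]
              else j[which.min(ko_de_records$p_adj[j])]
      status[i] <- if (any(sig)) "significant"
                   else if (any(under)) "same_direction_ns"
                   else "not_supported"
      kofc[i] <- ko_de_records$fc[pick]
      kop[i] <- ko_de_records$p_adj[pick]
    }
  }
  candidates$ko_dependent <- status
  candidates$ko_fc <- kofc
  candidates$ko_p_adj <- kop
  candidates
}

#' Assemble the final candidate report
#'
#' Bundles the ranked candidate table with the per-stage funnel counts and the
#' parameters of the run.
#'
#' @param candidates ranked data.frame ([scoreCandidates()], optionally after
#'   [annotateKoDependence()]).
#' @param stage_counts named list of per-stage in/out counts.
#' @param parameters named list of run parameters (recorded verbatim).
#' @return A [CandidateReport-class].
#' @export
buildReport <- function(candidates, stage_counts, parameters = list()) {
  stopifnot(is.data.frame(candidates), is.list(stage_counts))
  new("CandidateReport", candidates = candidates, funnel = stage_counts,
      parameters = parameters)
}

#' Write a candidate report to disk
#'
#' Emits `candidates.tsv` (the ranked table), `funnel.json` (stage counts and
#' parameters), and, when the report records them, `unmapped_genes.txt`.
#'
#' @param report a [CandidateReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "CandidateReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(candidates(report), file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(funnel = funnel(report),
                            parameters = report@parameters),
                       file.path(dir, "funnel.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  um <- report@parameters$unmapped_genes
  if (!is.null(um) && length(um))
    writeLines(um, file.path(dir, "unmapped_genes.txt"))
  invisible(dir)
}
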