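#' Fold-change classification of a two-group expression matrix
#'
#' The primary screen of the gonadal expression analysis: for each gene,
#' `fc = (mean_ref + pseudocount) / (mean_alt + pseudocount)` and a direction
#' class relative to the alternate group:
#' `under_in_alt` when `fc >= fc_cutoff`, `over_in_alt` when
#' `fc <= 1/fc_cutoff`, otherwise `unchanged`. The classification boundary is
#' inclusive. With `pseudocount = 0`, genes whose denominator is zero are
#' flagged `undefined` (fc `NA`) rather than crashing.
#'
#' @param mat an [ExpressionMatrix-class] with unit `"FPKM"`.
#' @param ref_group,alt_group group labels present in `sampleGroups(mat)`
#'   (reference = unaffected/wild-type; alternate = the contrasted condition).
#' @param fc_cutoff ratio cutoff, > 1 (default 1.5).
#' @param pseudocount added to both group means before the ratio (default 0.1
#'   FPKM; expression at this stage can be exactly zero).
#' @return data.frame with columns `gene`, `mean_ref`, `mean_alt`, `fc`,
#'   `direction`, `p_adj` (`NA`; this screen is ratio-only), plus attributes
#'   `fc_cutoff` and `pseudocount`.
#' @examples
#' m <- matrix(c(40, 5, 40, 5, 10, 5, 10, 5), nrow = 2,
#'             dimnames = list(c("Sox9", "Actb"), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, groups = c("B6", "B6", "POS", "POS"), unit = "FPKM")
#' foldChangeDE(em, "B6", "POS", fc_cutoff = 1.5)
#' @export
foldChangeDE <- function(mat, ref_group, alt_group, fc_cutoff = 1.5,
                         pseudocount = 0.1) {
  stopifnot(is(mat, "ExpressionMatrix"), fc_cutoff > 1, pseudocount >= 0)
  if (exprUnit(mat) != "FPKM")
    warning("fold-change screening is intended for FPKM-unit matrices")
  grp <- sampleGroups(mat)
  for (g in c(ref_group, alt_group))
    if (!g %in% grp) stop("group label absent from matrix: ", g)
  v <- exprValues(mat)
  mref <- rowMeans(v[, grp == ref_group, drop = FALSE])
  malt <- rowMeans(v[, grp == alt_group, drop = FALSE])
  fc <- (mref + pseudocount) / (malt + pseudocount)
  undef <- (malt + pseudocount) == 0
  fc[undef] <- NA_real_
  out <- data.frame(gene = rownames(v), mean_ref = unname(mref),
                    mean_alt = unname(malt), fc = unname(fc),
                    direction = classifyDirection(fc, fc_cutoff),
                    p_adj = NA_real_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fc_cutoff") <- fc_cutoff
  attr(out, "pseudocount") <- pseudocount
  out
}

classifyDirection <- function(fc, cutoff) {
  d <- rep("unchanged", length(fc))
  d[!is.na(fc) & fc >= cutoff] <- "under_in_alt"
  d[!is.na(fc) & fc <= 1 / cutoff] <- "over_in_alt"
  d[is.na(fc)] <- "undefined"
  d
}

#' Re-classify differential-expression records at a stricter cutoff
#'
#' Implements the cutoff escalation of the screen (e.g. 1.5 to 2): directions
#' are recomputed from the stored fold changes at `new_cutoff`. The resulting
#' non-`unchanged` set is always a subset of the input non-`unchanged` set.
#'
#' @param de_records data.frame from [foldChangeDE()] (or any frame with `fc`).
#' @param new_cutoff the stricter cutoff; must be >= the cutoff the records
#'   were classified with and >= 1.
#' @return the records re-classified, with attribute `fc_cutoff` updated.
#' @export
escalateCutoff <- function(de_records, new_cutoff) {
  stopifnot(is.data.frame(de_records), "fc" %in% colnames(de_records))
  if (new_cutoff < 1) stop("new_cutoff must be >= 1")
  old <- attr(de_records, "fc_cutoff")
  if (!is.null(old) && new_cutoff < old)
    stop(sprintf("new_cutoff (%g) below the active cutoff (%g)", new_cutoff, old))
  de_records$direction <- classifyDirection(de_records$fc, new_cutoff)
  attr(de_records, "fc_cutoff") <- new_cutoff
  de_records
}

#' TMM normalization factors for a count matrix
#'
#' Trimmed mean of M-values between-sample normalization: for each sample
#' against the reference sample, gene-wise log2 ratios of library-size-scaled
#' counts (M-values) are doubly trimmed — by `trim_m` on the M-values and
#' `trim_a` on the average log intensities (A-values) — and averaged with
#' inverse asymptotic-variance (precision) weights; the factor is 2 to that
#' mean. Genes with a zero count in either member of a pair are excluded from
#' that pair's trim. Factors are re-centered to geometric mean 1.
#'
#' When `ref_sample` is not given, the sample whose upper-quartile
#' count-per-library value is closest to the across-sample mean is used.
#'
#' @param mat an [ExpressionMatrix-class] with unit `"counts"`, >= 2 samples.
#' @param ref_sample optional reference sample ID.
#' @param trim_m two-sided trim fraction on M-values (default 0.30).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return A [TMMFactors-class].
#' @examples
#' cnt <- matrix(c(100L, 200L, 300L, 200L, 400L, 600L), ncol = 2,
#'               dimnames = list(paste0("g", 1:3), c("a", "b")))
#' em <- ExpressionMatrix(cnt, groups = c("x", "y"), unit = "counts")
#' normFactors(tmmNormalize(em))  # pure depth scaling: both factors 1
#' @export
tmmNormalize <- function(mat, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(is(mat, "ExpressionMatrix"))
  if (exprUnit(mat) != "counts") stop("TMM normalization requires a counts matrix")
  y <- exprValues(mat)
  if (ncol(y) < 2L) stop("TMM needs >= 2 samples")
  lib <- colSums(y)
  if (any(lib == 0))
    stop("sample with all-zero counts: ",
         paste(colnames(y)[lib == 0], collapse = ", "))
  if (is.null(ref_sample)) {
    f75 <- apply(y, 2L, stats::quantile, probs = 0.75) / lib
    ref_sample <- colnames(y)[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref_sample %in% colnames(y)) stop("unknown ref_sample: ", ref_sample)
  f <- vapply(colnames(y), function(s)
    tmmPairFactor(y[, s], y[, ref_sample], lib[s], lib[ref_sample],
                  trim_m, trim_a), numeric(1))
  f <- recenterFactors(f)
  new("TMMFactors", factors = f, refSample = ref_sample,
      trimM = trim_m, trimA = trim_a)
}

# One sample vs reference: weighted doubly-trimmed mean of M-values.
tmmPairFactor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # asymptotic variance of M under binomial sampling; weight = 1/v
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Replicate-based differential-expression test with adjusted p-values
#'
#' The knockout-vs-wild-type analysis: TMM-normalize the count matrix, test
#' each gene for a group difference, and control FDR with Benjamini-Hochberg
#' across tested genes; a gene is significant when `p_adj < alpha`.
#'
#' The default engine is the quasi-likelihood negative-binomial fit of
#' \pkg{edgeR} (the standard analysis behind TMM-normalized counts with
#' adjusted p-values, and the one with usable power at n = 3 per group).
#' `method = "welch"` instead applies a gene-wise unequal-variance t-test on
#' `log2(TMM-normalized counts-per-million + 0.5)`; genes with zero variance in
#' both groups get `p = NA` and are never called significant.
#'
#' @param mat an [ExpressionMatrix-class] with unit `"counts"`.
#' @param ref_group,alt_group group labels (e.g. wild-type vs knockout);
#'   each needs >= 2 replicates.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param method `"edgerQL"` (default) or `"welch"`.
#' @return data.frame with columns `gene`, `mean_ref`, `mean_alt` (normalized
#'   CPM), `fc` (`mean_ref/mean_alt` scale, from the model for `edgerQL`),
#'   `direction` (`under_in_alt`/`over_in_alt` by fc sign), `p`, `p_adj`,
#'   `significant`; attribute `alpha` and `method`.
#' @export
deTestAdjusted <- function(mat, ref_group, alt_group, alpha = 0.05,
                           method = c("edgerQL", "welch")) {
  method <- match.arg(method)
  stopifnot(is(mat, "ExpressionMatrix"))
  if (exprUnit(mat) != "counts") stop("replicate-based testing requires counts")
  grp <- sampleGroups(mat)
  for (g in c(ref_group, alt_group))
    if (sum(grp == g) < 2L)
      stop(sprintf("group '%s' needs >= 2 replicates", g))
  sel <- grp %in% c(ref_group, alt_group)
  y <- exprValues(mat)[, sel, drop = FALSE]
  grp <- factor(grp[sel], levels = c(ref_group, alt_group))

  tmm <- normFactors(tmmNormalize(ExpressionMatrix(y, groups = as.character(grp),
                                                   unit = "counts")))
  eff <- colSums(y) * tmm
  cpm <- t(t(y) / eff) * 1e6
  mref <- rowMeans(cpm[, grp == ref_group, drop = FALSE])
  malt <- rowMeans(cpm[, grp == alt_group, drop = FALSE])

  if (method == "edgerQL") {
    dge <- edgeR::DGEList(counts = y, group = grp,
                          norm.factors = unname(tmm))
    design <- stats::model.matrix(~grp)
    dge <- edgeR::estimateDisp(dge, design)
    fit <- edgeR::glmQLFit(dge, design)
    res <- edgeR::glmQLFTest(fit, coef = 2L)$table
    fc <- 2^(-res$logFC)  # coef is alt vs ref; report on the ref/alt scale
    p <- res$PValue
  } else {
    lx <- log2(cpm[, grp == ref_group, drop = FALSE] + 0.5)
    ly <- log2(cpm[, grp == alt_group, drop = FALSE] + 0.5)
    n1 <- ncol(lx); n2 <- ncol(ly)
    m1 <- rowMeans(lx); m2 <- rowMeans(ly)
    v1 <- apply(lx, 1L, stats::var); v2 <- apply(ly, 1L, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    p[se2 == 0] <- NA_real_  # constant gene: test undefined, never significant
    fc <- 2^(m1 - m2)
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(y), mean_ref = unname(mref),
                    mean_alt = unname(malt), fc = unname(fc),
                    direction = ifelse(fc > 1, "under_in_alt",
                                       ifelse(fc < 1, "over_in_alt", "unchanged")),
                    p = unname(p), p_adj = unname(p_adj),
                    significant = !is.na(p_adj) & p_adj < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  out
}
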