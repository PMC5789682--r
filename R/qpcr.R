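#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on cDNA input amount across a dilution series
#' (the classic y = m x + b calibration, typically five 1:4 dilutions of a
#' pooled-sample mix). Replicate Ct values at the same input amount are
#' averaged before fitting. `log_axis = TRUE` regresses Ct on `log(amount)`
#' instead, for protocols that calibrate against log-dilution.
#'
#' @param dilution_series data.frame with columns `amount` (cDNA input) and
#'   `ct` (cycle threshold); replicate rows per amount allowed.
#' @param log_axis fit against `log(amount)` rather than `amount`.
#' @return A [StandardCurve-class] with slope, intercept and R-squared.
#' @examples
#' d <- data.frame(amount = c(1, 0.25, 0.0625), ct = c(18, 21.3, 24.6))
#' curve <- fitStandardCurve(d)
#' ctToQuantity(20, curve)
#' @export
fitStandardCurve <- function(dilution_series, log_axis = FALSE) {
  stopifnot(is.data.frame(dilution_series),
            all(c("amount", "ct") %in% colnames(dilution_series)))
  agg <- stats::aggregate(ct ~ amount, data = dilution_series, FUN = mean)
  if (nrow(agg) < 2L) stop("need >= 2 distinct dilution points")
  x <- if (log_axis) log(agg$amount) else agg$amount
  fit <- stats::lm(agg$ct ~ x)
  m <- unname(stats::coef(fit)[2L])
  if (is.na(m) || abs(m) < 1e-12) stop("singular or flat standard-curve fit")
  tss <- sum((agg$ct - mean(agg$ct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  new("StandardCurve", slope = m, intercept = unname(stats::coef(fit)[1L]),
      r.squared = r2, logAxis = log_axis)
}

#' Convert a Ct value to a quantity on the standard-curve axis
#'
#' Inverts the calibration line: `x = (ct - b) / m`. With a log-axis curve the
#' returned value is on the log-amount axis.
#'
#' @param ct numeric Ct value(s).
#' @param curve a [StandardCurve-class].
#' @return numeric quantity on the fitted axis.
#' @export
ctToQuantity <- function(ct, curve) {
  stopifnot(is(curve, "StandardCurve"))
  (ct - curve@intercept) / curve@slope
}

#' Direction concordance between RNA-seq and qPCR fold changes
#'
#' For genes shared between a fold-change DE table and a qPCR fold-change
#' table, reports the fraction whose log fold changes agree in sign (the
#' standard cross-platform validation readout).
#'
#' @param de_records data.frame from [foldChangeDE()] (columns `gene`, `fc`).
#' @param qpcr_fc_table data.frame with columns `gene` and `fc` on the same
#'   ratio scale (reference over alternate).
#' @return list with `agreement` (fraction in \[0,1\]), `n_shared`, and a
#'   per-gene data.frame `detail`.
#' @export
qpcrConcordance <- function(de_records, qpcr_fc_table) {
  stopifnot(all(c("gene", "fc") %in% colnames(de_records)),
            all(c("gene", "fc") %in% colnames(qpcr_fc_table)))
  shared <- intersect(de_records$gene, qpcr_fc_table$gene)
  if (!length(shared)) stop("no shared gene symbols between the two tables")
  a <- de_records$fc[match(shared, de_records$gene)]
  b <- qpcr_fc_table$fc[match(shared, qpcr_fc_table$gene)]
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  agree <- sign(log(a[ok])) == sign(log(b[ok]))
  list(agreement = mean(agree), n_shared = sum(ok),
       detail = data.frame(gene = shared[ok], fc_rnaseq = a[ok],
                           fc_qpcr = b[ok], agree = agree,
                           stringsAsFactors = FALSE))
}
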