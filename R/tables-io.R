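#' Read a per-patient variant table
#'
#' Reads one variant observation per row, either from a tab-separated table
#' (header-driven, mirroring a clinical VUS summary table: patient ID, gene
#' symbol, zygosity, HGVS c./p., MAF in percent, optional in-silico prediction
#' and conservation columns) or from a VCF in which each record carries a gene
#' symbol and an allele-frequency annotation in INFO.
#'
#' Gene symbols are canonicalized to the human convention (uppercase). HGVS
#' strings are preserved verbatim apart from a prefix sanity check. MAF values
#' are stored on the 0-100 percent scale.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"vcf_subset"`.
#' @param maf_scale scale of the MAF column in a TSV: `"percent"` (default) or
#'   `"fraction"` (converted to percent on ingest). VCF `AF` is always a
#'   fraction and is converted.
#' @param predictors candidate in-silico predictor column names picked up from
#'   a TSV when present (raw tokens kept in `pred_<name>` columns).
#' @param vcf_gene_key,vcf_af_key INFO keys holding the gene symbol and allele
#'   frequency in the VCF dialect.
#' @return data.frame with columns `patient_id`, `gene`, `zygosity`
#'   (`het`/`hom`/`cmpd_het`), `hgvs_c`, `hgvs_p`, `maf_percent`,
#'   `conservation` (NA when absent) and any `pred_*` columns.
#' @examples
#' tsv <- system.file("extdata", "table2_vus.tsv", package = "crossprio")
#' v <- readVariantTable(tsv)
#' nrow(v)                  # 27 variant observations
#' length(unique(v$gene))   # 15 distinct genes
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf_subset"),
                             maf_scale = c("percent", "fraction"),
                             predictors = c("SIFT", "PolyPhen"),
                             vcf_gene_key = "GENE", vcf_af_key = "AF") {
  dialect <- match.arg(dialect)
  maf_scale <- match.arg(maf_scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vcf_subset")
    return(readVariantVcf(path, gene_key = vcf_gene_key, af_key = vcf_af_key))

  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  hdr <- colnames(tab)
  ip <- matchColumn(hdr, c("patient", "patient_id", "case", "case_id",
                           "dsd case id", "dsd_case_id"), "patient")
  ig <- matchColumn(hdr, c("gene", "gene_symbol", "symbol"), "gene")
  iz <- matchColumn(hdr, c("zygosity", "zyg"), "zygosity")
  ic <- matchColumn(hdr, c("hgvsc", "hgvs_c", "cdna"), "HGVSc")
  iq <- matchColumn(hdr, c("hgvsp", "hgvs_p", "protein"), "HGVSp")
  im <- matchColumn(hdr, c("maf", "maf_percent", "maf gnomad (%)",
                           "maf_gnomad_percent", "maf_gnomad"), "MAF")
  if (nrow(tab) == 0L) return(emptyVariantFrame())

  maf <- parseNumericColumn(tab[[im]], "MAF")
  if (maf_scale == "fraction") maf <- maf * 100
  if (any(!is.na(maf) & (maf < 0 | maf > 100)))
    stop("MAF out of the 0-100 percent range")

  out <- data.frame(
    patient_id = trimws(tab[[ip]]),
    gene = canonicalizeSymbols(tab[[ig]], "human"),
    zygosity = normalizeZygosity(tab[[iz]]),
    hgvs_c = trimws(tab[[ic]]),
    hgvs_p = trimws(tab[[iq]]),
    maf_percent = maf,
    stringsAsFactors = FALSE)
  if (any(!nzchar(out$patient_id)) || any(!nzchar(out$gene)))
    stop("patient_id and gene must be non-empty in every row")
  badc <- nzchar(out$hgvs_c) & !grepl("^[cgmn]\\.", out$hgvs_c)
  badp <- nzchar(out$hgvs_p) & !grepl("^p\\.", out$hgvs_p)
  if (any(badc | badp))
    warning(sprintf("%d HGVS string(s) lack a standard prefix (kept verbatim)",
                    sum(badc | badp)))

  icons <- matchColumn(hdr, c("conservation", "cons_score"), "conservation",
                       required = FALSE)
  out$conservation <- if (!is.na(icons))
    parseNumericColumn(tab[[icons]], "conservation") else NA_real_
  for (p in predictors) {
    j <- matchColumn(hdr, c(p, paste0("pred_", p)), p, required = FALSE)
    if (!is.na(j)) out[[paste0("pred_", p)]] <- trimws(tab[[j]])
  }
  out
}

emptyVariantFrame <- function() {
  data.frame(patient_id = character(), gene = character(), zygosity = character(),
             hgvs_c = character(), hgvs_p = character(), maf_percent = numeric(),
             conservation = numeric(), stringsAsFactors = FALSE)
}

# VCF-subset dialect: gene symbol and AF pulled from INFO; multi-allelic
# records are expanded to one row per ALT before interpretation; genomic
# coordinates are carried as opaque metadata (the pipeline keys on symbols).
readVariantVcf <- function(path, gene_key = "GENE", af_key = "AF") {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  info <- VariantAnnotation::info(vcf)
  if (!gene_key %in% colnames(info))
    stop(sprintf("missing mandatory INFO key '%s' (gene symbol)", gene_key))
  if (!af_key %in% colnames(info))
    stop(sprintf("missing mandatory INFO key '%s' (allele frequency)", af_key))
  gene <- canonicalizeSymbols(unlist(info[[gene_key]]), "human")
  af <- as.numeric(unlist(info[[af_key]]))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF dialect requires per-sample GT genotypes")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  pos <- BiocGenerics::start(rr)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))

  rows <- list()
  for (s in colnames(gt)) {
    g <- gsub("\\|", "/", gt[, s])
    carrier <- g %in% c("0/1", "1/0", "1/1")
    if (!any(carrier)) next
    zyg <- ifelse(g[carrier] == "1/1", "hom", "het")
    rows[[s]] <- data.frame(
      patient_id = s,
      gene = gene[carrier],
      zygosity = zyg,
      hgvs_c = sprintf("g.%d%s>%s", pos[carrier], ref[carrier], alt[carrier]),
      hgvs_p = "",
      maf_percent = af[carrier] * 100,
      conservation = NA_real_,
      chrom = chrom[carrier],
      pos = pos[carrier],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(emptyVariantFrame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a variant table in the canonical TSV layout
#'
#' Inverse of [readVariantTable()] for the TSV dialect; writing then re-reading
#' then re-writing is byte-stable.
#'
#' @param variants data.frame as returned by [readVariantTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  cols <- c("patient_id", "gene", "zygosity", "hgvs_c", "hgvs_p", "maf_percent",
            "conservation", grep("^pred_", colnames(variants), value = TRUE))
  cols <- intersect(cols, colnames(variants))
  utils::write.table(variants[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the patient (cohort) table
#'
#' @param path TSV with header columns `patient_id`, `category` (1-4),
#'   and optionally `karyotype`, `dsd_category`, `clinical_notes`.
#' @return data.frame with one row per patient.
#' @examples
#' tsv <- system.file("extdata", "table1_patients.tsv", package = "crossprio")
#' nrow(readPatientTable(tsv))  # 32
#' @export
readPatientTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  hdr <- colnames(tab)
  ip <- matchColumn(hdr, c("patient", "patient_id", "patient id"), "patient_id")
  ic <- matchColumn(hdr, "category", "category")
  cat <- parseNumericColumn(tab[[ic]], "category")
  if (any(!cat %in% 1:4))
    stop("phenotype category must be one of 1, 2, 3, 4")
  out <- data.frame(patient_id = trimws(tab[[ip]]),
                    category = as.integer(cat), stringsAsFactors = FALSE)
  for (opt in c("karyotype", "dsd_category", "clinical_notes")) {
    j <- matchColumn(hdr, opt, opt, required = FALSE)
    out[[opt]] <- if (!is.na(j)) trimws(tab[[j]]) else NA_character_
  }
  if (anyDuplicated(out$patient_id)) stop("duplicate patient_id rows")
  out
}

#' Read a gene expression matrix from TSV
#'
#' First column holds gene symbols; remaining columns are samples. Group labels
#' come either from the `groups` argument (named by sample, or positional) or
#' from a `sample|group` header suffix.
#'
#' @param path TSV file path.
#' @param unit `"FPKM"` or `"counts"`.
#' @param groups optional character vector of group labels (named by sample ID
#'   or positional); when `NULL`, labels are parsed from `|` header suffixes.
#' @param species species tag for the row symbols (`"mouse"` or `"human"`).
#' @param dup_action what to do with duplicate gene rows after
#'   canonicalization: `"error"` (default), `"first"`, or `"sum"`.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, unit = c("FPKM", "counts"), groups = NULL,
                                 species = c("mouse", "human"),
                                 dup_action = c("error", "first", "sum")) {
  unit <- match.arg(unit)
  species <- match.arg(species)
  dup_action <- match.arg(dup_action)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(unique(nf)) > 1L)
    stop("format error: ragged rows (unequal field counts) in ", path)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("format error: need a gene column plus >=1 sample")
  genes <- canonicalizeSymbols(tab[[1L]], species)
  vals <- vapply(seq(2L, ncol(tab)),
                 function(j) parseNumericColumn(tab[[j]], colnames(tab)[j]),
                 numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab))
  colnames(vals) <- colnames(tab)[-1L]

  if (is.null(groups)) {
    if (!all(grepl("\\|", colnames(vals))))
      stop("no 'groups' given and sample headers lack a '|group' suffix")
    groups <- sub("^.*\\|", "", colnames(vals))
    colnames(vals) <- sub("\\|[^|]*$", "", colnames(vals))
  } else if (!is.null(names(groups))) {
    if (!all(colnames(vals) %in% names(groups)))
      stop("named 'groups' must cover every sample column")
    groups <- unname(groups[colnames(vals)])
  }

  if (anyDuplicated(genes)) {
    if (dup_action == "error")
      stop(sprintf("duplicate gene row(s) after canonicalization: %s",
                   paste(utils::head(unique(genes[duplicated(genes)]), 5L),
                         collapse = ", ")))
    if (dup_action == "first") {
      keep <- !duplicated(genes)
      vals <- vals[keep, , drop = FALSE]; genes <- genes[keep]
    } else {
      vals <- rowsum(vals, group = genes, reorder = FALSE)
      genes <- rownames(vals)
    }
  }
  rownames(vals) <- genes
  ExpressionMatrix(vals, groups = groups, unit = unit, species = species)
}

#' Write an ExpressionMatrix in the canonical TSV layout
#'
#' Sample headers carry a `|group` suffix so that [readExpressionMatrix()]
#' recovers group labels; write-read-write round-trips are byte-identical.
#'
#' @param mat an [ExpressionMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path) {
  v <- exprValues(mat)
  df <- data.frame(gene = rownames(v),
                   as.data.frame(v, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-1L] <- paste0(colnames(v), "|", unname(sampleGroups(mat)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; `#` lines ignored; duplicates (after canonicalization)
#' deduplicated with a warning. An empty file yields an empty set with a
#' warning, not an error.
#'
#' @param path file path.
#' @param species `"human"` or `"mouse"`.
#' @param name set name (defaults to the file name).
#' @return A [GeneSet-class].
#' @export
readGeneSet <- function(path, species = c("human", "mouse"), name = NULL) {
  species <- match.arg(species)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) warning("empty gene list: ", path)
  GeneSet(lines, species = species,
          name = if (is.null(name)) basename(path) else name)
}

#' Read a two-column human-mouse ortholog map
#'
#' Tab-separated `human<TAB>mouse` symbol pairs, one per line; `#` lines
#' ignored; duplicate pairs deduplicated with a warning. One-to-many relations
#' in either direction are retained.
#'
#' @param path file path.
#' @param provenance provenance note (defaults to the file name).
#' @return An [OrthologMap-class].
#' @export
readOrthologMap <- function(path, provenance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    warning("empty ortholog map: ", path)
    return(new("OrthologMap",
               pairs = data.frame(human = character(), mouse = character(),
                                  stringsAsFactors = FALSE),
               provenance = if (is.null(provenance)) basename(path) else provenance))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("each ortholog-map line needs two tab-separated symbols")
  human <- vapply(parts, `[[`, character(1), 1L)
  mouse <- vapply(parts, `[[`, character(1), 2L)
  n_in <- length(human)
  map <- OrthologMap(human, mouse,
                     provenance = if (is.null(provenance)) basename(path) else provenance)
  if (nrow(map@pairs) < n_in)
    warning(sprintf("%d duplicate ortholog pair(s) removed", n_in - nrow(map@pairs)))
  map
}

#' Ortholog lookups
#'
#' Explicit lookups through an [OrthologMap-class]. Every queried symbol is
#' present in the result; unmapped symbols map to `character(0)` rather than
#' being dropped.
#'
#' @param map an [OrthologMap-class].
#' @param symbols symbols to look up (canonicalized internally).
#' @return named list, query symbol -> character vector of counterparts.
#' @export
mouseOrthologs <- function(map, symbols) {
  symbols <- canonicalizeSymbols(symbols, "human")
  hits <- split(map@pairs$mouse, factor(map@pairs$human, levels = symbols))
  lapply(hits, as.character)
}

#' @rdname mouseOrthologs
#' @export
humanOrthologs <- function(map, symbols) {
  symbols <- canonicalizeSymbols(symbols, "mouse")
  hits <- split(map@pairs$human, factor(map@pairs$mouse, levels = symbols))
  lapply(hits, as.character)
}

#' Read a term-to-gene annotation table
#'
#' Two-column TSV (`term`, `gene`), one annotation per line, `#` lines ignored.
#' The universe defaults to all annotated genes.
#'
#' @param path file path.
#' @return A [TermAnnotation-class].
#' @export
readTermAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("term annotation needs two columns: term, gene")
  TermAnnotation(data.frame(term = tab[[1L]], gene = tab[[2L]],
                            stringsAsFactors = FALSE))
}
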