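#' Canonicalize gene symbols for a species
#'
#' Human symbols are uppercased; mouse symbols are title-cased (first letter
#' upper, remainder lower), the standard case conventions of the two
#' nomenclatures. Cross-species comparisons in this package always go through
#' an [OrthologMap-class], never through case-folding.
#'
#' @param symbols character vector.
#' @param species `"human"` or `"mouse"`.
#' @return canonical character vector of the same length.
#' @examples
#' canonicalizeSymbols("sox9", "human")  # "SOX9"
#' canonicalizeSymbols("SOX9", "mouse")  # "Sox9"
#' @export
canonicalizeSymbols <- function(symbols, species = c("human", "mouse")) {
  species <- match.arg(species)
  symbols <- trimws(as.character(symbols))
  if (species == "human") {
    toupper(symbols)
  } else {
    paste0(toupper(substring(symbols, 1L, 1L)),
           tolower(substring(symbols, 2L)))
  }
}

# Harmonize raw zygosity tokens to the het/hom/cmpd_het enum; error on unknown.
normalizeZygosity <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  map <- c(het = "het", heterozygous = "het",
           hom = "hom", homozygous = "hom", hemizygous = "hom",
           cmpdhet = "cmpd_het", compoundhet = "cmpd_het",
           compoundheterozygous = "cmpd_het")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("unknown zygosity token '%s' at row %d", x[bad], bad))
  }
  out
}

# Locate a column by any of several header aliases (case-insensitive);
# errors naming the column when mandatory.
matchColumn <- function(header, aliases, what, required = TRUE) {
  hit <- which(tolower(header) %in% tolower(aliases))
  if (!length(hit)) {
    if (required)
      stop(sprintf("missing mandatory column '%s' (accepted headers: %s)",
                   what, paste(aliases, collapse = ", ")))
    return(NA_integer_)
  }
  hit[1L]
}

# Strict numeric parse reporting the offending row on failure.
parseNumericColumn <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop(sprintf("non-numeric %s value '%s' at row %d", what, x[bad[1L]], bad[1L]))
  out
}

# geometric-mean recentering used for TMM factors
recenterFactors <- function(f) f / exp(mean(log(f)))
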