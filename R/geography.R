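#' Geographic lineage class table
#'
#' Loads the haplogroup-prefix to geographic class map used to quantify
#' East/West Eurasian admixture: West Eurasian (R0 incl. HV, N1, JT, UK,
#' W, X), East Eurasian (M incl. C, D, G, Z, M9-M13; A; B; F; N9a) and
#' South Asian (U2a-c, U9, R1-R2, R5-R6, N1d).  Classification is by
#' longest-prefix match, so sub-haplogroup entries (U2a) override their
#' parent class (U).
#'
#' @param path Optional TSV path (columns \code{prefix}, \code{class})
#'   overriding the packaged table.
#' @return Data frame with columns \code{prefix}, \code{class}.
#' @export
geo_classes <- function(path = NULL) {
  df <- read.delim(path %||% extdata("geo_classes.tsv"),
                   colClasses = "character", na.strings = NULL)
  stopifnot(all(c("prefix", "class") %in% names(df)),
            !anyDuplicated(df$prefix))
  df
}

#' Classify haplogroups by geographic origin
#'
#' @param haplogroup Character vector of haplogroup labels.
#' @param table Class table, see \code{\link{geo_classes}}.
#' @return Character vector of classes (\code{"WestEurasian"},
#'   \code{"EastEurasian"}, \code{"SouthAsian"} or \code{"Unclassified"}).
#' @examples
#' geo_class(c("D", "U5a1", "U2a"))
#' @export
geo_class <- function(haplogroup, table = geo_classes()) {
  vapply(as.character(haplogroup), function(hg) {
    if (is.na(hg) || !nzchar(hg)) stop("haplogroup label must be non-empty")
    ok <- vapply(table$prefix, function(p) startsWith(hg, p), TRUE)
    if (!any(ok)) return("Unclassified")
    cand <- table[ok, , drop = FALSE]
    best <- cand[nchar(cand$prefix) == max(nchar(cand$prefix)), , drop = FALSE]
    if (nrow(best) > 1L)
      stop("ambiguous prefix match for haplogroup ", hg)
    best$class
  }, "", USE.NAMES = FALSE)
}

#' Per-population geographic lineage frequencies
#'
#' @param haplogroups Character vector of final haplogroup calls (one per
#'   individual), or the data frame returned by
#'   \code{\link{call_haplogroups}}.
#' @param table Class table.
#' @return Data frame with one row per class present: \code{class},
#'   \code{n}, \code{fraction}, \code{pct} (percentage rounded to 1
#'   decimal).  Fractions sum to 1 over all rows.
#' @examples
#' lineage_frequencies(call_haplogroups(altai_pazyryk()))
#' @export
lineage_frequencies <- function(haplogroups, table = geo_classes()) {
  if (is.data.frame(haplogroups)) haplogroups <- haplogroups$haplogroup
  if (!length(haplogroups)) stop("empty population")
  cls <- geo_class(haplogroups, table)
  tab <- table(factor(cls, levels = c("WestEurasian", "EastEurasian",
                                      "SouthAsian", "Unclassified")))
  tab <- tab[tab > 0]
  data.frame(class = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / length(cls),
             pct = round(100 * as.numeric(tab) / length(cls), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
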