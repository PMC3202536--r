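## Seed-family aggregation: combine member miRNA profiles into one family
## profile before correlation. Abundance-style data are averaged across
## members; signed log2-ratio data are summed, mirroring how the two kinds
## of miRNA quantification are usually aggregated.

#' Aggregate member miRNAs into a family profile
#'
#' Builds one expression profile for a miRNA family: per sample, the mean
#' (\code{"average"}) or sum (\code{"sum"}) of the member values, with
#' missing members excluded from the mean and treated as absent in the
#' sum (all-missing samples stay \code{NA}). With \code{"auto"}, the mode
#' follows the matrix value kind: abundance data are averaged, log2-ratio
#' data are summed. A sample counts as detectable for the family if at
#' least one member is detectable in it.
#'
#' @param x an \linkS4class{ExpressionMatrix} of miRNAs.
#' @param members character vector of member miRNA names.
#' @param name family name.
#' @param aggregation \code{"auto"}, \code{"average"} or \code{"sum"}.
#' @param limit detection limit used for the family mask.
#' @return A \linkS4class{MiRNAProfile} named \code{name}.
#' @export
buildFamilyProfile <- function(x, members, name,
                               aggregation = c("auto", "average", "sum"),
                               limit = -Inf) {
  aggregation <- match.arg(aggregation)
  v <- exprValues(x)
  missing <- setdiff(members, rownames(v))
  if (length(missing))
    stop("family member(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  if (aggregation == "auto")
    aggregation <- if (valueKind(x) == "abundance") "average" else "sum"
  sub <- v[members, , drop = FALSE]
  vals <- if (aggregation == "average") colMeans(sub, na.rm = TRUE)
          else colSums(sub, na.rm = TRUE)
  allNA <- colSums(!is.na(sub)) == 0L
  vals[allNA] <- NA_real_
  det <- colSums(!is.na(sub) & sub >= limit) >= 1L
  MiRNAProfile(name, vals, det)
}

#' Family definitions from a seed table
#'
#' Groups miRNAs by seed family and keeps families with at least
#' \code{minMembers} members that passed the detectability gate — families
#' with a single usable member add nothing beyond the member itself.
#' Custom families (e.g. a combined miR-200 family spanning two seed
#' groups) are expressed as extra rows of the seed table.
#'
#' @param seedTable data.frame with columns \code{mirna}, \code{family}.
#' @param detectable character vector of miRNA names that passed
#'   [detectabilityFilter()]; \code{NULL} keeps all.
#' @param minMembers minimum qualifying members (default 2).
#' @return Named list of character vectors (members per family).
#' @export
familiesFromSeedTable <- function(seedTable, detectable = NULL,
                                  minMembers = 2L) {
  stopifnot(all(c("mirna", "family") %in% names(seedTable)))
  tab <- seedTable
  if (!is.null(detectable))
    tab <- tab[tab$mirna %in% detectable, , drop = FALSE]
  fams <- split(tab$mirna, tab$family)
  fams <- lapply(fams, unique)
  fams[vapply(fams, length, 0L) >= minMembers]
}
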