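#' Select a core discriminating marker panel
#'
#' Builds a \linkS4class{Panel} from specificity results under one of
#' two policies. \code{"one-per-group"} (the published core-set rule)
#' picks, for each group, its specific locus with the highest one-vs-rest
#' F_ST (all-\code{NA} F_ST, as for a published table, or ties resolve to
#' the lexicographically earliest locus id), giving a panel of exactly
#' one locus per group. \code{"minimal"} searches exhaustively for the
#' smallest locus subset whose group signature rows are pairwise
#' distinct; with one indicator locus per group, the minimal panel drops
#' one indicator because the residual group's all-"other" signature row
#' stays unique. The search deduplicates loci with identical group
#' signature patterns first (duplicate patterns can never help), so it
#' is exhaustive over distinct patterns and exact.
#'
#' @param results A \linkS4class{SpecificityResults}.
#' @param policy \code{"one-per-group"} or \code{"minimal"}.
#' @param groups Groups the panel must discriminate (default: all in
#'   \code{results}).
#' @param columns Optional named list/matrix of alignment columns per
#'   locus (attached when the loci come from an alignment).
#' @return A \linkS4class{Panel}; its signature rows are asserted
#'   pairwise distinct on construction.
#' @export
selectCorePanel <- function(results, policy = c("one-per-group", "minimal"),
                            groups = NULL, columns = NULL) {
  policy <- match.arg(policy)
  stopifnot(is(results, "SpecificityResults"))
  groups <- groups %||% results@groups
  specific <- which(!is.na(results@assigned) &
                      results@assigned %in% groups)
  if (!length(specific)) stopf("no specific loci to select from")
  ids <- results@lociIds[specific]
  sig <- results@alleleMatrix[groups, specific, drop = FALSE]
  colnames(sig) <- ids
  if (anyNA(sig))
    stopf("signature alleles undefined for some (group, locus) pairs")

  if (policy == "one-per-group") {
    uncovered <- setdiff(groups, results@assigned[specific])
    if (length(uncovered))
      stopf("no specific locus for group(s): %s",
            paste(uncovered, collapse = ", "))
    chosen <- vapply(groups, function(g) {
      cand <- specific[results@assigned[specific] == g]
      cand <- cand[order(-replaceNA(results@fst[cbind(cand, match(g, results@groups))]),
                         results@lociIds[cand])]
      results@lociIds[cand[1L]]
    }, character(1L))
  } else {
    chosen <- minimalSubset(sig)
    if (is.null(chosen))
      stopf("no locus subset discriminates group(s): %s",
            paste(groups, collapse = ", "))
  }
  buildPanel(results, chosen, groups, policy, columns)
}

replaceNA <- function(x) ifelse(is.na(x), -Inf, x)

## exact smallest subset with pairwise-distinct signature rows; exhaustive
## over distinct signature patterns (adding a locus whose pattern already
## occurs in a set never separates any additional group pair)
minimalSubset <- function(sig) {
  pat <- apply(sig, 2L, paste, collapse = "\r")
  firstOfPattern <- colnames(sig)[!duplicated(pat)]
  firstOfPattern <- sort(firstOfPattern)
  usig <- sig[, firstOfPattern, drop = FALSE]
  for (k in seq_len(ncol(usig))) {
    combos <- utils::combn(ncol(usig), k)
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      rows <- apply(usig[, sel, drop = FALSE], 1L, paste, collapse = "\r")
      if (!anyDuplicated(rows)) return(colnames(usig)[sel])
    }
  }
  NULL
}

buildPanel <- function(results, chosen, groups, policy, columns) {
  idx <- match(chosen, results@lociIds)
  sig <- results@alleleMatrix[groups, idx, drop = FALSE]
  colnames(sig) <- chosen
  colm <- matrix(NA_integer_, length(chosen), 2L,
                 dimnames = list(chosen, c("start", "end")))
  kinds <- rep(NA_character_, length(chosen))
  if (!is.null(columns)) {
    for (i in seq_along(chosen)) {
      ci <- columns[[chosen[i]]]
      if (!is.null(ci)) {
        colm[i, ] <- as.integer(ci[1:2])
        kinds[i] <- attr(ci, "kind") %||% NA_character_
      }
    }
  }
  new("Panel", lociIds = chosen, signature = sig, columns = colm,
      kinds = kinds, policy = policy)
}

#' Panel restricted to a candidate group set
#'
#' When external knowledge restricts the candidate cytoplasm types (for
#' example, material known sterile narrows the candidates to the
#' sterile-cytoplasm groups), a smaller panel suffices: only the
#' candidate groups' signature rows need be pairwise distinct.
#'
#' @param results A \linkS4class{SpecificityResults}.
#' @param candidateGroups At least two group labels.
#' @param policy As in \code{\link{selectCorePanel}} (default
#'   \code{"minimal"}).
#' @param columns As in \code{\link{selectCorePanel}}.
#' @return A \linkS4class{Panel} over the candidate groups.
#' @export
constrainedPanel <- function(results, candidateGroups, policy = "minimal",
                             columns = NULL) {
  if (length(candidateGroups) < 2L)
    stopf("need at least 2 candidate groups (a single candidate needs no markers)")
  if (!all(candidateGroups %in% results@groups))
    stopf("candidate group(s) not in results: %s",
          paste(setdiff(candidateGroups, results@groups), collapse = ", "))
  selectCorePanel(results, policy, groups = candidateGroups,
                  columns = columns)
}

#' Columns lookup for panel construction from called loci
#'
#' @param loci List of \linkS4class{VariantLocus}.
#' @return Named list mapping locus id to \code{c(start, end)} with a
#'   \code{"kind"} attribute, for the \code{columns} argument of
#'   \code{\link{selectCorePanel}}.
#' @export
lociColumns <- function(loci) {
  out <- lapply(loci, function(lc) {
    v <- c(lc@start, lc@end)
    attr(v, "kind") <- lc@kind
    v
  })
  names(out) <- vapply(loci, slot, character(1L), "id")
  out
}

#' Allele frequencies and minor-allele-frequency filter
#'
#' \code{alleleFrequencies} tabulates allele counts per locus over
#' non-missing samples (overall and per group) and the haploid
#' minor-allele frequency (for multi-allelic loci: the frequency of the
#' most frequent non-major allele, always in [0, 0.5]).
#' \code{mafFilter} partitions loci into kept and eliminated at a strict
#' less-than threshold: a locus is eliminated iff \code{maf < threshold}
#' (so a locus exactly at the boundary is kept, matching the published
#' "less than 1\%" elimination rule; a singleton among 176 haploid
#' samples, frequency ~0.0057, falls below 1\%).
#'
#' @param loci List of \linkS4class{VariantLocus}.
#' @param groups Optional group label per sample for per-group counts.
#' @return \code{alleleFrequencies}: data.frame with \code{locus_id},
#'   \code{n} (non-missing), \code{maf}, \code{major}, \code{minor}.
#' @export
alleleFrequencies <- function(loci, groups = NULL) {
  rows <- lapply(loci, function(lc) {
    calls <- allelesAt(lc)
    obs <- calls[!is.na(calls)]
    tab <- sort(table(obs), decreasing = TRUE)
    maf <- if (length(tab) > 1L) as.integer(tab[2L]) / length(obs) else 0
    data.frame(locus_id = lc@id, n = length(obs),
               maf = maf, major = names(tab)[1L],
               minor = if (length(tab) > 1L) names(tab)[2L] else
                 NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname alleleFrequencies
#' @param threshold MAF threshold in (0, 0.5); default 0.01.
#' @return \code{mafFilter}: list with \code{kept} and \code{eliminated}
#'   (lists of loci) and \code{table} (the frequency table with an
#'   \code{eliminated} flag). The partition is exhaustive.
#' @export
mafFilter <- function(loci, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 0.5)
    stopf("threshold must lie in (0, 0.5)")
  tab <- alleleFrequencies(loci)
  tab$eliminated <- tab$maf < threshold
  list(kept = loci[!tab$eliminated], eliminated = loci[tab$eliminated],
       table = tab)
}
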