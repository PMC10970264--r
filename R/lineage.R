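#' Genotype samples at a marker panel
#'
#' In-silico stand-in for KASP genotyping: reads each panel locus
#' directly off the alignment. A SNP call is the base at the locus
#' column; an InDel call is the gap-stripped subsequence over the event
#' columns (the empty string is the deletion allele). \code{N} anywhere
#' in the locus, or a gap at a SNP locus, yields a missing call.
#'
#' @param aln A \linkS4class{PlastomeAlignment}.
#' @param panel A \linkS4class{Panel} with alignment columns attached.
#' @return Character matrix samples x loci of allele calls
#'   (\code{NA} = missing).
#' @export
genotypeAtPanel <- function(aln, panel) {
  if (anyNA(panel@columns))
    stopf("panel has no alignment columns (built from a published table?)")
  m <- alignmentMatrix(aln)
  if (max(panel@columns) > ncol(m))
    stopf("panel locus column %d outside the %d-column alignment",
          max(panel@columns), ncol(m))
  out <- matrix(NA_character_, nrow(m), length(panel@lociIds),
                dimnames = list(rownames(m), panel@lociIds))
  for (i in seq_along(panel@lociIds)) {
    cols <- panel@columns[i, 1L]:panel@columns[i, 2L]
    sub <- m[, cols, drop = FALSE]
    if (length(cols) == 1L) {
      cc <- sub[, 1L]
      out[, i] <- ifelse(cc %in% c("N", "-"), NA_character_, cc)
    } else {
      calls <- apply(sub, 1L, function(x) paste(x[x != "-"], collapse = ""))
      out[, i] <- ifelse(grepl("N", calls, fixed = TRUE), NA_character_,
                         calls)
    }
  }
  out
}

#' Trio maternal assignment
#'
#' Compares a hybrid's panel genotype vector with both candidate
#' parents. The verdict is \code{maternal=mother} only when the hybrid
#' matches the mother at every locus where both are non-missing and
#' differs from the father at at least one such locus (symmetrically for
#' the father). Parents indistinguishable over the informative loci give
#' \code{ambiguous} - the information-theoretic limit, never a guess;
#' a hybrid matching neither parent fully is \code{inconsistent}.
#' Missing calls are excluded from all concordance counts. An optional
#' mismatch budget (default 0, strict identity as observed for
#' plastome inheritance) tolerates that many hybrid-mother conflicts;
#' any nonzero use is reported with a message.
#'
#' @param hybrid,mother,father Named character vectors of panel calls
#'   (rows of \code{\link{genotypeAtPanel}} output).
#' @param hybridId,motherId,fatherId Identifiers for the report.
#' @param mismatchBudget Allowed mismatches toward the assigned parent.
#' @return One-row data.frame: ids, per-parent match counts, informative
#'   locus count, verdict.
#' @export
assignMaternal <- function(hybrid, mother, father, hybridId = "hybrid",
                           motherId = "mother", fatherId = "father",
                           mismatchBudget = 0L) {
  if (length(hybrid) != length(mother) || length(hybrid) != length(father))
    stopf("genotype vectors come from different panels (lengths %d/%d/%d)",
          length(hybrid), length(mother), length(father))
  if (mismatchBudget > 0L)
    message(sprintf("assignMaternal: nonzero mismatch budget (%d) in use",
                    mismatchBudget))
  okM <- !is.na(hybrid) & !is.na(mother)
  okF <- !is.na(hybrid) & !is.na(father)
  okP <- !is.na(mother) & !is.na(father)
  matchM <- sum(hybrid[okM] == mother[okM])
  matchF <- sum(hybrid[okF] == father[okF])
  parentsDiffer <- any(mother[okP] != father[okP])
  fullM <- sum(okM) > 0L && (sum(okM) - matchM) <= mismatchBudget
  fullF <- sum(okF) > 0L && (sum(okF) - matchF) <= mismatchBudget
  diffFromF <- any(hybrid[okF] != father[okF])
  diffFromM <- any(hybrid[okM] != mother[okM])
  verdict <- if (!parentsDiffer || (sum(okM) + sum(okF)) == 0L) "ambiguous"
  else if (fullM && diffFromF) "maternal=mother"
  else if (fullF && diffFromM) "maternal=father"
  else if (fullM || fullF) "ambiguous"
  else "inconsistent"
  data.frame(hybrid_id = hybridId, mother_id = motherId,
             father_id = fatherId, n_informative = sum(okM & okF),
             match_mother = matchM, match_father = matchF,
             parents_differ = parentsDiffer, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Trace maternal lineage for every hybrid in a panel
#'
#' Runs \code{\link{assignMaternal}} for each sheet row with role
#' \code{hybrid} (both parents must be in the alignment), genotyping all
#' samples at the panel first.
#'
#' @param aln A \linkS4class{PlastomeAlignment}.
#' @param panel A \linkS4class{Panel} with alignment columns.
#' @param mismatchBudget See \code{\link{assignMaternal}}.
#' @return Data.frame with one row per hybrid.
#' @export
traceTrios <- function(aln, panel, mismatchBudget = 0L) {
  sheet <- sampleSheet(aln)
  gt <- genotypeAtPanel(aln, panel)
  hyb <- sheet[sheet$role == "hybrid", , drop = FALSE]
  if (!nrow(hyb)) stopf("no hybrid samples in the sheet")
  rows <- lapply(seq_len(nrow(hyb)), function(i) {
    h <- hyb[i, ]
    assignMaternal(gt[h$sample_id, ], gt[h$mother_id, ], gt[h$father_id, ],
                   h$sample_id, h$mother_id, h$father_id, mismatchBudget)
  })
  do.call(rbind, rows)
}

## group -> cytoplasm candidate labels (group H holds both the S-type
## CMS lineage and fertile cultivars, so its call stays a label set)
CMS_LABELS <- list(B = "fertile-type", C = "C-CMS", D = "fertile-type",
                   H = c("S-CMS", "Huanggai"), T = "T-CMS")

#' Classify the cytoplasm type of a sample from its panel genotype
#'
#' Matches the sample's calls against the panel's group signature rows.
#' The group is assigned only when the calls are compatible with exactly
#' one signature row (compatible = equal at every non-missing call);
#' several compatible rows (possible only through missing calls for a
#' valid panel) or none give an unclassified result. When fertility is
#' known it restricts the candidate groups first (sterile cytoplasm ->
#' C/H/T, fertile -> B/D/H by default), which is what allows the smaller
#' constrained panels. Marker data alone never yields a fertility
#' verdict - group H contains both sterile and fertile lineages - so the
#' result carries candidate cytoplasm labels.
#'
#' @param calls Named character vector of panel calls (one row of
#'   \code{\link{genotypeAtPanel}}).
#' @param panel A \linkS4class{Panel}.
#' @param fertilityKnown \code{NULL}, \code{"sterile"} or
#'   \code{"fertile"}.
#' @param sterileGroups,fertileGroups Candidate sets used when fertility
#'   is known.
#' @param sampleId Identifier for the report.
#' @return One-row data.frame: \code{sample_id}, \code{group}
#'   (\code{NA} if unclassified), \code{labels} (semicolon-joined
#'   cytoplasm candidates), \code{n_called}.
#' @export
classifyCytoplasm <- function(calls, panel, fertilityKnown = NULL,
                              sterileGroups = c("C", "H", "T"),
                              fertileGroups = c("B", "D", "H"),
                              sampleId = "sample") {
  sig <- panel@signature
  cand <- rownames(sig)
  if (!is.null(fertilityKnown)) {
    cand <- switch(fertilityKnown,
                   sterile = intersect(cand, sterileGroups),
                   fertile = intersect(cand, fertileGroups),
                   stopf("fertilityKnown must be NULL, 'sterile' or 'fertile'"))
  }
  ok <- !is.na(calls)
  compatible <- cand[vapply(cand, function(g)
    all(calls[ok] == sig[g, ok]), logical(1L))]
  group <- NA_character_
  if (sum(ok) > 0L && length(compatible) == 1L) group <- compatible
  if (length(compatible) > 1L && all(ok))
    stopf("panel signature rows are not distinct over candidates %s",
          paste(compatible, collapse = ", "))
  labels <- if (is.na(group)) NA_character_
  else paste(CMS_LABELS[[group]] %||% "unknown-cytoplasm", collapse = ";")
  data.frame(sample_id = sampleId, group = group, labels = labels,
             n_called = sum(ok), stringsAsFactors = FALSE)
}
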