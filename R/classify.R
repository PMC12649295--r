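## Rank-wise classification of query sequences with cutoff gating, and
## merging of classifications from multiple reference sets.

## Ranks walked during assignment, deepest first (strain is never assigned).
.ASSIGN_RANKS <- c("species", "genus", "family", "order", "class", "phylum")

#' Best reference hit for a query
#'
#' Aligns the query against every reference and returns the reference with
#' the highest length-adjusted similarity; ties go to the lexicographically
#' smallest reference id. A query with no alignable content gets score 0 and
#' empty taxonomy.
#'
#' @param query A single sequence (character, \code{DNAString}, or length-1
#'   named \code{DNAStringSet}).
#' @param refs A [BarcodeSet-class] (or named \code{DNAStringSet}) of
#'   reference barcodes.
#' @param params An [AlignmentParams-class].
#' @param refTax Optional [TaxonomyTable-class]; if given, the hit carries the
#'   reference's rank names.
#' @return A list: \code{query} (id or NA), \code{ref}, \code{score},
#'   \code{s}, \code{l}, \code{taxonomy} (named character over the ranks).
#' @export
bestHit <- function(query, refs, params = alignmentParams(), refTax = NULL) {
  stopifnot(length(refs) > 0)
  qid <- if (!is.null(names(query))) names(query)[1] else NA_character_
  q <- .as_seq_chars(query)[1]
  rseq <- .as_seq_chars(refs)
  r <- .align_batch(q, rseq, params)
  l <- r[, "length"]
  s <- ifelse(l == 0, 0, r[, "nmatch"] / pmax(l, 1))
  score <- adjustScore(s, l, params)
  ord <- order(-score, names(refs))
  i <- ord[1]
  taxonomy <- stats::setNames(rep("", length(.RANKS)), .RANKS)
  if (score[i] > 0 && !is.null(refTax)) {
    tb <- taxTable(refTax)
    row <- tb[match(names(refs)[i], tb$id), ]
    if (!is.na(row$id[1]))
      taxonomy[.RANKS] <- vapply(.RANKS, function(rk) {
        v <- row[[rk]]
        if (.annotated(v, rk)) v else ""
      }, "")
  }
  list(query = qid, ref = if (score[i] > 0) names(refs)[i] else NA_character_,
       score = unname(score[i]), s = unname(s[i]), l = unname(l[i]),
       taxonomy = taxonomy)
}

#' Assign a taxonomy to a hit using taxon-specific cutoffs
#'
#' Walks the ranks from species up to phylum. At each rank the applicable
#' cutoff is looked up with [bestCutoff()] starting from the hit's taxon at
#' the rank above (species cutoffs are keyed by the hit's genus, genus
#' cutoffs by its family, and so on), falling back along the ancestor chain
#' to the global entry. The assignment is accepted at the deepest rank whose
#' cutoff the hit's score reaches; names below the accepted rank are blanked.
#'
#' @param hit A hit from [bestHit()] (with taxonomy filled).
#' @param cutoffs A [CutoffTable-class] with at least a global species entry.
#' @param tax The reference [TaxonomyTable-class] (for ancestor chains).
#' @param source Label of the reference set, kept for provenance.
#' @return One-row data.frame: query, ref, score, accepted_rank, cutoff_used,
#'   cutoff_confidence, cutoff_taxon, source, and the six rank name columns.
#' @export
assignTaxonomy <- function(hit, cutoffs, tax, source = "ref") {
  names_out <- stats::setNames(rep("", length(.ASSIGN_RANKS)), .ASSIGN_RANKS)
  accepted <- NA_character_
  cutoff_used <- NA_real_
  cutoff_conf <- NA_real_
  cutoff_taxon <- NA_character_
  if (hit$score > 0) {
    e <- cutoffEntries(cutoffs)
    for (rk in .ASSIGN_RANKS) {
      if (!nzchar(hit$taxonomy[[rk]])) next
      if (!rk %in% e$level_rank) next
      ri <- match(rk, .RANKS)
      above <- hit$taxonomy[.RANKS[seq(ri + 1L, length(.RANKS))]]
      above <- above[nzchar(above)]
      scope_taxon <- if (length(above) > 0) above[[1]] else "All"
      entry <- tryCatch(bestCutoff(scope_taxon, rk, cutoffs, tax),
                        error = function(e) NULL)
      if (is.null(entry)) next
      if (hit$score >= entry$cutoff - .TOL) {
        accepted <- rk
        cutoff_used <- entry$cutoff
        cutoff_conf <- entry$confidence
        cutoff_taxon <- entry$taxon
        ai <- match(rk, .ASSIGN_RANKS)
        for (r2 in .ASSIGN_RANKS[seq(ai, length(.ASSIGN_RANKS))])
          names_out[[r2]] <- hit$taxonomy[[r2]]
        break
      }
    }
  }
  out <- data.frame(query = hit$query, ref = hit$ref, score = hit$score,
                    accepted_rank = accepted, cutoff_used = cutoff_used,
                    cutoff_confidence = cutoff_conf,
                    cutoff_taxon = cutoff_taxon, source = source,
                    stringsAsFactors = FALSE)
  for (rk in .ASSIGN_RANKS) out[[rk]] <- names_out[[rk]]
  out
}

#' Classify query sequences against a reference set
#'
#' Runs [bestHit()] and [assignTaxonomy()] for every query.
#'
#' @param queries A [BarcodeSet-class] (or named \code{DNAStringSet}).
#' @param refs Reference [BarcodeSet-class].
#' @param tax Reference [TaxonomyTable-class].
#' @param cutoffs A [CutoffTable-class].
#' @param params An [AlignmentParams-class].
#' @param source Reference-set label kept in the results.
#' @return data.frame, one row per query (see [assignTaxonomy()]).
#' @export
classifySequences <- function(queries, refs, tax, cutoffs,
                              params = alignmentParams(), source = "ref") {
  stopifnot(length(queries) > 0)
  rows <- lapply(seq_along(queries), function(i) {
    hit <- bestHit(queries[i], refs, params, refTax = tax)
    assignTaxonomy(hit, cutoffs, tax, source = source)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge classification results from multiple reference sets
#'
#' Per query, keeps the result with the deeper accepted rank; at equal rank
#' the higher score wins; still equal, the result whose source label sorts
#' first. Queries present in only one input are kept as-is. The merge is
#' idempotent and commutative up to these tie rules.
#'
#' @param a,b Classification data.frames from [classifySequences()].
#' @return Merged data.frame, one row per query.
#' @export
mergeResults <- function(a, b) {
  all_rows <- rbind(a, b)
  depth <- match(all_rows$accepted_rank, .ASSIGN_RANKS)  # 1 = deepest
  depth[is.na(depth)] <- length(.ASSIGN_RANKS) + 1L
  ord <- order(all_rows$query, depth, -all_rows$score, all_rows$source)
  all_rows <- all_rows[ord, , drop = FALSE]
  out <- all_rows[!duplicated(all_rows$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}
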