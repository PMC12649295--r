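## Intra-group similarity statistics and taxon-distribution tables.

#' Within-group similarity variation
#'
#' For every ground-truth group with at least two sequences, computes the
#' minimum and median pairwise similarity over all C(n,2) within-group pairs.
#' Pairs absent from the sparse matrix contribute the matrix floor (the only
#' information retained about them), not zero.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param truth A [RankPartition-class].
#' @return data.frame with columns rank, taxon, n, min_sim, median_sim; one
#'   row per group with n >= 2.
#' @export
groupVariation <- function(mat, truth) {
  groups <- partitionGroups(truth)
  if (length(groups) == 0) stop("empty ground truth")
  groups <- groups[lengths(groups) >= 2]
  rows <- lapply(names(groups), function(taxon) {
    ids <- groups[[taxon]]
    cmb <- utils::combn(ids, 2)
    vals <- simScore(mat, cmb[1, ], cmb[2, ], default = scoreFloor(mat))
    data.frame(rank = partitionRank(truth), taxon = taxon,
               n = length(ids), min_sim = min(vals),
               median_sim = stats::median(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(rank = character(0), taxon = character(0),
                      n = integer(0), min_sim = numeric(0),
                      median_sim = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank-level summary of group variation
#'
#' Summarizes [groupVariation()] rows at one rank by the median across groups
#' of the per-group minimum and median similarities (the usual rank-by-marker
#' summary of within-group variability).
#'
#' @param variations data.frame from [groupVariation()] (possibly several
#'   ranks row-bound together).
#' @param rank Rank to summarize; default: each rank present, one row each.
#' @return data.frame with columns rank, median_of_min, median_of_median,
#'   groups_evaluated.
#' @export
rankSummary <- function(variations, rank = NULL) {
  ranks <- if (is.null(rank)) unique(variations$rank) else rank
  rows <- lapply(ranks, function(r) {
    v <- variations[variations$rank == r, , drop = FALSE]
    if (nrow(v) == 0) stop("no group variation rows at rank ", r)
    data.frame(rank = r, median_of_min = stats::median(v$min_sim),
               median_of_median = stats::median(v$median_sim),
               groups_evaluated = nrow(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Taxon distribution tables
#'
#' Per rank and taxon, the number of sequences and the number of distinct
#' child groups at the next lower rank (strains for species, species for
#' genera, ...). The returned object also carries, as attribute
#' \code{top_share}, the share of sequences held by the top-5 taxa per rank,
#' a tabular analogue of the usual taxonomic-composition charts.
#'
#' @param tax A [TaxonomyTable-class].
#' @param ids Ids to tabulate (default: all).
#' @param topN How many dominant taxa enter the share (default 5).
#' @return data.frame with columns rank, taxon, seq_count, subgroup_count,
#'   with attribute \code{top_share} (data.frame: rank, share).
#' @export
taxonDistribution <- function(tax, ids = NULL, topN = 5L) {
  tb <- taxTable(tax)
  if (!is.null(ids)) {
    miss <- setdiff(ids, tb$id)
    if (length(miss) > 0)
      stop("ids not in taxonomy table: ",
           paste(utils::head(miss, 5), collapse = ", "))
    tb <- tb[tb$id %in% ids, , drop = FALSE]
  }
  rows <- list()
  shares <- list()
  for (ri in seq_along(.RANKS)) {
    r <- .RANKS[ri]
    keep <- .annotated(tb[[r]], r)
    sub <- tb[keep, , drop = FALSE]
    if (nrow(sub) == 0) next
    counts <- sort(table(sub[[r]]), decreasing = TRUE)
    child <- if (ri > 1) .RANKS[ri - 1] else NA
    subgroups <- vapply(names(counts), function(taxon) {
      if (is.na(child)) return(NA_integer_)
      ch <- sub[[child]][sub[[r]] == taxon]
      length(unique(ch[.annotated(ch, child)]))
    }, 1L)
    rows[[r]] <- data.frame(rank = r, taxon = names(counts),
                            seq_count = as.integer(counts),
                            subgroup_count = subgroups,
                            stringsAsFactors = FALSE)
    shares[[r]] <- data.frame(rank = r,
                              share = sum(utils::head(as.integer(counts), topN)) /
                                      nrow(sub),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ts <- do.call(rbind, shares)
  rownames(ts) <- NULL
  attr(out, "top_share") <- ts
  out
}
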