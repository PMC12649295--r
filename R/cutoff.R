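## Cutoff prediction: threshold sweeps maximizing the clustering F-measure,
## globally and per taxonomic group, with eligibility filtering and the
## higher-rank "best" fallback.

.sweep_grid <- function(cfg) {
  nsteps <- floor((cfg@end - cfg@start) / cfg@step + .TOL)
  round(cfg@start + cfg@step * (0:nsteps), 9)
}

#' Sweep similarity thresholds and predict a cutoff
#'
#' Clusters the covered ids of \code{truth} at every threshold of the sweep
#' grid and scores each clustering with the clustering F-measure. The
#' predicted cutoff is the smallest grid threshold attaining the maximal F
#' (its resolving power); the full threshold-F curve is returned for
#' reporting. Clustering is restricted to ids annotated at the level rank,
#' since only they contribute ground truth.
#'
#' The sweep is evaluated incrementally: edges are added in descending score
#' order while the grid is walked from high to low, so the whole sweep costs
#' little more than one clustering.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param truth A [RankPartition-class] with at least two groups.
#' @param cfg A [SweepConfig-class].
#' @return A list with \code{entry} (one-row data.frame: level_rank,
#'   scope_rank, taxon, cutoff, confidence, seq_no, group_no, fallback_from)
#'   and \code{curve} (data.frame: threshold, f, ascending).
#' @export
sweepPredict <- function(mat, truth, cfg = sweepConfig()) {
  groups <- partitionGroups(truth)
  if (length(groups) == 0) stop("empty ground truth")
  if (length(groups) < 2)
    stop("degenerate truth: all ids fall in a single ground-truth group")
  ids <- coveredIds(truth)
  bad <- setdiff(ids, simIds(mat))
  if (length(bad) > 0)
    stop("truth ids not in matrix: ", paste(utils::head(bad, 5), collapse = ", "))
  grid <- .sweep_grid(cfg)
  class_code <- integer(length(ids))
  names(class_code) <- unlist(groups, use.names = FALSE)
  class_code[unlist(groups, use.names = FALSE)] <-
    rep(seq_along(groups), lengths(groups))
  ids <- sort(ids)
  class_code <- class_code[ids]

  p <- simPairs(mat)
  p <- p[p$id1 %in% ids & p$id2 %in% ids, , drop = FALSE]
  p <- p[order(-p$score), , drop = FALSE]
  ei <- match(p$id1, ids); ej <- match(p$id2, ids)

  ## incremental union-find from the top of the grid downwards
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  fvals <- numeric(length(grid))
  k <- 1L
  for (g in rev(seq_along(grid))) {
    t <- grid[g]
    while (k <= nrow(p) && p$score[k] >= t - .TOL) {
      ri <- find(ei[k]); rj <- find(ej[k])
      if (ri != rj) parent[ri] <- rj
      k <- k + 1L
    }
    labels <- vapply(seq_len(n), find, 1L)
    fvals[g] <- .fmeasure_core(class_code, labels, names(groups))$value
  }
  best <- max(fvals)
  cutoff <- min(grid[fvals == best])
  entry <- data.frame(level_rank = partitionRank(truth),
                      scope_rank = if (is.na(cfg@scopeRank)) "all" else cfg@scopeRank,
                      taxon = if (is.na(cfg@scopeTaxon)) "All" else cfg@scopeTaxon,
                      cutoff = cutoff, confidence = best,
                      seq_no = length(ids), group_no = length(groups),
                      fallback_from = NA_character_, stringsAsFactors = FALSE)
  list(entry = entry, curve = data.frame(threshold = grid, f = fvals))
}

#' Predict the global cutoff for a dataset
#'
#' Convenience wrapper: partitions all matrix ids at \code{levelRank} and runs
#' [sweepPredict()]. The resulting entry is keyed taxon = \code{"All"}.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param tax A [TaxonomyTable-class].
#' @param levelRank Rank whose groups are ground truth.
#' @param cfg A [SweepConfig-class]; its level rank is overridden by
#'   \code{levelRank}.
#' @param ids Ids to consider (default: all matrix ids).
#' @return A list with \code{table} (a one-entry [CutoffTable-class]) and
#'   \code{curve}.
#' @export
predictGlobal <- function(mat, tax, levelRank = "species", cfg = sweepConfig(),
                          ids = simIds(mat)) {
  cfg@levelRank <- levelRank
  truth <- partitionAtRank(tax, intersect(ids, taxIds(tax)), levelRank)
  res <- sweepPredict(mat, truth, cfg)
  tab <- new("CutoffTable", entries = res$entry,
             metadata = list(m = minAlignLength(mat),
                             sweep = c(start = cfg@start, end = cfg@end,
                                       step = cfg@step)))
  list(table = tab, curve = res$curve)
}

#' Predict local cutoffs per taxonomic group
#'
#' For every group at \code{scopeRank} passing the eligibility filter (more
#' than \code{minSeq} sequences, at least \code{minGroups} distinct
#' \code{levelRank} groups, largest group at most \code{maxDominance} of the
#' sequences), runs [sweepPredict()] restricted to the group's ids.
#' Ineligible groups are skipped with a message naming the failed criterion.
#' Counting uses the ids annotated at \code{levelRank}, since only those
#' contribute ground truth.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param tax A [TaxonomyTable-class].
#' @param levelRank Ground-truth rank (e.g. "species").
#' @param scopeRank Scope rank strictly above \code{levelRank} (e.g. "genus").
#' @param filter An [EligibilityFilter-class].
#' @param cfg A [SweepConfig-class].
#' @param ids Ids to consider (default: all matrix ids).
#' @return A [CutoffTable-class] with one entry per eligible group.
#' @export
predictLocal <- function(mat, tax, levelRank = "species", scopeRank = "genus",
                         filter = eligibilityFilter(), cfg = sweepConfig(),
                         ids = simIds(mat)) {
  li <- match(levelRank, .RANKS); si <- match(scopeRank, .RANKS)
  if (is.na(li) || is.na(si)) stop("unknown rank")
  if (si <= li) stop("scopeRank must be strictly above levelRank")
  scope <- partitionAtRank(tax, intersect(ids, taxIds(tax)), scopeRank)
  entries <- list()
  for (taxon in names(partitionGroups(scope))) {
    gids <- partitionGroups(scope)[[taxon]]
    truth <- partitionAtRank(tax, gids, levelRank)
    nseq <- length(coveredIds(truth))
    ngrp <- length(partitionGroups(truth))
    skip <- NULL
    if (nseq <= filter@minSeq) {
      skip <- sprintf("%d sequences (need more than %d)", nseq, filter@minSeq)
    } else if (ngrp < filter@minGroups) {
      skip <- sprintf("%d groups (need at least %d)", ngrp, filter@minGroups)
    } else {
      dom <- max(lengths(partitionGroups(truth))) / nseq
      if (dom > filter@maxDominance)
        skip <- sprintf("dominated by a single group (%.0f%% > %.0f%%)",
                        100 * dom, 100 * filter@maxDominance)
    }
    if (!is.null(skip)) {
      message("skipping ", scopeRank, " ", taxon, ": ", skip)
      next
    }
    lcfg <- cfg
    lcfg@levelRank <- levelRank
    lcfg@scopeRank <- scopeRank
    lcfg@scopeTaxon <- taxon
    entries[[taxon]] <- sweepPredict(mat, truth, lcfg)$entry
  }
  ent <- if (length(entries) == 0) {
    data.frame(level_rank = character(0), scope_rank = character(0),
               taxon = character(0), cutoff = numeric(0),
               confidence = numeric(0), seq_no = integer(0),
               group_no = integer(0), fallback_from = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, entries)
  rownames(ent) <- NULL
  new("CutoffTable", entries = ent,
      metadata = list(m = minAlignLength(mat),
                      sweep = c(start = cfg@start, end = cfg@end,
                                step = cfg@step),
                      filter = c(minSeq = filter@minSeq,
                                 minGroups = filter@minGroups,
                                 maxDominance = filter@maxDominance)))
}

## Ancestor chain of a taxon (names at successively higher ranks, ending in
## "All"), derived from the taxonomy table. `rank` is the taxon's own rank;
## if unknown it is searched among the ranks above levelRank.
.ancestor_chain <- function(taxon, levelRank, tax) {
  if (identical(taxon, "All")) return("All")
  tb <- taxTable(tax)
  li <- match(levelRank, .RANKS)
  ranks_above <- .RANKS[seq(li + 1L, length(.RANKS))]
  own <- NULL
  for (r in ranks_above) {
    if (taxon %in% tb[[r]]) { own <- r; break }
  }
  if (is.null(own)) return(c(taxon, "All"))  # unknown taxon: itself then global
  row <- tb[which(tb[[own]] == taxon)[1], ]
  higher <- .RANKS[seq(match(own, .RANKS) + 1L, length(.RANKS))]
  chain <- c(taxon, unlist(row[higher], use.names = FALSE))
  chain <- chain[nzchar(chain)]
  c(chain, "All")
}

#' Best cutoff along a taxon's ancestor chain
#'
#' When a taxon's own predicted cutoff is unreliable (low resolving power) or
#' absent, the best cutoff is the one predicted for the taxon or the
#' higher-level group on its ancestor chain (genus, family, order, class,
#' phylum, then the global entry) that achieves the highest confidence
#' (F-measure). Ties go to the most specific entry. \code{fallback_from}
#' records the source taxon when it is not the requested taxon.
#'
#' @param taxon Taxon name (or \code{"All"}).
#' @param levelRank Level rank of the wanted cutoff.
#' @param table A [CutoffTable-class] holding entries for the chain.
#' @param tax A [TaxonomyTable-class] used to derive the ancestor chain.
#' @return A one-row entry data.frame (see [sweepPredict()]).
#' @export
bestCutoff <- function(taxon, levelRank, table, tax) {
  chain <- .ancestor_chain(taxon, levelRank, tax)
  e <- cutoffEntries(table)
  e <- e[e$level_rank == levelRank & e$taxon %in% chain, , drop = FALSE]
  if (nrow(e) == 0)
    stop("no cutoff entry on the ancestor chain of '", taxon,
         "' at level ", levelRank)
  e$chain_pos <- match(e$taxon, chain)
  e <- e[order(-e$confidence, e$chain_pos), , drop = FALSE]
  out <- e[1, setdiff(names(e), "chain_pos"), drop = FALSE]
  if (out$taxon != taxon) out$fallback_from <- out$taxon
  rownames(out) <- NULL
  out
}

#' Write a cutoff table as JSON
#'
#' Serialization: \code{{"<level rank>": {"<taxon>": {"cut-off": x,
#' "confidence": f, "sequence number": n, "group number": g, "scope rank": r,
#' "fallback from": t|null}}}} plus a \code{"_metadata"} object. Reading the
#' file back reproduces the table exactly.
#'
#' @param table A [CutoffTable-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCutoffs <- function(table, path) {
  e <- cutoffEntries(table)
  out <- list()
  for (lv in unique(e$level_rank)) {
    sub <- e[e$level_rank == lv, , drop = FALSE]
    out[[lv]] <- stats::setNames(lapply(seq_len(nrow(sub)), function(i) {
      list(`cut-off` = sub$cutoff[i], confidence = sub$confidence[i],
           `sequence number` = sub$seq_no[i], `group number` = sub$group_no[i],
           `scope rank` = sub$scope_rank[i],
           `fallback from` = if (is.na(sub$fallback_from[i])) NULL
                             else sub$fallback_from[i])
    }), sub$taxon)
  }
  out[["_metadata"]] <- cutoffMetadata(table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a cutoff table written by [writeCutoffs()]
#'
#' @param path Input path.
#' @return A [CutoffTable-class].
#' @export
readCutoffs <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path)
  meta <- raw[["_metadata"]]
  raw[["_metadata"]] <- NULL
  rows <- list()
  for (lv in names(raw)) {
    for (taxon in names(raw[[lv]])) {
      x <- raw[[lv]][[taxon]]
      rows[[length(rows) + 1L]] <- data.frame(
        level_rank = lv,
        scope_rank = if (is.null(x[["scope rank"]])) "all" else x[["scope rank"]],
        taxon = taxon,
        cutoff = as.numeric(x[["cut-off"]]),
        confidence = as.numeric(x[["confidence"]]),
        seq_no = as.integer(x[["sequence number"]]),
        group_no = as.integer(x[["group number"]]),
        fallback_from = if (is.null(x[["fallback from"]])) NA_character_
                        else x[["fallback from"]],
        stringsAsFactors = FALSE)
    }
  }
  ent <- do.call(rbind, rows)
  rownames(ent) <- NULL
  new("CutoffTable", entries = ent,
      metadata = if (is.null(meta)) list() else lapply(meta, unlist))
}
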