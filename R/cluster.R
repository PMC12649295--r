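## Threshold clustering, clustering F-measure, indistinguishable species.

## Tolerance for threshold comparisons, so grid values produced by seq() and
## scores produced by ratios agree despite binary-float representation.
.TOL <- 1e-9

## Union-find over 1..n with path halving; returns component labels.
.uf_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(edges_i)) {
    ri <- find(edges_i[k]); rj <- find(edges_j[k])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, 1L)
}

#' Cluster sequences at a similarity threshold
#'
#' Computes the connected components of the graph on \code{ids} with an edge
#' wherever the stored pairwise score is at or above \code{t} (single-linkage
#' threshold clustering). Cluster ids are the lexicographically smallest
#' member, making the result deterministic.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param t Similarity threshold in [0,1]; thresholds below the matrix floor
#'   (for \code{t < 1}) trigger a warning because dropped entries could have
#'   merged clusters.
#' @param ids Ids to cluster (default: all ids of the matrix).
#' @return A [Clustering-class].
#' @export
clusterAt <- function(mat, t, ids = simIds(mat)) {
  if (length(ids) == 0) stop("empty id set")
  bad <- setdiff(ids, simIds(mat))
  if (length(bad) > 0)
    stop("ids not in matrix: ", paste(utils::head(bad, 5), collapse = ", "))
  if (t < 1 && t < scoreFloor(mat) - .TOL)
    warning("threshold ", t, " is below the matrix floor ", scoreFloor(mat),
            "; components may be under-merged")
  ids <- sort(ids)
  p <- simPairs(mat)
  p <- p[p$id1 %in% ids & p$id2 %in% ids & p$score >= t - .TOL, , drop = FALSE]
  comp <- .uf_components(length(ids), match(p$id1, ids), match(p$id2, ids))
  cl <- split(ids, comp)
  names(cl) <- vapply(cl, `[`, "", 1L)  # ids sorted, so first = smallest
  cl <- cl[order(names(cl))]
  new("Clustering", threshold = t, clusters = cl)
}

## Core F computation on integer membership vectors; shared by
## clusteringFMeasure and the sweep. cls/cluster are integer codes over the
## same id ordering. Returns list(value, perClass df).
.fmeasure_core <- function(class_code, cluster_code, class_names) {
  n <- length(class_code)
  ov <- table(class_code, cluster_code)
  nk <- rowSums(ov)   # class sizes
  nj <- colSums(ov)   # cluster sizes (restricted to evaluated ids)
  ## F_kj = 2 n_kj / (n_k + n_j); best over clusters per class
  denom <- outer(nk, nj, `+`)
  F <- 2 * ov / denom
  bestF <- apply(F, 1, max)
  value <- sum(nk / n * bestF)
  list(value = value,
       per_class = data.frame(class = class_names, n = as.integer(nk),
                              best_F = as.numeric(bestF),
                              stringsAsFactors = FALSE, row.names = NULL))
}

#' Clustering F-measure against a ground-truth partition
#'
#' Scores a clustering against the taxonomic ground truth with the clustering
#' F-measure: for each ground-truth class k of size n_k and cluster j of size
#' n_j sharing n_kj ids, F(k,j) is the harmonic mean of precision n_kj/n_j and
#' recall n_kj/n_k; each class contributes its best F over clusters, weighted
#' by class size. Evaluation is restricted to the ids covered by the
#' partition. The value is 1 exactly when clusters coincide with classes.
#'
#' @param cl A [Clustering-class] whose ids include the partition's covered
#'   ids.
#' @param truth A [RankPartition-class].
#' @return A list with \code{value} (overall F in [0,1]) and
#'   \code{per_class} (data.frame: class, n, best_F).
#' @export
clusteringFMeasure <- function(cl, truth) {
  groups <- partitionGroups(truth)
  if (length(groups) == 0) stop("empty ground truth")
  covered <- coveredIds(truth)
  member <- unlist(clusters(cl), use.names = FALSE)
  miss <- setdiff(covered, member)
  if (length(miss) > 0)
    stop("ids in truth but not clustered: ",
         paste(utils::head(miss, 5), collapse = ", "))
  class_code <- rep(seq_along(groups), lengths(groups))
  ids <- unlist(groups, use.names = FALSE)
  cluster_of <- rep(seq_along(clusters(cl)), lengths(clusters(cl)))
  names(cluster_of) <- member
  .fmeasure_core(class_code, unname(cluster_of[ids]), names(groups))
}

#' Detect indistinguishable species complexes
#'
#' Clusters all sequences at 100% similarity; every cluster containing
#' sequences of two or more species yields a complex of those species.
#' Complexes sharing a species (a species whose sequences split across
#' clusters) are unioned. Within-species co-clustering alone never creates a
#' complex.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param species The species-rank [RankPartition-class] of the same dataset.
#' @param t Similarity defining "indistinguishable" (default 1.0).
#' @return A list of complexes, each a list with \code{members} (sorted
#'   species names, >= 2) and \code{representative} (alphabetically first
#'   member).
#' @export
indistinguishableComplexes <- function(mat, species, t = 1.0) {
  stopifnot(partitionRank(species) == "species")
  covered <- coveredIds(species)
  if (length(covered) == 0) return(list())
  cl <- clusterAt(mat, t, ids = covered)
  sp_of <- rep(names(partitionGroups(species)), lengths(partitionGroups(species)))
  names(sp_of) <- unlist(partitionGroups(species), use.names = FALSE)
  merged <- lapply(clusters(cl), function(memb) sort(unique(unname(sp_of[memb]))))
  merged <- merged[lengths(merged) >= 2]
  if (length(merged) == 0) return(list())
  ## union complexes sharing a species
  sp <- sort(unique(unlist(merged)))
  comp <- .uf_components(length(sp),
                         unlist(lapply(merged, function(m) match(m[-length(m)], sp))),
                         unlist(lapply(merged, function(m) match(m[-1], sp))))
  out <- lapply(split(sp, comp), function(m) {
    m <- sort(m)
    list(members = m, representative = m[1])
  })
  names(out) <- NULL
  out[order(vapply(out, function(x) x$representative, ""))]
}

#' Remove indistinguishable species, keeping one representative per complex
#'
#' For each complex, drops the sequences of all member species except the
#' representative (alphabetically first member unless overridden). All other
#' records are retained.
#'
#' @param x A [BarcodeSet-class] (or named \code{DNAStringSet}).
#' @param tax A [TaxonomyTable-class].
#' @param complexes Output of [indistinguishableComplexes()].
#' @param representatives Optional named character vector overriding the
#'   representative per complex, named by the default representative.
#' @return \code{x} with the dropped species' sequences removed.
#' @export
deduplicateSpecies <- function(x, tax, complexes, representatives = NULL) {
  if (length(complexes) == 0) return(x)
  drop_species <- unlist(lapply(complexes, function(cx) {
    rep <- cx$representative
    if (!is.null(representatives) && rep %in% names(representatives)) {
      rep <- representatives[[rep]]
      if (!rep %in% cx$members)
        stop("override representative '", rep, "' is not a member of the complex")
    }
    setdiff(cx$members, rep)
  }))
  tb <- taxTable(tax)
  drop_ids <- tb$id[tb$species %in% drop_species]
  x[!names(x) %in% drop_ids]
}
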