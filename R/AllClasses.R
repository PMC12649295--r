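#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

## The seven-rank vocabulary used throughout, ordered from the most specific
## (strain) to the most inclusive (phylum).
.RANKS <- c("strain", "species", "genus", "family", "order", "class", "phylum")

#' Taxonomic rank vocabulary
#'
#' Returns the fixed rank vocabulary used by all partitioning, cutoff and
#' classification functions, ordered from the most specific (strain) to the
#' most inclusive (phylum).
#'
#' @return Character vector of the seven rank names.
#' @export
#' @examples
#' taxRanks()
taxRanks <- function() .RANKS

#' BarcodeSet: a set of DNA barcode sequences
#'
#' A thin extension of [Biostrings::DNAStringSet-class] that enforces unique,
#' non-empty sequence identifiers and carries a marker label (e.g. \code{"ITS"},
#' \code{"LSU"}). The marker label is purely descriptive: it never alters any
#' computation, only reporting.
#'
#' @slot marker Character scalar; one of \code{"ITS"}, \code{"ITS1"},
#'   \code{"ITS2"}, \code{"LSU"} or \code{"other"}.
#' @export
setClass("BarcodeSet", contains = "DNAStringSet",
         representation(marker = "character"),
         prototype(marker = "other"))

setValidity("BarcodeSet", function(object) {
  ids <- names(object)
  if (length(object) > 0 && (is.null(ids) || any(!nzchar(ids))))
    return("all sequences must have non-empty ids (names)")
  if (anyDuplicated(ids))
    return(paste0("duplicate sequence ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object) > 0 && any(width(object) < 1))
    return("zero-length sequences are not allowed")
  if (length(object@marker) != 1L)
    return("marker must be a single label")
  TRUE
})

#' Construct a BarcodeSet
#'
#' @param seqs A named character vector or [Biostrings::DNAStringSet-class];
#'   names are the sequence ids. Residues are uppercased.
#' @param marker Marker label (reporting only).
#' @return A [BarcodeSet-class].
#' @export
#' @examples
#' BarcodeSet(c(a = "ACGT", b = "ACGA"), marker = "ITS")
BarcodeSet <- function(seqs, marker = "other") {
  if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
  new("BarcodeSet", seqs, marker = marker)
}

#' @describeIn BarcodeSet-class marker label accessor
#' @param x A BarcodeSet.
#' @export
marker <- function(x) {
  stopifnot(is(x, "BarcodeSet"))
  x@marker
}

setMethod("show", "BarcodeSet", function(object) {
  cat("BarcodeSet of", length(object), "sequences, marker:", object@marker, "\n")
  callNextMethod()
})

#' TaxonomyTable: per-sequence taxonomic annotation
#'
#' Rows keyed by sequence id with name columns for the seven ranks
#' (strain ... phylum) plus optional \code{is_type} and \code{is_new} flags.
#' An empty string means "unannotated at this rank" and excludes the row from
#' partitions at that rank.
#'
#' @slot tab A data.frame with columns \code{id}, the seven ranks,
#'   \code{is_type}, \code{is_new}.
#' @export
setClass("TaxonomyTable", representation(tab = "data.frame"))

setValidity("TaxonomyTable", function(object) {
  tb <- object@tab
  need <- c("id", .RANKS)
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  if (anyDuplicated(tb$id))
    return(paste0("duplicate ids: ",
                  paste(unique(tb$id[duplicated(tb$id)]), collapse = ", ")))
  if (any(!nzchar(tb$id))) return("empty ids are not allowed")
  TRUE
})

setMethod("show", "TaxonomyTable", function(object) {
  tb <- object@tab
  cat("TaxonomyTable:", nrow(tb), "records\n")
  for (r in rev(.RANKS)) {
    ann <- sum(.annotated(tb[[r]], r))
    cat(sprintf("  %-8s %5d annotated, %4d groups\n", r, ann,
                length(unique(tb[[r]][.annotated(tb[[r]], r)]))))
  }
})

#' RankPartition: ground-truth grouping at one rank
#'
#' Maps taxon names at one rank to the sets of sequence ids annotated with
#' them. Ids unannotated at the rank are excluded (\code{covered} holds the
#' included ids).
#'
#' @slot rank One of [taxRanks()].
#' @slot groups Named list of character vectors (taxon name -> ids).
#' @slot covered Character vector, the union of the groups.
#' @export
setClass("RankPartition",
         representation(rank = "character", groups = "list", covered = "character"))

setValidity("RankPartition", function(object) {
  if (!object@rank %in% .RANKS) return("unknown rank")
  all_ids <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) return("groups are not disjoint")
  if (!setequal(all_ids, object@covered)) return("covered != union of groups")
  TRUE
})

setMethod("show", "RankPartition", function(object) {
  cat("RankPartition at rank", object@rank, ":", length(object@groups),
      "groups over", length(object@covered), "ids\n")
})

#' @describeIn RankPartition-class the taxon-name -> id-set mapping
#' @param x A RankPartition.
#' @export
partitionGroups <- function(x) {
  stopifnot(is(x, "RankPartition"))
  x@groups
}

#' @describeIn RankPartition-class the ids covered (annotated) at the rank
#' @export
coveredIds <- function(x) {
  stopifnot(is(x, "RankPartition"))
  x@covered
}

#' @describeIn RankPartition-class the rank of the partition
#' @export
partitionRank <- function(x) {
  stopifnot(is(x, "RankPartition"))
  x@rank
}

#' AlignmentParams: local alignment and score-adjustment parameters
#'
#' Parameters of the pairwise similarity computation: the minimum alignment
#' length \code{m} used by the \code{s * l / m} adjustment, the alignment
#' scoring scheme, and the retention floor for sparse similarity matrices.
#'
#' @slot m Minimum alignment length in bases (e.g. 400 for full ITS/LSU,
#'   50 for ITS1/ITS2).
#' @slot match,mismatch Integer match reward / mismatch penalty.
#' @slot gapOpen,gapExtend Non-negative integer affine gap costs; a gap of
#'   length L costs \code{gapOpen + L * gapExtend}.
#' @slot floor Minimum score retained in similarity matrices, in [0,1].
#' @export
setClass("AlignmentParams",
         representation(m = "integer", match = "integer", mismatch = "integer",
                        gapOpen = "integer", gapExtend = "integer", floor = "numeric"))

setValidity("AlignmentParams", function(object) {
  if (object@m < 1L) return("m must be >= 1")
  if (object@floor < 0 || object@floor > 1) return("floor must be in [0,1]")
  if (object@gapOpen < 0L || object@gapExtend < 0L) return("gap costs must be >= 0")
  TRUE
})

#' Construct alignment parameters
#'
#' Defaults follow the common nucleotide-search scheme (match +2, mismatch -3,
#' gap open 5, gap extend 2). \code{m = 400} suits full-length ITS/LSU
#' barcodes; use \code{m = 50} for the short ITS1/ITS2 sub-regions.
#'
#' @param m Minimum alignment length in bases.
#' @param match,mismatch,gapOpen,gapExtend Alignment scoring parameters.
#' @param floor Retention floor for sparse matrices.
#' @return An [AlignmentParams-class].
#' @export
#' @examples
#' alignmentParams(m = 50)
alignmentParams <- function(m = 400L, match = 2L, mismatch = -3L,
                            gapOpen = 5L, gapExtend = 2L, floor = 0.5) {
  new("AlignmentParams", m = as.integer(m), match = as.integer(match),
      mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend), floor = floor)
}

setMethod("show", "AlignmentParams", function(object) {
  cat(sprintf("AlignmentParams: m=%d match=%+d mismatch=%+d gapOpen=%d gapExtend=%d floor=%.2f\n",
              object@m, object@match, object@mismatch, object@gapOpen,
              object@gapExtend, object@floor))
})

#' SimilarityMatrix: sparse symmetric pairwise similarity scores
#'
#' Stores length-adjusted pairwise similarity scores in [0,1] for unordered id
#' pairs, together with the minimum-alignment-length parameter \code{m} and the
#' retention floor. Self-similarity is defined as 1 and never stored; entries
#' below the floor are dropped.
#'
#' @slot ids Ordered character vector of sequence ids.
#' @slot pairs data.frame with columns \code{id1}, \code{id2}, \code{score}
#'   (\code{id1 < id2} lexicographically).
#' @slot m Minimum alignment length used.
#' @slot floor Retention floor.
#' @export
setClass("SimilarityMatrix",
         representation(ids = "character", pairs = "data.frame",
                        m = "integer", floor = "numeric"))

setValidity("SimilarityMatrix", function(object) {
  if (anyDuplicated(object@ids)) return("duplicate ids")
  p <- object@pairs
  if (!all(c("id1", "id2", "score") %in% names(p))) return("pairs needs id1,id2,score")
  if (nrow(p) > 0) {
    if (any(p$score < 0 | p$score > 1)) return("scores must be in [0,1]")
    if (any(p$id1 == p$id2)) return("self-pairs are not stored")
    if (any(!(p$id1 %in% object@ids) | !(p$id2 %in% object@ids)))
      return("pair ids outside id universe")
    if (any(p$score < object@floor - 1e-12)) return("stored score below floor")
    if (any(p$id1 >= p$id2)) return("pairs must be canonically ordered id1 < id2")
    if (anyDuplicated(paste(p$id1, p$id2))) return("duplicate pairs")
  }
  TRUE
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix:", length(object@ids), "ids,", nrow(object@pairs),
      sprintf("stored pairs (m=%d, floor=%.2f)\n", object@m, object@floor))
})

#' @describeIn SimilarityMatrix-class id universe accessor
#' @param x A SimilarityMatrix.
#' @export
simIds <- function(x) {
  stopifnot(is(x, "SimilarityMatrix"))
  x@ids
}

#' @describeIn SimilarityMatrix-class stored pairs as a data.frame
#' @export
simPairs <- function(x) {
  stopifnot(is(x, "SimilarityMatrix"))
  x@pairs
}

#' @describeIn SimilarityMatrix-class minimum alignment length used
#' @export
minAlignLength <- function(x) {
  stopifnot(is(x, "SimilarityMatrix"))
  x@m
}

#' @describeIn SimilarityMatrix-class retention floor
#' @export
scoreFloor <- function(x) {
  stopifnot(is(x, "SimilarityMatrix"))
  x@floor
}

#' Clustering: threshold clustering of sequence ids
#'
#' Connected components of the graph whose edges are pairs with similarity
#' at or above the threshold. Cluster ids are the lexicographically smallest
#' member of each cluster, so clusterings are deterministic.
#'
#' @slot threshold The similarity threshold used.
#' @slot clusters Named list (cluster id -> character vector of member ids).
#' @export
setClass("Clustering",
         representation(threshold = "numeric", clusters = "list"))

setValidity("Clustering", function(object) {
  ids <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(ids)) return("clusters are not disjoint")
  cid <- vapply(object@clusters, function(v) min(v), "")
  if (!identical(unname(cid), names(object@clusters)) &&
      !all(cid == names(object@clusters)))
    return("cluster ids must be the smallest member")
  TRUE
})

setMethod("show", "Clustering", function(object) {
  cat(sprintf("Clustering at t=%.4g: %d clusters over %d ids\n",
              object@threshold, length(object@clusters),
              length(unlist(object@clusters, use.names = FALSE))))
})

#' @describeIn Clustering-class cluster membership list
#' @param x A Clustering.
#' @export
clusters <- function(x) {
  stopifnot(is(x, "Clustering"))
  x@clusters
}

#' @describeIn Clustering-class threshold used
#' @export
clusterThreshold <- function(x) {
  stopifnot(is(x, "Clustering"))
  x@threshold
}

#' SweepConfig: threshold-sweep configuration
#'
#' The grid of similarity thresholds swept when predicting a cutoff, and the
#' rank whose groups serve as ground truth. Optionally restricted to one
#' higher-rank group (local prediction).
#'
#' @slot start,end,step Sweep grid \code{start, start+step, ..., end}.
#' @slot levelRank Rank whose groups are the ground truth.
#' @slot scopeRank,scopeTaxon Optional restriction to one group.
#' @export
setClass("SweepConfig",
         representation(start = "numeric", end = "numeric", step = "numeric",
                        levelRank = "character", scopeRank = "character",
                        scopeTaxon = "character"))

setValidity("SweepConfig", function(object) {
  if (object@start >= object@end) return("start must be < end")
  if (object@step <= 0) return("step must be > 0")
  if (!object@levelRank %in% .RANKS) return("unknown levelRank")
  TRUE
})

#' Construct a sweep configuration
#'
#' The default grid is 0.70 to 1.00 in steps of 0.001, appropriate for
#' species-level cutoffs; for genus and higher ranks a lower \code{start}
#' (e.g. 0.5) is advisable because optimal cutoffs can fall well below 0.7.
#'
#' @param start,end,step Sweep grid bounds and resolution.
#' @param levelRank Rank whose groups are the ground truth (default species).
#' @param scopeRank,scopeTaxon Optional restriction to one group.
#' @return A [SweepConfig-class].
#' @export
sweepConfig <- function(start = 0.70, end = 1.00, step = 0.001,
                        levelRank = "species", scopeRank = NA_character_,
                        scopeTaxon = NA_character_) {
  new("SweepConfig", start = start, end = end, step = step,
      levelRank = levelRank, scopeRank = scopeRank, scopeTaxon = scopeTaxon)
}

setMethod("show", "SweepConfig", function(object) {
  cat(sprintf("SweepConfig: [%g, %g] step %g, level=%s%s\n", object@start,
              object@end, object@step, object@levelRank,
              if (!is.na(object@scopeTaxon))
                paste0(", scope=", object@scopeRank, ":", object@scopeTaxon) else ""))
})

#' EligibilityFilter: group-eligibility rules for local cutoff prediction
#'
#' A scope group enters local prediction only if it has more than
#' \code{minSeq} sequences, at least \code{minGroups} distinct ground-truth
#' groups, and its largest ground-truth group holds at most
#' \code{maxDominance} of the sequences.
#'
#' @slot minSeq Exclusive lower bound on group sequence count (default 30,
#'   i.e. "more than 30").
#' @slot minGroups Minimum number of distinct ground-truth groups (default 5).
#' @slot maxDominance Exclusion threshold on the largest group's share
#'   (default 0.70; groups with a share strictly above it are skipped).
#' @export
setClass("EligibilityFilter",
         representation(minSeq = "integer", minGroups = "integer",
                        maxDominance = "numeric"))

setValidity("EligibilityFilter", function(object) {
  if (object@minSeq < 1L || object@minGroups < 1L || object@maxDominance <= 0)
    return("all thresholds must be positive")
  TRUE
})

#' Construct an eligibility filter
#'
#' @param minSeq,minGroups,maxDominance See [EligibilityFilter-class].
#' @return An [EligibilityFilter-class].
#' @export
eligibilityFilter <- function(minSeq = 30L, minGroups = 5L, maxDominance = 0.70) {
  new("EligibilityFilter", minSeq = as.integer(minSeq),
      minGroups = as.integer(minGroups), maxDominance = maxDominance)
}

#' CutoffTable: predicted similarity cutoffs keyed by (level, scope, taxon)
#'
#' Each entry records the predicted cutoff for delineating groups at
#' \code{level_rank} within the scope taxon (\code{"All"} for global entries),
#' its confidence (the F-measure at the cutoff, i.e. the resolving power),
#' and the evaluated sequence/group counts. Entries produced by the best-cutoff
#' fallback carry the source taxon in \code{fallback_from}.
#'
#' @slot entries data.frame with columns \code{level_rank}, \code{scope_rank},
#'   \code{taxon}, \code{cutoff}, \code{confidence}, \code{seq_no},
#'   \code{group_no}, \code{fallback_from}.
#' @slot metadata List: marker label, \code{m}, sweep configuration, etc.
#' @export
setClass("CutoffTable",
         representation(entries = "data.frame", metadata = "list"))

setValidity("CutoffTable", function(object) {
  e <- object@entries
  need <- c("level_rank", "scope_rank", "taxon", "cutoff", "confidence",
            "seq_no", "group_no", "fallback_from")
  if (!all(need %in% names(e)))
    return(paste("entries missing columns:",
                 paste(setdiff(need, names(e)), collapse = ", ")))
  if (nrow(e) > 0) {
    if (any(e$confidence < 0 | e$confidence > 1)) return("confidence outside [0,1]")
    if (any(e$seq_no < e$group_no)) return("seq_no must be >= group_no")
    if (anyDuplicated(paste(e$level_rank, e$scope_rank, e$taxon)))
      return("duplicate (level, scope, taxon) keys")
  }
  TRUE
})

setMethod("show", "CutoffTable", function(object) {
  cat("CutoffTable:", nrow(object@entries), "entries\n")
  if (nrow(object@entries) > 0)
    print(utils::head(object@entries, 10))
})

#' @describeIn CutoffTable-class entries as a data.frame
#' @param x A CutoffTable.
#' @export
cutoffEntries <- function(x) {
  stopifnot(is(x, "CutoffTable"))
  x@entries
}

#' @describeIn CutoffTable-class metadata list
#' @export
cutoffMetadata <- function(x) {
  stopifnot(is(x, "CutoffTable"))
  x@metadata
}

#' Combine cutoff tables
#'
#' Concatenates the entries of several [CutoffTable-class] objects (e.g. a
#' global entry with local per-genus entries). Duplicate
#' (level, scope, taxon) keys are an error.
#'
#' @param ... CutoffTable objects.
#' @return A combined [CutoffTable-class]; metadata is taken from the first.
#' @export
combineCutoffs <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) > 0, all(vapply(tabs, is, TRUE, "CutoffTable")))
  ent <- do.call(rbind, lapply(tabs, cutoffEntries))
  new("CutoffTable", entries = ent, metadata = cutoffMetadata(tabs[[1]]))
}
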