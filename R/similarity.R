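## Pairwise similarity: local-alignment percent identity with the minimum
## alignment-length adjustment s * l / m.

#' Length-adjusted similarity score
#'
#' Adjusts a percent-identity fraction \code{s} for short alignments: when the
#' alignment length \code{l} is at least the minimum \code{m}, the score is
#' \code{s} unchanged; when shorter, it is \code{s * l / m}. This prevents
#' short sequences from appearing artificially similar to all others. The
#' result is clamped to [0,1]; \code{l = 0} gives 0.
#'
#' @param s Percent identity as a fraction in [0,1] (vectorized).
#' @param l Alignment length in columns (vectorized).
#' @param params An [AlignmentParams-class] supplying \code{m}.
#' @return Adjusted similarity in [0,1].
#' @export
#' @examples
#' p <- alignmentParams(m = 400)
#' adjustScore(0.98, 450, p)  # 0.98: long enough
#' adjustScore(0.98, 300, p)  # 0.735
adjustScore <- function(s, l, params = alignmentParams()) {
  stopifnot(all(s >= 0 & s <= 1), all(l >= 0))
  out <- ifelse(l >= params@m, s, s * l / params@m)
  pmin(pmax(out, 0), 1)
}

## Batch alignment of one subject against many patterns.
## Returns a matrix with columns score, nmatch, length.
.align_batch <- function(subject, patterns, params) {
  .sw_batch(subject, patterns, params@match, params@mismatch,
            params@gapOpen, params@gapExtend)
}

.as_seq_chars <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is(x, "DNAString")) {
    out <- as.character(x)
  } else {
    out <- toupper(as.character(x))
  }
  out
}

#' Pairwise similarity between two barcodes
#'
#' Computes the best local alignment between two sequences under the scoring
#' scheme in \code{params}. The raw identity \code{s} is the number of matched
#' columns divided by the total alignment columns (gap columns count in the
#' denominator); the reported \code{score} applies the \code{s * l / m}
#' adjustment. Ambiguity codes (N etc.) always score as mismatches. The result
#' is symmetric in its arguments.
#'
#' @param a,b Sequences (character scalars, \code{DNAString}, or length-1
#'   \code{DNAStringSet}).
#' @param params An [AlignmentParams-class].
#' @return A list with elements \code{s}, \code{l}, \code{score}.
#' @export
#' @examples
#' pairSimilarity("ACGTACGTACGT", "ACGTACGAACGT", alignmentParams(m = 10))
pairSimilarity <- function(a, b, params = alignmentParams()) {
  a <- .as_seq_chars(a)[1]
  b <- .as_seq_chars(b)[1]
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  r <- .align_batch(a, b, params)
  l <- as.integer(r[1, "length"])
  s <- if (l == 0) 0 else unname(r[1, "nmatch"]) / l
  list(s = s, l = l, score = unname(adjustScore(s, l, params)))
}

#' Build a sparse pairwise similarity matrix
#'
#' Evaluates all unordered pairs of sequences with the internal local aligner,
#' applies the length adjustment, and stores scores at or above the retention
#' floor. Self-similarity is defined as 1 and never stored.
#'
#' @param x A [BarcodeSet-class] or named \code{DNAStringSet} (>= 2 sequences,
#'   unique ids).
#' @param params An [AlignmentParams-class].
#' @return A [SimilarityMatrix-class].
#' @export
buildSimilarityMatrix <- function(x, params = alignmentParams()) {
  ids <- names(x)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique ids")
  n <- length(x)
  if (n < 2) stop("need at least 2 sequences")
  seqs <- .as_seq_chars(x)
  id1 <- character(0); id2 <- character(0); sc <- numeric(0)
  for (i in seq_len(n - 1L)) {
    r <- .align_batch(seqs[i], seqs[(i + 1L):n], params)
    l <- r[, "length"]
    s <- ifelse(l == 0, 0, r[, "nmatch"] / pmax(l, 1))
    score <- adjustScore(s, l, params)
    keep <- score >= params@floor
    if (any(keep)) {
      ji <- ids[(i + 1L):n][keep]
      a <- rep(ids[i], sum(keep))
      swap <- ji < a
      id1 <- c(id1, ifelse(swap, ji, a))
      id2 <- c(id2, ifelse(swap, a, ji))
      sc <- c(sc, score[keep])
    }
  }
  pairs <- data.frame(id1 = id1, id2 = id2, score = sc, stringsAsFactors = FALSE)
  new("SimilarityMatrix", ids = ids, pairs = pairs,
      m = params@m, floor = params@floor)
}

#' Look up pairwise scores in a similarity matrix
#'
#' Returns the stored score for each requested pair; identical ids give 1,
#' absent pairs give \code{default} (the floor by convention in variation
#' statistics, 0 by default here).
#'
#' @param mat A [SimilarityMatrix-class].
#' @param a,b Id vectors (recycled to common length).
#' @param default Value for pairs not stored.
#' @return Numeric vector of scores.
#' @export
simScore <- function(mat, a, b, default = 0) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  k1 <- pmin(a, b); k2 <- pmax(a, b)
  p <- simPairs(mat)
  idx <- match(paste0(k1, "\r", k2), paste0(p$id1, "\r", p$id2))
  out <- ifelse(is.na(idx), default, p$score[idx])
  out[a == b] <- 1
  out
}

#' Import precomputed pairwise similarities (12-column tabular format)
#'
#' Reads the standard 12-column tabular output of pairwise search tools
#' (query id, subject id, percent identity on a 0-100 scale, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value, bit
#' score). Per (query, subject) pair only the row with the highest bit score
#' is kept; identity is converted to a fraction and length-adjusted; the two
#' directions are symmetrized by taking the maximum; self-pairs are dropped,
#' as are scores below the floor.
#'
#' @param path Path to the tabular file (no header).
#' @param params An [AlignmentParams-class].
#' @param ids Optional id universe; defaults to the ids seen in the file.
#' @return A [SimilarityMatrix-class].
#' @export
importPairwise <- function(path, params = alignmentParams(), ids = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(raw) != 12)
    stop("expected 12 tab-separated columns, found ", ncol(raw))
  num_cols <- c(3, 4, 12)
  for (j in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v))
      stop("malformed row at line ", which(is.na(v))[1],
           ": non-numeric value in column ", j)
    raw[[j]] <- v
  }
  q <- as.character(raw[[1]]); s <- as.character(raw[[2]])
  pid <- raw[[3]] / 100; len <- raw[[4]]; bits <- raw[[12]]
  if (any(pid < 0 | pid > 1.0000001))
    stop("percent identity outside 0-100 at line ", which(pid < 0 | pid > 1.0000001)[1])
  ## best hit per directed pair
  key <- paste0(q, "\r", s)
  ord <- order(key, -bits)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  q <- q[sel]; s <- s[sel]; pid <- pid[sel]; len <- len[sel]
  score <- adjustScore(pmin(pid, 1), len, params)
  ## symmetrize by max over the two directions, drop self-pairs
  keep <- q != s
  q <- q[keep]; s <- s[keep]; score <- score[keep]
  k1 <- pmin(q, s); k2 <- pmax(q, s)
  ukey <- paste0(k1, "\r", k2)
  agg <- tapply(score, ukey, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  pairs <- data.frame(id1 = vapply(parts, `[`, "", 1),
                      id2 = vapply(parts, `[`, "", 2),
                      score = as.numeric(agg), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$score >= params@floor, , drop = FALSE]
  rownames(pairs) <- NULL
  universe <- if (is.null(ids)) sort(unique(c(raw[[1]], raw[[2]]))) else ids
  new("SimilarityMatrix", ids = universe, pairs = pairs,
      m = params@m, floor = params@floor)
}

#' Write a similarity matrix as 3-column TSV
#'
#' The first line is a comment header recording \code{m} and the floor;
#' the body has columns id1, id2, score.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSimilarityMatrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m=%d floor=%g ids=%s", mat@m, mat@floor,
                     paste(mat@ids, collapse = ",")), con)
  utils::write.table(simPairs(mat), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("id1", "id2", "score"))
  invisible(path)
}

#' Read a similarity matrix written by [writeSimilarityMatrix()]
#'
#' @param path Input path.
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  m <- as.integer(sub(".*m=(\\d+).*", "\\1", header))
  floor <- as.numeric(sub(".*floor=([0-9.eE+-]+) .*", "\\1", header))
  ids <- strsplit(sub(".*ids=", "", header), ",", fixed = TRUE)[[1]]
  pairs <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                             stringsAsFactors = FALSE)
  new("SimilarityMatrix", ids = ids, pairs = pairs, m = m, floor = floor)
}
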