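## Shared fixtures and independent oracles for the test suite.

## -- sequence helpers --------------------------------------------------------

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

## substitute exactly k interior positions (>= margin from either end), always
## to a different base, so the optimal local alignment keeps full length
mutate_subs <- function(s, k, margin = 4) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq(margin + 1, length(v) - margin), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

## insert one random base at a random position
mutate_indel <- function(s) {
  v <- strsplit(s, "")[[1]]
  p <- sample(length(v), 1)
  paste(append(v, sample(c("A", "C", "G", "T"), 1), after = p), collapse = "")
}

## -- hand-built similarity matrices ------------------------------------------

## build a SimilarityMatrix directly from a data.frame of (id1, id2, score)
msim <- function(ids, pairs, m = 400L, floor = 0) {
  if (nrow(pairs) > 0) {
    k1 <- pmin(pairs$id1, pairs$id2)
    k2 <- pmax(pairs$id1, pairs$id2)
    pairs <- data.frame(id1 = k1, id2 = k2, score = pairs$score,
                        stringsAsFactors = FALSE)
  }
  new("SimilarityMatrix", ids = ids, pairs = pairs, m = as.integer(m),
      floor = floor)
}

edge_df <- function(...) {
  e <- list(...)
  data.frame(id1 = vapply(e, `[[`, "", 1), id2 = vapply(e, `[[`, "", 2),
             score = as.numeric(vapply(e, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

## random sparse similarity matrix over n ids
random_msim <- function(n, density = 0.3, floor = 0) {
  ids <- sprintf("r%02d", seq_len(n))
  cmb <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(cmb)) < density
  pairs <- data.frame(id1 = cmb[1, keep], id2 = cmb[2, keep],
                      score = round(stats::runif(sum(keep)), 3),
                      stringsAsFactors = FALSE)
  msim(ids, pairs, floor = floor)
}

## -- independent oracles ------------------------------------------------------

## exhaustive clustering F-measure: loops over every class x cluster pair,
## computing precision/recall/harmonic mean from raw set intersections
fmeasure_oracle <- function(cluster_list, class_list) {
  covered <- unlist(class_list, use.names = FALSE)
  n <- length(covered)
  total <- 0
  for (cls in class_list) {
    best <- 0
    for (clu in cluster_list) {
      clu <- intersect(clu, covered)
      nkj <- length(intersect(cls, clu))
      if (nkj == 0) next
      P <- nkj / length(clu)
      R <- nkj / length(cls)
      F <- 2 * P * R / (P + R)
      if (F > best) best <- F
    }
    total <- total + length(cls) / n * best
  }
  total
}

## connected components at threshold t via igraph (independent of the
## union-find implementation in the package)
components_oracle <- function(mat, ids, t) {
  p <- simPairs(mat)
  p <- p[p$id1 %in% ids & p$id2 %in% ids & p$score >= t - 1e-9, , drop = FALSE]
  g <- igraph::graph_from_data_frame(p[, c("id1", "id2")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership
  unname(split(names(memb), memb))
}

## local alignment oracle via Biostrings (exact affine-gap DP, independent
## implementation): returns score, nmatch, length
bios_align <- function(a, b, match = 2, mismatch = -3, gapOpen = 5, gapExtend = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(b),
                                       Biostrings::DNAString(a),
                                       type = "local", substitutionMatrix = sm,
                                       gapOpening = gapOpen,
                                       gapExtension = gapExtend)
  c(score = Biostrings::score(aln), nmatch = Biostrings::nmatch(aln),
    length = Biostrings::nchar(aln))
}

## -- small taxonomy fixture ---------------------------------------------------

## two phyla / two genera / four species over eight ids
tiny_tax <- function() {
  taxonomyTable(data.frame(
    id = sprintf("t%d", 1:8),
    species = c("S1", "S1", "S2", "S2", "S3", "S3", "S4", "S4"),
    genus = c("G1", "G1", "G1", "G1", "G2", "G2", "G2", "G2"),
    family = c("F1", "F1", "F1", "F1", "F2", "F2", "F2", "F2"),
    order = "O1", class = "C1",
    phylum = c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P2"),
    stringsAsFactors = FALSE))
}

## spec for quick end-to-end datasets with a clean identity gap
gap_spec <- function(seed, planted = 0L, counts = list(phyla = 2, classes = 1,
                                                       orders = 1, families = 2,
                                                       genera = 5, species = 5,
                                                       strains = 2)) {
  simulationSpec(counts = counts, lengthRange = c(150, 300),
                 ladder = c(species = 0.02, genus = 0.06, family = 0.12,
                            order = 0.18, class = 0.25),
                 strainNoise = 0.001, indelFrac = 0.1,
                 plantedComplexes = planted, seed = seed)
}

short_params <- function(floor = 0.5) alignmentParams(m = 50L, floor = floor)
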