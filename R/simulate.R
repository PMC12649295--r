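## Synthetic barcode-dataset generator: hierarchical taxonomy with a
## rank-structured divergence ladder, planted indistinguishable species
## complexes, and error-bearing query reads. Every downstream stage of the
## package can be verified against the planted ground truth.

## Run code under a given seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' SimulationSpec: parameters of the synthetic barcode generator
#'
#' @slot counts Named list (phyla, classes, orders, families, genera, species,
#'   strains): children per parent node. Each element is a single integer
#'   (fixed) or a length-2 integer range from which counts are drawn with a
#'   long-tailed distribution, creating the taxonomic imbalance typical of
#'   barcode reference sets (a few dominant genera).
#' @slot lengthRange Barcode length range in nt: c(450, 800) emulates long
#'   markers (full ITS/LSU), c(150, 300) short ones (ITS1/ITS2).
#' @slot ladder Named numeric: expected substitution fraction introduced at
#'   each rank split (defaults species 0.005, genus 0.05, family 0.12,
#'   order 0.18, class 0.25; strictly increasing with rank height).
#' @slot strainNoise Substitution fraction among strains of a species
#'   (default 0.002).
#' @slot indelFrac Fraction of edits realized as single-base indels
#'   (default 0.1).
#' @slot plantedComplexes Number of species pairs forced to identical
#'   barcodes (default 0).
#' @slot unannotatedFraction Fraction of records with a blanked family
#'   (default 0).
#' @slot seed Master seed; all stages derive from it, so generated datasets
#'   are byte-reproducible.
#' @export
setClass("SimulationSpec",
         representation(counts = "list", lengthRange = "numeric",
                        ladder = "numeric", strainNoise = "numeric",
                        indelFrac = "numeric", plantedComplexes = "integer",
                        unannotatedFraction = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  need <- c("phyla", "classes", "orders", "families", "genera", "species", "strains")
  if (!all(need %in% names(object@counts)))
    return(paste("counts must name:", paste(need, collapse = ", ")))
  lad <- object@ladder[c("species", "genus", "family", "order", "class")]
  if (anyNA(lad)) return("ladder must name species, genus, family, order, class")
  if (any(diff(lad) <= 0))
    return("divergence ladder must be strictly increasing with rank height")
  fr <- c(object@ladder, object@strainNoise, object@indelFrac,
          object@unannotatedFraction)
  if (any(fr < 0 | fr > 1)) return("all fractions must be in [0,1]")
  if (length(object@lengthRange) != 2 || object@lengthRange[1] > object@lengthRange[2])
    return("lengthRange must be c(min, max)")
  TRUE
})

#' Construct a simulation spec
#'
#' @param counts,lengthRange,ladder,strainNoise,indelFrac,plantedComplexes,unannotatedFraction,seed
#'   See [SimulationSpec-class].
#' @return A [SimulationSpec-class].
#' @export
#' @examples
#' simulationSpec(counts = list(phyla = 2, classes = 2, orders = 2,
#'                              families = 2, genera = 2, species = 3,
#'                              strains = 2), seed = 7)
simulationSpec <- function(counts = list(phyla = 2, classes = 2, orders = 1,
                                         families = 2, genera = 2, species = 3,
                                         strains = 2),
                           lengthRange = c(450, 800),
                           ladder = c(species = 0.005, genus = 0.05,
                                      family = 0.12, order = 0.18, class = 0.25),
                           strainNoise = 0.002, indelFrac = 0.1,
                           plantedComplexes = 0L, unannotatedFraction = 0,
                           seed = 1L) {
  new("SimulationSpec", counts = counts, lengthRange = lengthRange,
      ladder = ladder, strainNoise = strainNoise, indelFrac = indelFrac,
      plantedComplexes = as.integer(plantedComplexes),
      unannotatedFraction = unannotatedFraction, seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec: counts",
      paste(names(object@counts), vapply(object@counts, function(x)
        paste(x, collapse = "-"), ""), sep = "=", collapse = " "), "\n")
  cat("  lengths", paste(object@lengthRange, collapse = "-"),
      "nt; ladder", paste(names(object@ladder), object@ladder, sep = "=",
                          collapse = " "), "\n")
  cat(sprintf("  strainNoise=%g indelFrac=%g plantedComplexes=%d unannotated=%g seed=%d\n",
              object@strainNoise, object@indelFrac, object@plantedComplexes,
              object@unannotatedFraction, object@seed))
})

## Draw a children count: fixed integer, or long-tailed draw from a range
## (geometric tail favouring the low end, occasionally hitting the high end,
## which yields the dominant-taxon imbalance).
.sample_count <- function(x) {
  if (length(x) == 1) return(as.integer(x))
  lo <- as.integer(x[1]); hi <- as.integer(x[2])
  min(lo + stats::rgeom(1, prob = 0.35), hi)
}

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

## Mutate a base vector: substitutions with transition:transversion 2:1,
## a fraction of the edits realized as single-base indels. The edit count is
## the stochastically rounded expectation L * rate (floor plus a Bernoulli
## remainder) rather than a binomial draw: every split then introduces at
## least floor(L * rate) edits, which guarantees the divergence ladder is
## realized and keeps the planted identity gap well-posed.
.mutate <- function(v, rate, indelFrac) {
  L <- length(v)
  mu <- L * rate
  n_edit <- min(L, floor(mu) + stats::rbinom(1, 1, mu - floor(mu)))
  if (n_edit == 0) return(v)
  n_indel <- stats::rbinom(1, n_edit, indelFrac)
  n_sub <- n_edit - n_indel
  if (n_sub > 0) {
    pos <- sample.int(length(v), min(n_sub, length(v)))
    for (p in pos) {
      b <- v[p]
      if (stats::runif(1) < 2 / 3) {
        v[p] <- .TRANSITION[[b]]
      } else {
        v[p] <- sample(setdiff(.BASES, c(b, .TRANSITION[[b]])), 1)
      }
    }
  }
  if (n_indel > 0) {
    for (k in seq_len(n_indel)) {
      if (stats::runif(1) < 0.5 && length(v) > 1) {
        v <- v[-sample.int(length(v), 1)]           # deletion
      } else {
        p <- sample.int(length(v) + 1L, 1) - 1L      # insertion after p
        v <- append(v, sample(.BASES, 1), after = p)
      }
    }
  }
  v
}

#' Simulate a barcode dataset with planted ground truth
#'
#' Generates one random ancestral sequence per phylum and descends the
#' taxonomy recursively; each split at a rank introduces the ladder's
#' substitution fraction (plus indels), so sequence divergence increases with
#' rank height: strains of a species are near-identical, congeneric species
#' differ by roughly twice the species rate, and so on. Planted complexes
#' copy one species' sequences verbatim onto a congeneric species, making the
#' pair indistinguishable at 100% similarity. A fraction of records can have
#' their family annotation blanked. Fully reproducible from the spec's seed.
#'
#' @param spec A [SimulationSpec-class].
#' @return A list: \code{records} ([BarcodeSet-class]), \code{taxonomy}
#'   ([TaxonomyTable-class]), \code{truth} (list with \code{complexes} as in
#'   [indistinguishableComplexes()] and the \code{spec}).
#' @export
simulateDataset <- function(spec) {
  validObject(spec)
  .with_seed(spec@seed, {
    cnt <- spec@counts
    recs <- list()   # per strain: list(id, ranks..., seq)
    counters <- new.env()
    nm <- function(prefix) {
      i <- get0(prefix, envir = counters, inherits = FALSE, ifnotfound = 0L) + 1L
      assign(prefix, i, envir = counters)
      sprintf("%s%03d", prefix, i)
    }
    sid <- 0L
    species_seqs <- list()  # species name -> list of strain indices in recs
    for (p in seq_len(.sample_count(cnt$phyla))) {
      phy <- nm("Phylum")
      len <- sample(seq(spec@lengthRange[1], spec@lengthRange[2]), 1)
      phy_seq <- sample(.BASES, len, replace = TRUE)
      for (cl in seq_len(.sample_count(cnt$classes))) {
        cla <- nm("Class")
        cla_seq <- .mutate(phy_seq, spec@ladder[["class"]], spec@indelFrac)
        for (o in seq_len(.sample_count(cnt$orders))) {
          ord <- nm("Order")
          ord_seq <- .mutate(cla_seq, spec@ladder[["order"]], spec@indelFrac)
          for (f in seq_len(.sample_count(cnt$families))) {
            fam <- nm("Family")
            fam_seq <- .mutate(ord_seq, spec@ladder[["family"]], spec@indelFrac)
            for (g in seq_len(.sample_count(cnt$genera))) {
              gen <- nm("Genus")
              gen_seq <- .mutate(fam_seq, spec@ladder[["genus"]], spec@indelFrac)
              for (s in seq_len(.sample_count(cnt$species))) {
                sp <- paste(gen, nm("sp"))
                sp_seq <- .mutate(gen_seq, spec@ladder[["species"]], spec@indelFrac)
                idx <- integer(0)
                for (st in seq_len(.sample_count(cnt$strains))) {
                  sid <- sid + 1L
                  strain_seq <- .mutate(sp_seq, spec@strainNoise, spec@indelFrac)
                  recs[[sid]] <- list(id = sprintf("sq%05d", sid),
                                      strain = sprintf("st%05d", sid),
                                      species = sp, genus = gen, family = fam,
                                      order = ord, class = cla, phylum = phy,
                                      seq = strain_seq)
                  idx <- c(idx, sid)
                }
                species_seqs[[sp]] <- idx
              }
            }
          }
        }
      }
    }

    ## plant indistinguishable complexes: copy species A's sequences onto a
    ## congeneric species B, verbatim
    complexes <- list()
    if (spec@plantedComplexes > 0) {
      sp_names <- names(species_seqs)
      genus_of <- vapply(sp_names, function(s) recs[[species_seqs[[s]][1]]]$genus, "")
      used <- character(0)
      genera_pool <- unique(genus_of[duplicated(genus_of) | duplicated(genus_of, fromLast = TRUE)])
      genera_pool <- sample(genera_pool)
      for (gen in genera_pool) {
        if (length(complexes) >= spec@plantedComplexes) break
        cand <- setdiff(sp_names[genus_of == gen], used)
        if (length(cand) < 2) next
        pair <- sort(sample(cand, 2))
        a_idx <- species_seqs[[pair[1]]]
        b_idx <- species_seqs[[pair[2]]]
        for (k in seq_along(b_idx))
          recs[[b_idx[k]]]$seq <- recs[[a_idx[((k - 1) %% length(a_idx)) + 1]]]$seq
        used <- c(used, pair)
        complexes[[length(complexes) + 1L]] <-
          list(members = pair, representative = pair[1])
      }
      if (length(complexes) < spec@plantedComplexes)
        warning("could only plant ", length(complexes), " of ",
                spec@plantedComplexes, " complexes (not enough congeneric species)")
      ## canonical order, matching indistinguishableComplexes()
      complexes <- complexes[order(vapply(complexes, `[[`, "", "representative"))]
    }

    tb <- data.frame(id = vapply(recs, `[[`, "", "id"),
                     strain = vapply(recs, `[[`, "", "strain"),
                     species = vapply(recs, `[[`, "", "species"),
                     genus = vapply(recs, `[[`, "", "genus"),
                     family = vapply(recs, `[[`, "", "family"),
                     order = vapply(recs, `[[`, "", "order"),
                     class = vapply(recs, `[[`, "", "class"),
                     phylum = vapply(recs, `[[`, "", "phylum"),
                     stringsAsFactors = FALSE)
    if (spec@unannotatedFraction > 0) {
      nblank <- round(spec@unannotatedFraction * nrow(tb))
      if (nblank > 0)
        tb$family[sample.int(nrow(tb), nblank)] <- ""
    }
    seqs <- DNAStringSet(vapply(recs, function(r) paste(r$seq, collapse = ""), ""))
    names(seqs) <- tb$id
    list(records = new("BarcodeSet", seqs, marker = "other"),
         taxonomy = taxonomyTable(tb),
         truth = list(complexes = complexes, spec = spec))
  })
}

#' Simulate query reads from a barcode dataset
#'
#' Each query is a contiguous subsequence of a randomly chosen strain of its
#' species, with substitutions applied at \code{errorRate} (sequencing-error
#' model; no indels). The origin of every query is recorded.
#'
#' @param records A [BarcodeSet-class] from [simulateDataset()].
#' @param tax The matching [TaxonomyTable-class].
#' @param abundance Named integer vector: reads per species.
#' @param errorRate Per-base substitution probability.
#' @param lengthRange Query length range; requests longer than the source are
#'   clamped with a warning.
#' @param seed Seed for this batch.
#' @return A list: \code{queries} ([BarcodeSet-class]) and \code{origin}
#'   (data.frame: query, source, species).
#' @export
simulateQueries <- function(records, tax, abundance, errorRate = 0,
                            lengthRange = c(150, 300), seed = 1L) {
  tb <- taxTable(tax)
  miss <- setdiff(names(abundance)[abundance > 0], tb$species)
  if (length(miss) > 0)
    stop("species not in taxonomy: ", paste(utils::head(miss, 3), collapse = ", "))
  .with_seed(seed, {
    qseqs <- character(0); qids <- character(0)
    src <- character(0); sp_out <- character(0)
    qn <- 0L
    clamped <- FALSE
    for (sp in names(abundance)) {
      k <- abundance[[sp]]
      if (k <= 0) next
      pool <- tb$id[tb$species == sp]
      pool <- intersect(pool, names(records))
      for (i in seq_len(k)) {
        source_id <- if (length(pool) == 1) pool else sample(pool, 1)
        v <- strsplit(as.character(records[[source_id]]), "")[[1]]
        want <- sample(seq(lengthRange[1], lengthRange[2]), 1)
        if (want > length(v)) { want <- length(v); clamped <- TRUE }
        start <- sample.int(length(v) - want + 1L, 1)
        piece <- v[start:(start + want - 1L)]
        if (errorRate > 0) piece <- .mutate(piece, errorRate, 0)
        qn <- qn + 1L
        qids <- c(qids, sprintf("q%05d", qn))
        qseqs <- c(qseqs, paste(piece, collapse = ""))
        src <- c(src, source_id)
        sp_out <- c(sp_out, sp)
      }
    }
    if (clamped) warning("some requested query lengths exceeded the source; clamped")
    qs <- DNAStringSet(qseqs)
    names(qs) <- qids
    list(queries = new("BarcodeSet", qs, marker = "other"),
         origin = data.frame(query = qids, source = src, species = sp_out,
                             stringsAsFactors = FALSE))
  })
}

#' Realized identity gap of a partition
#'
#' Measures, on a computed similarity matrix, the maximum between-group score
#' and the minimum within-group score of a ground-truth partition. When the
#' two bound an open interval (max between < min within), any threshold
#' strictly inside separates the groups perfectly, which is what the
#' cutoff-recovery tests exploit. Between-group pairs absent from the sparse
#' matrix are bounded by the floor; within-group absent pairs take the floor.
#'
#' @param mat A [SimilarityMatrix-class].
#' @param truth A [RankPartition-class].
#' @return Named numeric: \code{max_between}, \code{min_within}.
#' @export
identityGap <- function(mat, truth) {
  groups <- partitionGroups(truth)
  grp_of <- rep(names(groups), lengths(groups))
  names(grp_of) <- unlist(groups, use.names = FALSE)
  p <- simPairs(mat)
  p <- p[p$id1 %in% names(grp_of) & p$id2 %in% names(grp_of), , drop = FALSE]
  between <- grp_of[p$id1] != grp_of[p$id2]
  max_between <- if (any(between)) max(p$score[between]) else scoreFloor(mat)
  min_within <- Inf
  for (g in groups) {
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    vals <- simScore(mat, cmb[1, ], cmb[2, ], default = scoreFloor(mat))
    min_within <- min(min_within, vals)
  }
  c(max_between = max_between, min_within = min_within)
}
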