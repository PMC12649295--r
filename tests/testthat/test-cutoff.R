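## Planted two-species fixture: between-pair maximum 0.900, within-pair
## minimum 0.990. Any threshold in (0.900, 0.990] separates the species.
planted_two <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  tax <- taxonomyTable(data.frame(id = ids,
                                  species = c("SA", "SA", "SB", "SB"),
                                  genus = "G1", stringsAsFactors = FALSE))
  mat <- msim(ids, edge_df(c("a1", "a2", "0.990"), c("b1", "b2", "0.995"),
                           c("a1", "b1", "0.900"), c("a1", "b2", "0.850"),
                           c("a2", "b1", "0.880"), c("a2", "b2", "0.870")))
  list(mat = mat, tax = tax,
       truth = partitionAtRank(tax, ids, "species"))
}

test_that("sweepPredict recovers a planted cutoff inside the identity gap", {
  fx <- planted_two()
  res <- sweepPredict(fx$mat, fx$truth, sweepConfig(start = 0.7, step = 0.001))
  expect_equal(res$entry$cutoff, 0.901)
  expect_equal(res$entry$confidence, 1.0)
  expect_equal(res$entry$seq_no, 4L)
  expect_equal(res$entry$group_no, 2L)
  ## grid coarsening: step 0.01 moves the cutoff to the next grid point
  res2 <- sweepPredict(fx$mat, fx$truth, sweepConfig(start = 0.7, step = 0.01))
  expect_equal(res2$entry$cutoff, 0.91)
  ## curve spans the grid and attains its maximum at the cutoff
  expect_equal(nrow(res$curve), 301)
  expect_equal(max(res$curve$f), res$entry$confidence)
})

test_that("all-singleton truth with no edges above start returns the start", {
  ids <- c("a", "b", "c")
  tax <- taxonomyTable(data.frame(id = ids, species = c("S1", "S2", "S3"),
                                  stringsAsFactors = FALSE))
  mat <- msim(ids, edge_df(c("a", "b", "0.60")))
  truth <- partitionAtRank(tax, ids, "species")
  res <- sweepPredict(mat, truth, sweepConfig(start = 0.7, step = 0.001))
  expect_equal(res$entry$cutoff, 0.7)
  expect_equal(res$entry$confidence, 1.0)
})

test_that("degenerate single-group truth is rejected", {
  ids <- c("a", "b")
  tax <- taxonomyTable(data.frame(id = ids, species = "S1",
                                  stringsAsFactors = FALSE))
  mat <- msim(ids, edge_df(c("a", "b", "0.99")))
  expect_error(sweepPredict(mat, partitionAtRank(tax, ids, "species")),
               "degenerate")
})

test_that("predicted confidence is self-consistent with an independent re-clustering", {
  set.seed(67)
  for (rep in 1:5) {
    mat <- random_msim(12, density = 0.4)
    ids <- simIds(mat)
    tax <- taxonomyTable(data.frame(
      id = ids, species = sample(c("S1", "S2", "S3"), 12, replace = TRUE),
      stringsAsFactors = FALSE))
    truth <- partitionAtRank(tax, ids, "species")
    if (length(partitionGroups(truth)) < 2) next
    res <- sweepPredict(mat, truth, sweepConfig(start = 0.5, step = 0.01))
    cl <- clusterAt(mat, res$entry$cutoff, ids = coveredIds(truth))
    expect_equal(clusteringFMeasure(cl, truth)$value, res$entry$confidence)
  }
})

## taxonomy with three genera: GBig (40 seqs, 6 species, balanced),
## GSmall (10 seqs), GDom (40 seqs, one species at 80%)
local_fixture <- function() {
  mk <- function(genus, species_sizes) {
    sp <- rep(sprintf("%s_sp%d", genus, seq_along(species_sizes)), species_sizes)
    data.frame(id = sprintf("%s_%02d", genus, seq_along(sp)), species = sp,
               genus = genus, family = "F1", order = "O1", class = "C1",
               phylum = "P1", stringsAsFactors = FALSE)
  }
  df <- rbind(mk("GBig", c(7, 7, 7, 7, 6, 6)),
              mk("GSmall", c(5, 5)),
              mk("GDom", c(32, 2, 2, 2, 1, 1)))
  tax <- taxonomyTable(df)
  ## similarity: within species 0.99, within genus 0.9, across genera 0.6
  ids <- df$id
  cmb <- utils::combn(ids, 2)
  sp <- df$species[match(cmb[1, ], df$id)] == df$species[match(cmb[2, ], df$id)]
  gn <- df$genus[match(cmb[1, ], df$id)] == df$genus[match(cmb[2, ], df$id)]
  pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                      score = ifelse(sp, 0.99, ifelse(gn, 0.9, 0.6)),
                      stringsAsFactors = FALSE)
  list(tax = tax, mat = msim(ids, pairs))
}

test_that("local prediction applies the group-eligibility filter", {
  fx <- local_fixture()
  expect_message(
    expect_message(
      tab <- predictLocal(fx$mat, fx$tax, "species", "genus",
                          eligibilityFilter(), sweepConfig(start = 0.7)),
      "GSmall.*sequences"),
    "GDom.*dominated")
  e <- cutoffEntries(tab)
  expect_identical(e$taxon, "GBig")
  ## restriction consistency: the local entry equals a direct sweep on the
  ## genus' ids alone
  gids <- taxTable(fx$tax)$id[taxTable(fx$tax)$genus == "GBig"]
  direct <- sweepPredict(fx$mat, partitionAtRank(fx$tax, gids, "species"),
                         sweepConfig(start = 0.7))
  expect_equal(e$cutoff, direct$entry$cutoff)
  expect_equal(e$confidence, direct$entry$confidence)
  expect_equal(e$seq_no, direct$entry$seq_no)
})

test_that("eligibility bounds are exclusive/inclusive as documented", {
  fx <- local_fixture()
  ## minSeq is exclusive ("more than 30"): a 40-seq genus passes minSeq 39
  ## but fails minSeq 40
  suppressMessages({
    t39 <- predictLocal(fx$mat, fx$tax, "species", "genus",
                        eligibilityFilter(minSeq = 39), sweepConfig(start = 0.7))
    t40 <- predictLocal(fx$mat, fx$tax, "species", "genus",
                        eligibilityFilter(minSeq = 40), sweepConfig(start = 0.7))
    ## minGroups is inclusive ("at least 5"): GBig has 6 species
    t6 <- predictLocal(fx$mat, fx$tax, "species", "genus",
                       eligibilityFilter(minGroups = 6), sweepConfig(start = 0.7))
    t7 <- predictLocal(fx$mat, fx$tax, "species", "genus",
                       eligibilityFilter(minGroups = 7), sweepConfig(start = 0.7))
  })
  expect_equal(nrow(cutoffEntries(t39)), 1)
  expect_equal(nrow(cutoffEntries(t40)), 0)
  expect_equal(nrow(cutoffEntries(t6)), 1)
  expect_equal(nrow(cutoffEntries(t7)), 0)
})

test_that("predictLocal validates the rank pair", {
  fx <- local_fixture()
  expect_error(predictLocal(fx$mat, fx$tax, "genus", "species"),
               "strictly above")
  expect_error(predictLocal(fx$mat, fx$tax, "species", "kingdom"),
               "unknown rank")
})

test_that("bestCutoff walks the ancestor chain by confidence", {
  tax <- taxonomyTable(data.frame(
    id = c("a", "b"), species = c("S1", "S2"), genus = "G1", family = "F1",
    order = "O1", class = "C1", phylum = "P1", stringsAsFactors = FALSE))
  mk_entry <- function(taxon, scope, cutoff, conf)
    data.frame(level_rank = "species", scope_rank = scope, taxon = taxon,
               cutoff = cutoff, confidence = conf, seq_no = 10L, group_no = 5L,
               fallback_from = NA_character_, stringsAsFactors = FALSE)
  tab <- new("CutoffTable",
             entries = rbind(mk_entry("G1", "genus", 0.99, 0.50),
                             mk_entry("F1", "family", 0.95, 0.90),
                             mk_entry("All", "all", 0.97, 0.80)),
             metadata = list())
  ## low-confidence own entry loses to the family ancestor
  got <- bestCutoff("G1", "species", tab, tax)
  expect_equal(got$taxon, "F1")
  expect_equal(got$fallback_from, "F1")
  expect_equal(got$cutoff, 0.95)
  ## a high-confidence own entry wins
  tab2 <- new("CutoffTable",
              entries = rbind(mk_entry("G1", "genus", 0.99, 0.99),
                              mk_entry("F1", "family", 0.95, 0.90)),
              metadata = list())
  got2 <- bestCutoff("G1", "species", tab2, tax)
  expect_equal(got2$taxon, "G1")
  expect_true(is.na(got2$fallback_from))
  ## absent taxon falls back to the global entry
  tab3 <- new("CutoffTable", entries = mk_entry("All", "all", 0.97, 0.80),
              metadata = list())
  got3 <- bestCutoff("G9", "species", tab3, tax)
  expect_equal(got3$taxon, "All")
  ## confidence ties resolve to the most specific entry
  tab4 <- new("CutoffTable",
              entries = rbind(mk_entry("G1", "genus", 0.99, 0.90),
                              mk_entry("F1", "family", 0.95, 0.90)),
              metadata = list())
  expect_equal(bestCutoff("G1", "species", tab4, tax)$taxon, "G1")
  ## nothing on the chain: error
  tab5 <- new("CutoffTable",
              entries = mk_entry("Gx", "genus", 0.9, 0.9), metadata = list())
  expect_error(bestCutoff("G1", "species", tab5, tax), "no cutoff entry")
})

test_that("cutoff tables round-trip through JSON exactly", {
  fx <- local_fixture()
  suppressMessages(
    tab <- predictLocal(fx$mat, fx$tax, "species", "genus",
                        eligibilityFilter(), sweepConfig(start = 0.7)))
  glob <- predictGlobal(fx$mat, fx$tax, "species", sweepConfig(start = 0.7))$table
  both <- combineCutoffs(glob, tab)
  tf <- withr::local_tempfile(fileext = ".json")
  writeCutoffs(both, tf)
  back <- readCutoffs(tf)
  e1 <- cutoffEntries(both); e2 <- cutoffEntries(back)
  e2 <- e2[match(paste(e1$level_rank, e1$taxon), paste(e2$level_rank, e2$taxon)), ]
  rownames(e2) <- NULL
  expect_equal(e1$cutoff, e2$cutoff)
  expect_equal(e1$confidence, e2$confidence)
  expect_equal(e1$seq_no, e2$seq_no)
  expect_equal(e1$group_no, e2$group_no)
  expect_identical(e1$scope_rank, e2$scope_rank)
})

test_that("combineCutoffs rejects duplicate keys", {
  fx <- local_fixture()
  glob <- predictGlobal(fx$mat, fx$tax, "species", sweepConfig(start = 0.7))$table
  expect_error(combineCutoffs(glob, glob), "duplicate")
})
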