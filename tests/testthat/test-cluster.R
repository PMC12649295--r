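## 4-node fixture from the threshold-clustering contract:
## s(a,b)=0.99, s(b,c)=0.98, s(a,c)=0.90, every pair with d <= 0.8
four_node <- function() {
  msim(c("a", "b", "c", "d"),
       edge_df(c("a", "b", "0.99"), c("b", "c", "0.98"), c("a", "c", "0.90"),
               c("a", "d", "0.80"), c("b", "d", "0.79"), c("c", "d", "0.78")))
}

test_that("threshold clustering yields connected components of the >= t graph", {
  mat <- four_node()
  c1 <- clusterAt(mat, 0.985)
  expect_identical(clusters(c1), list(a = c("a", "b"), c = "c", d = "d"))
  ## single-linkage transitivity via b at t = 0.97
  c2 <- clusterAt(mat, 0.97)
  expect_identical(clusters(c2), list(a = c("a", "b", "c"), d = "d"))
  ## t = 1.0 with no identical pairs: all singletons
  c3 <- clusterAt(mat, 1.0)
  expect_length(clusters(c3), 4)
  expect_true(all(lengths(clusters(c3)) == 1))
})

test_that("clusterAt validates its inputs", {
  mat <- four_node()
  expect_error(clusterAt(mat, 0.9, ids = character(0)), "empty")
  expect_error(clusterAt(mat, 0.9, ids = c("a", "zz")), "not in matrix")
  matf <- msim(c("a", "b"), edge_df(c("a", "b", "0.9")), floor = 0.5)
  expect_warning(clusterAt(matf, 0.3), "below the matrix floor")
})

test_that("components agree with an igraph oracle on random matrices", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:20) {
    mat <- random_msim(sample(5:15, 1), density = runif(1, 0.1, 0.6))
    t <- runif(1)
    got <- clusters(clusterAt(mat, t))
    want <- components_oracle(mat, simIds(mat), t)
    norm <- function(cl) unname(lapply(cl, sort))[order(vapply(cl, min, ""))]
    expect_identical(norm(got), norm(want))
  }
})

test_that("cluster count is non-increasing as the threshold decreases", {
  set.seed(17)
  mat <- random_msim(20, density = 0.3)
  counts <- vapply(seq(1, 0, by = -0.05),
                   function(t) length(clusters(clusterAt(mat, t))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering F-measure matches its contract on worked examples", {
  ## perfect match
  tax <- tiny_tax()
  truth <- partitionAtRank(tax, taxIds(tax), "species")
  pg <- partitionGroups(truth)
  names(pg) <- vapply(pg, min, "")
  perfect <- new("Clustering", threshold = 0.99, clusters = pg)
  expect_equal(clusteringFMeasure(perfect, truth)$value, 1.0)

  ## classes {a,b,c},{d,e}; clusters {a,b},{c,d,e} -> 0.8
  t2 <- taxonomyTable(data.frame(id = c("a", "b", "c", "d", "e"),
                                 species = c("X", "X", "X", "Y", "Y"),
                                 stringsAsFactors = FALSE))
  truth2 <- partitionAtRank(t2, c("a", "b", "c", "d", "e"), "species")
  cl2 <- new("Clustering", threshold = 0.9,
             clusters = list(a = c("a", "b"), c = c("c", "d", "e")))
  rep2 <- clusteringFMeasure(cl2, truth2)
  expect_equal(rep2$value, 0.8)
  expect_equal(rep2$per_class$best_F, c(0.8, 0.8))

  ## one big cluster against n singleton classes -> 2/(n+1)
  n <- 7
  t3 <- taxonomyTable(data.frame(id = letters[1:n], species = LETTERS[1:n],
                                 stringsAsFactors = FALSE))
  truth3 <- partitionAtRank(t3, letters[1:n], "species")
  cl3 <- new("Clustering", threshold = 0.5,
             clusters = list(a = letters[1:n]))
  expect_equal(clusteringFMeasure(cl3, truth3)$value, 2 / (n + 1))
})

test_that("clustering F-measure equals the exhaustive oracle on random instances", {
  set.seed(53)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    ids <- sprintf("i%02d", 1:n)
    cls <- split(ids, sample(1:sample(2:4, 1), n, replace = TRUE))
    clu <- split(ids, sample(1:sample(2:5, 1), n, replace = TRUE))
    names(clu) <- vapply(clu, min, "")
    lab <- character(n); names(lab) <- unlist(cls)
    lab[unlist(cls)] <- rep(paste0("S", seq_along(cls)), lengths(cls))
    tax <- taxonomyTable(data.frame(id = ids, species = lab[ids],
                                    stringsAsFactors = FALSE))
    truth <- partitionAtRank(tax, ids, "species")
    got <- clusteringFMeasure(new("Clustering", threshold = 0.9, clusters = clu),
                              truth)$value
    want <- fmeasure_oracle(clu, partitionGroups(truth))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("F-measure errors on empty truth and unclustered covered ids", {
  truth <- partitionAtRank(tiny_tax(), sprintf("t%d", 1:8), "species")
  cl <- new("Clustering", threshold = 0.9, clusters = list(t1 = c("t1", "t2")))
  expect_error(clusteringFMeasure(cl, truth), "not clustered")
})

test_that("indistinguishable complexes form by cross-species 100% co-clustering", {
  tax <- taxonomyTable(data.frame(
    id = c("a", "b", "c", "d"),
    species = c("S1", "S2", "S3", "S4"), stringsAsFactors = FALSE))
  sp <- partitionAtRank(tax, c("a", "b", "c", "d"), "species")
  ## a~b at 1.0: one complex {S1,S2}
  m1 <- msim(c("a", "b", "c", "d"), edge_df(c("a", "b", "1.0")))
  cx1 <- indistinguishableComplexes(m1, sp)
  expect_length(cx1, 1)
  expect_identical(cx1[[1]]$members, c("S1", "S2"))
  expect_identical(cx1[[1]]$representative, "S1")
  ## transitive closure: a~b, b~c -> {S1,S2,S3}
  m2 <- msim(c("a", "b", "c", "d"),
             edge_df(c("a", "b", "1.0"), c("b", "c", "1.0")))
  cx2 <- indistinguishableComplexes(m2, sp)
  expect_length(cx2, 1)
  expect_identical(cx2[[1]]$members, c("S1", "S2", "S3"))
  ## no pair at 1.0: empty
  m3 <- msim(c("a", "b", "c", "d"), edge_df(c("a", "b", "0.999")))
  expect_length(indistinguishableComplexes(m3, sp), 0)
})

test_that("within-species co-clustering alone never creates a complex", {
  tax <- taxonomyTable(data.frame(id = c("a", "b", "c"),
                                  species = c("S1", "S1", "S2"),
                                  stringsAsFactors = FALSE))
  sp <- partitionAtRank(tax, c("a", "b", "c"), "species")
  m <- msim(c("a", "b", "c"), edge_df(c("a", "b", "1.0")))
  expect_length(indistinguishableComplexes(m, sp), 0)
})

test_that("complexes sharing a species are unioned", {
  ## S2's sequences split across two 100% clusters, one shared with S1, the
  ## other with S3: a single complex {S1,S2,S3}
  tax <- taxonomyTable(data.frame(
    id = c("a", "b1", "b2", "c"),
    species = c("S1", "S2", "S2", "S3"), stringsAsFactors = FALSE))
  sp <- partitionAtRank(tax, c("a", "b1", "b2", "c"), "species")
  m <- msim(c("a", "b1", "b2", "c"),
            edge_df(c("a", "b1", "1.0"), c("b2", "c", "1.0")))
  cx <- indistinguishableComplexes(m, sp)
  expect_length(cx, 1)
  expect_identical(cx[[1]]$members, c("S1", "S2", "S3"))
})

test_that("deduplication retains one representative species per complex", {
  tax <- taxonomyTable(data.frame(
    id = sprintf("x%d", 1:7),
    species = c("S1", "S1", "S1", "S2", "S2", "S3", "S4"),
    stringsAsFactors = FALSE))
  recs <- BarcodeSet(stats::setNames(rep("ACGTACGT", 7), sprintf("x%d", 1:7)))
  cx <- list(list(members = c("S1", "S2"), representative = "S1"))
  out <- deduplicateSpecies(recs, tax, cx)
  expect_setequal(names(out), c("x1", "x2", "x3", "x6", "x7"))
  ## empty complexes: identity
  expect_identical(names(deduplicateSpecies(recs, tax, list())), names(recs))
  ## two disjoint 2-species complexes reduce the species count by exactly 2
  cx2 <- list(list(members = c("S1", "S2"), representative = "S1"),
              list(members = c("S3", "S4"), representative = "S3"))
  out2 <- deduplicateSpecies(recs, tax, cx2)
  tb <- taxTable(tax)
  left <- unique(tb$species[tb$id %in% names(out2)])
  expect_equal(length(unique(tb$species)) - length(left), 2)
  ## representative override must stay inside the complex
  expect_error(deduplicateSpecies(recs, tax, cx, representatives = c(S1 = "S9")),
               "not a member")
})
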