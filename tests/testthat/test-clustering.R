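test_that("poolAssemblies namespaces ids and preserves sources", {
  set.seed(31)
  assemblies <- lapply(seq(19, 63, 2), function(k) {
    Assembly(paste0("k", k), seqsOfLengths(rep(20, 10)))
  })
  pooled <- poolAssemblies(assemblies)
  expect_identical(length(pooled), 230L)
  expect_identical(anyDuplicated(contigIds(pooled)), 0L)
  expect_identical(contigIds(pooled)[1:2], c("k19|c1", "k19|c2"))
  # assemblies sharing an original id keep both copies
  p2 <- poolAssemblies(list(Assembly("k19", c(c1 = "ACGT")),
                            Assembly("k21", c(c1 = "TTTT"))))
  expect_setequal(contigIds(p2), c("k19|c1", "k21|c1"))
  # single assembly: identity up to renaming
  p1 <- poolAssemblies(list(Assembly("k19", c(c1 = "ACGT"))))
  expect_identical(as.character(contigs(p1)), c(`k19|c1` = "ACGT"))
})

test_that("pairIdentity handles identity, containment and substitutions", {
  expect_identical(pairIdentity("ACGTACGT", "ACGTACGT"), 1)
  expect_identical(pairIdentity("CGTA", "ACGTACGT"), 1)
  # reverse complement containment: revcomp("AAAC") = "GTTT"
  expect_identical(pairIdentity("AAAC", "GGTTTGG"), 1)
  expect_lt(pairIdentity("AAAC", "GGTTTGG", ClusterParams(bothStrands = FALSE)), 1)
  # 100-base sequence vs a copy with 5 substitutions
  set.seed(41)
  a <- randomSeq(100)
  ch <- strsplit(a, "")[[1]]
  for (p in sample.int(100, 5)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  expect_identical(pairIdentity(a, paste(ch, collapse = "")), 0.95)
})

test_that("N never counts as a match", {
  expect_identical(pairIdentity("ACNT", "ACGT"), 0.75)
  expect_identical(pairIdentity("ACNT", "ACNT"), 0.75)
})

test_that("pairIdentity agrees with the exhaustive oracle on random pairs", {
  set.seed(53)
  for (i in 1:60) {
    a <- randomSeq(sample(8:60, 1))
    b <- randomSeq(sample(8:90, 1))
    if (runif(1) < 0.3) { # occasionally inject N runs
      substr(a, 2, 4) <- "NNN"
    }
    for (bs in c(TRUE, FALSE)) {
      expect_equal(pairIdentity(a, b, ClusterParams(bothStrands = bs)),
                   oracleIdentity(a, b, bothStrands = bs))
    }
  }
})

test_that("clustering collapses duplicates and substrings at c = 1", {
  pooled <- Assembly("pooled", c(a = "ACGTACGT", b = "ACGTACGT", d = "CGTA"))
  res <- clusterContigs(pooled, ClusterParams(1.0, wordSize = 4L))
  expect_identical(contigIds(representatives(res)), "a")
  expect_identical(nrow(clusterMembers(res)), 2L)
  expect_true(all(clusterMembers(res)$identity == 1))
})

test_that("c = 1 never merges sequences differing at a non-N position", {
  set.seed(67)
  for (i in 1:30) {
    a <- randomSeq(sample(20:80, 1))
    ch <- strsplit(a, "")[[1]]
    p <- sample.int(length(ch), 1)
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    pooled <- Assembly("pooled", c(x = a, y = paste(ch, collapse = "")))
    res <- clusterContigs(pooled, ClusterParams(1.0))
    expect_identical(length(representatives(res)), 2L)
  }
})

test_that("greedy clustering matches the brute-force oracle", {
  set.seed(71)
  for (i in 1:40) {
    pool <- randomPool(sample(4:10, 1), c(20, 150))
    c0 <- sample(c(0.9, 0.95, 1.0), 1)
    res <- clusterContigs(Assembly("pooled", pool), ClusterParams(c0))
    expect_identical(sort(contigIds(representatives(res))),
                     oracleCluster(pool, c0)$repIds)
  }
})

test_that("clustering is independent of input order", {
  set.seed(83)
  pool <- randomPool(8, c(20, 120))
  r1 <- clusterContigs(Assembly("pooled", pool), ClusterParams(0.95))
  r2 <- clusterContigs(Assembly("pooled", pool[sample(length(pool))]), ClusterParams(0.95))
  expect_identical(sort(contigIds(representatives(r1))),
                   sort(contigIds(representatives(r2))))
  m1 <- clusterMembers(r1)
  m2 <- clusterMembers(r2)
  expect_identical(m1[order(m1$member_id), ], m2[order(m2$member_id), ])
})

test_that("representative count is non-increasing as c decreases", {
  set.seed(89)
  pool <- Assembly("pooled", randomPool(12, c(30, 200)))
  reps <- vapply(c(1.0, 0.95, 0.9), function(c0) {
    length(representatives(clusterContigs(pool, ClusterParams(c0))))
  }, 0L)
  expect_true(all(diff(reps) <= 0))
})

test_that("the word prefilter never changes the result", {
  set.seed(97)
  for (i in 1:12) {
    pool <- Assembly("pooled", randomPool(6, c(20, 150)))
    c0 <- sample(c(0.9, 0.95, 1.0), 1)
    for (ws in c(4L, 8L)) {
      p <- ClusterParams(c0, wordSize = ws)
      on <- clusterContigs(pool, p, usePrefilter = TRUE)
      off <- clusterContigs(pool, p, usePrefilter = FALSE)
      expect_identical(contigIds(representatives(on)),
                       contigIds(representatives(off)))
      expect_identical(clusterMembers(on), clusterMembers(off))
    }
  }
})

test_that("contigs shorter than the word size become their own representatives", {
  pooled <- Assembly("pooled", c(a = "ACGTACGTACGT", b = "ACG"))
  expect_message(res <- clusterContigs(pooled, ClusterParams(1.0)), "shorter than the word size")
  expect_setequal(contigIds(representatives(res)), c("a", "b"))
})

test_that("representatives are never shorter than their members", {
  set.seed(103)
  pool <- Assembly("pooled", randomPool(10, c(20, 200)))
  res <- clusterContigs(pool, ClusterParams(0.9))
  m <- clusterMembers(res)
  lens <- setNames(Biostrings::width(contigs(pool)), contigIds(pool))
  expect_true(all(lens[m$representative_id] >= lens[m$member_id]))
  # every input contig appears exactly once
  expect_identical(sort(c(contigIds(representatives(res)), m$member_id)),
                   sort(contigIds(pool)))
})

test_that("clustering can lose KOIs carried only by collapsed members", {
  # an unannotated longer contig absorbs an annotated shorter one
  pool <- poolAssemblies(list(
    Assembly("k19", c(c1 = "ACGTACGTACGTACGTACGT")),
    Assembly("k21", c(c9 = "ACGTACGTACGTACGTACGTAAAA"))
  ))
  tables <- list(k19 = AnnotationTable("k19", list(c1 = "K00007")),
                 k21 = AnnotationTable("k21"))
  res <- clusterContigs(pool, ClusterParams(1.0))
  caTab <- projectAnnotations(representatives(res), tables)
  expect_identical(contigIds(representatives(res)), "k21|c9")
  expect_identical(koiSet(caTab), character(0))  # K00007 lost by clustering
})
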