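test_that("koiSet is the union over contigs with duplicates collapsed", {
  tab <- AnnotationTable("k19", list(c1 = c("K00001", "K00002"), c2 = "K00002"))
  expect_identical(koiSet(tab), c("K00001", "K00002"))
  expect_identical(koiSet(AnnotationTable("k19")), character(0))
  many <- AnnotationTable("k19", setNames(rep(list("K00005"), 10), paste0("c", 1:10)))
  expect_identical(koiSet(many), "K00005")
})

test_that("pairwiseMissingMatrix computes ordered set differences", {
  m <- pairwiseMissingMatrix(list(k19 = c("K00001", "K00002"), k21 = "K00002"))
  expect_identical(m["k19", "k21"], 1)
  expect_identical(m["k21", "k19"], 0)
  expect_identical(diag(m), c(k19 = 0, k21 = 0))
  # identical sets: all off-diagonal zero
  m2 <- pairwiseMissingMatrix(list(a = c("K00001"), b = c("K00001")))
  expect_true(all(m2 == 0))
  expect_error(pairwiseMissingMatrix(list(a = "K00001", a = "K00002")), "duplicate")
  expect_error(pairwiseMissingMatrix(list(a = "K00001")), "at least two")
})

test_that("the matrix agrees with a brute-force oracle on random families", {
  set.seed(7)
  for (i in 1:100) {
    sets <- randomKoiFamily(sample(2:6, 1))
    m <- pairwiseMissingMatrix(sets)
    for (r in names(sets)) {
      for (cc in names(sets)) {
        expect_identical(m[r, cc],
                         if (r == cc) 0 else as.numeric(sum(!(sets[[r]] %in% sets[[cc]]))))
      }
    }
  }
})

test_that("anti-symmetry identity: cell(r,c) - cell(c,r) = |r| - |c|", {
  set.seed(17)
  for (i in 1:50) {
    sets <- randomKoiFamily(sample(2:6, 1))
    m <- pairwiseMissingMatrix(sets)
    sizes <- lengths(sets)
    for (r in names(sets)) {
      for (cc in names(sets)) {
        expect_identical(m[r, cc] - m[cc, r], as.numeric(sizes[[r]] - sizes[[cc]]))
      }
    }
  }
})

test_that("vs-rest mode compares each row against the union of the others", {
  sets <- list(k19 = c("K00001", "K00002"), k21 = c("K00002"), k23 = c("K00003"))
  m <- pairwiseMissingMatrix(sets, mode = "vs-rest")
  expect_identical(unname(m["k19", c("k21", "k23")]), c(1, 1))  # only K00001 unique
  expect_identical(unname(m["k21", "k19"]), 0)
})

test_that("caComparison counts both directions and totals per-k counts", {
  rpt <- caComparison(c("K00001", "K00002"), list(k19 = c("K00002", "K00003")))
  pk <- rpt@perK
  expect_identical(pk$missing_from_ca[pk$label == "k19"], 1L)
  expect_identical(pk$missing_from_single[pk$label == "k19"], 1L)
  # all single sets contained in the CA
  rpt0 <- caComparison(c("K00001", "K00002"),
                       list(k19 = "K00001", k21 = c("K00001", "K00002")))
  expect_true(all(rpt0@perK$missing_from_ca == 0))
  expect_identical(totalMissingFromCa(rpt0), 0)
  # the per-k sum counts one KOI once per row; the distinct union collapses it
  rptDup <- caComparison("K00009", list(k19 = "K00001", k21 = "K00001"))
  expect_identical(totalMissingFromCa(rptDup), 2)
  expect_identical(rptDup@totalMissingFromCaDistinct, 1)
  expect_error(caComparison("K00001", list(CA = "K00002")), "distinct")
})

test_that("caReportFromCounts reproduces the printed totaling convention", {
  rpt <- caReportFromCounts(c(k19 = 3, k21 = 1, k23 = 0))
  expect_identical(totalMissingFromCa(rpt), 4)
  expect_true(is.na(rpt@totalMissingFromCaDistinct))
})

test_that("uniqueContigsForKois selects a minimal longest-contig cover", {
  asm <- Assembly("k19", c(c5 = "ACGTACGTAC", long = "ACGTACGTACGTACGT", s = "ACGTAC"))
  tab <- AnnotationTable("k19", list(c5 = "K00003"))
  sel <- uniqueContigsForKois(asm, tab, "K00003")
  expect_identical(sel$contigIds, "c5")
  # two targets on one contig: that contig only
  tab2 <- AnnotationTable("k19", list(long = c("K00001", "K00002"), s = "K00002"))
  sel2 <- uniqueContigsForKois(asm, tab2, c("K00001", "K00002"))
  expect_identical(sel2$contigIds, "long")
  # no overlap: empty, all not coverable
  sel3 <- uniqueContigsForKois(asm, tab, c("K11111", "K22222"))
  expect_identical(sel3$contigIds, character(0))
  expect_identical(sel3$notCoverable, c("K11111", "K22222"))
  # longest annotated contig preferred, ties by id
  tab3 <- AnnotationTable("k19", list(c5 = "K00001", long = "K00001"))
  expect_identical(uniqueContigsForKois(asm, tab3, "K00001")$contigIds, "long")
})

test_that("recovery restores exactly the KOIs missing from the CA", {
  ca <- Assembly("CA", c(r1 = "ACGTACGTACGTACGTACGT"))
  caTab <- AnnotationTable("CA", list(r1 = c("K00001", "K00002")))
  k19 <- Assembly("k19", c(a = "ACGTACGTAC", b = "GGGGCCCCAA"))
  t19 <- AnnotationTable("k19", list(a = "K00003"))
  k63 <- Assembly("k63", c(x = "TTTTAAAACC", y = "CCCCAAAATT"))
  t63 <- AnnotationTable("k63", list(x = c("K00003", "K00004")))
  rec <- recoverAnnotations(ca, caTab, list(
    list(assembly = k63, table = t63), list(assembly = k19, table = t19)
  ))
  # K00003 recovered from k19 (ascending k), K00004 from k63
  expect_identical(recoveredKois(rec), c("K00003", "K00004"))
  expect_setequal(rec@recovered$contig_id, c("k19|a", "k63|x"))
  expect_identical(rec@recovered$kois[rec@recovered$contig_id == "k19|a"], "K00003")
  expect_identical(rec@recovered$kois[rec@recovered$contig_id == "k63|x"], "K00004")
  expect_identical(koiSet(rec@finalTable), sprintf("K0000%d", 1:4))
  # nothing to recover: final equals the CA
  rec0 <- recoverAnnotations(ca, caTab, list(
    list(assembly = k19, table = AnnotationTable("k19", list(a = "K00001")))
  ))
  expect_identical(nrow(rec0@recovered), 0L)
  expect_identical(contigIds(finalAssembly(rec0)), contigIds(ca))
})

test_that("recovery is complete and weakly minimal on synthetic scenarios", {
  for (seed in 1:3) {
    catalog <- simulateCatalog(30, c(120, 500), 0.6, seed = seed)
    sc <- simulateMultikScenario(catalog, kValues = c(19L, 33L, 47L, 63L),
                                 plantLosses = 4L, seed = seed)
    for (c0 in c(0.9, 1.0)) {
      ca <- buildCA(sc$assemblies, ClusterParams(c0))
      caTab <- projectAnnotations(representatives(ca), sc$tables)
      singles <- lapply(names(sc$assemblies), function(l) {
        list(assembly = sc$assemblies[[l]], table = sc$tables[[l]])
      })
      rec <- recoverAnnotations(ca, caTab, singles)
      # completeness: the final KOI set is the union of all single-k KOI sets
      expect_identical(koiSet(rec@finalTable),
                       sort(union(koiSet(caTab), sc$truth$koiUnion)))
      expect_identical(setdiff(sc$truth$koiUnion, koiSet(rec@finalTable)), character(0))
      # recovered KOIs are disjoint from the CA's
      expect_identical(intersect(recoveredKois(rec), koiSet(caTab)), character(0))
      # weak minimality: every recovered contig contributed at least one new KOI
      expect_true(all(nzchar(rec@recovered$kois)))
      # the planted losses are among the recovered KOIs
      expect_true(all(sc$truth$plantedLostKois %in% recoveredKois(rec)))
    }
  }
})

test_that("contigKoiCounts reports per-label contig and KOI counts in order", {
  a <- Assembly("k19", seqsOfLengths(rep(20, 3)))
  t1 <- AnnotationTable("k19", list(c1 = c("K00001", "K00002")))
  b <- Assembly("k21", seqsOfLengths(rep(20, 5), prefix = "d"))
  t2 <- AnnotationTable("k21")
  cnt <- contigKoiCounts(list(a, b), list(t1, t2))
  expect_identical(cnt$label, c("k19", "k21"))
  expect_identical(cnt$n_contigs, c(3L, 5L))
  expect_identical(cnt$n_kois, c(2L, 0L))
})
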