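test_that("catalogs are reproducible and respect the KO fraction", {
  c1 <- simulateCatalog(100, c(100, 300), koFraction = 0.5, seed = 7)
  c2 <- simulateCatalog(100, c(100, 300), koFraction = 0.5, seed = 7)
  expect_identical(transcripts(c1), transcripts(c2))
  expect_identical(sum(!is.na(transcripts(c1)$ko)), 50L)
  c3 <- simulateCatalog(100, c(100, 300), koFraction = 0.5, seed = 8)
  expect_false(identical(transcripts(c1)$sequence, transcripts(c3)$sequence))
  # labels are distinct and well-formed
  kos <- transcripts(c1)$ko
  kos <- kos[!is.na(kos)]
  expect_identical(anyDuplicated(kos), 0L)
  expect_true(all(grepl("^K[0-9]{5}$", kos)))
  # extremes of the fraction
  expect_identical(sum(!is.na(transcripts(simulateCatalog(20, c(50, 80), 0, seed = 1))$ko)), 0L)
  allKo <- transcripts(simulateCatalog(20, c(50, 80), 1, seed = 1))$ko
  expect_identical(sum(is.na(allKo)), 0L)
  expect_identical(anyDuplicated(allKo), 0L)
})

test_that("simulateAssembly reproduces the catalog in the identity limit", {
  catalog <- simulateCatalog(15, c(100, 200), 0.6, seed = 3)
  sim <- simulateAssembly(catalog, 19, captureLow = 1, captureHigh = 1,
                          fragProb = 0, dupProb = 0, seed = 5)
  expect_identical(as.character(contigs(sim$assembly)),
                   setNames(transcripts(catalog)$sequence, transcripts(catalog)$id))
  tr <- transcripts(catalog)
  expect_identical(sort(koiSet(sim$table)), sort(tr$ko[!is.na(tr$ko)]))
  # capture 0: empty
  empty <- simulateAssembly(catalog, 19, captureLow = 0, captureHigh = 0, seed = 5)
  expect_identical(length(empty$assembly), 0L)
})

test_that("full fragmentation doubles contigs and duplicates each KO label", {
  catalog <- simulateCatalog(10, c(100, 200), 1, seed = 9)
  sim <- simulateAssembly(catalog, 21, captureLow = 1, captureHigh = 1,
                          fragProb = 1, dupProb = 0, seed = 2)
  expect_identical(length(sim$assembly), 20L)
  e <- annotationEntries(sim$table)
  expect_identical(nrow(e), 20L)
  expect_true(all(table(e$ko) == 2))
  # fragments concatenate back to the transcript
  seqs <- as.character(contigs(sim$assembly))
  tr <- transcripts(catalog)
  for (i in seq_len(nrow(tr))) {
    expect_identical(paste0(seqs[paste0(tr$id[i], ".f1")], seqs[paste0(tr$id[i], ".f2")]),
                     unname(tr$sequence[i]))
  }
})

test_that("duplicated copies carry a small substitution load", {
  catalog <- simulateCatalog(10, c(200, 300), 1, seed = 13)
  sim <- simulateAssembly(catalog, 23, captureLow = 1, captureHigh = 1,
                          fragProb = 0, dupProb = 1, editRate = 0.02, seed = 6)
  expect_identical(length(sim$assembly), 20L)
  seqs <- as.character(contigs(sim$assembly))
  tr <- transcripts(catalog)
  for (i in seq_len(nrow(tr))) {
    orig <- seqs[[tr$id[i]]]
    dup <- seqs[[paste0(tr$id[i], ".d1")]]
    ident <- pairIdentity(orig, dup, ClusterParams(bothStrands = FALSE))
    expect_equal(ident, 1 - round(0.02 * nchar(orig)) / nchar(orig), tolerance = 1e-9)
  }
})

test_that("every annotation traces to a catalog transcript's KO", {
  catalog <- simulateCatalog(40, c(100, 400), 0.6, seed = 17)
  sc <- simulateMultikScenario(catalog, kValues = c(19L, 41L, 63L), seed = 17)
  truthKo <- setNames(transcripts(catalog)$ko, transcripts(catalog)$id)
  for (tab in sc$tables) {
    e <- annotationEntries(tab)
    tid <- sub("([.]|\\|).*$", "", e$contig_id)
    expect_true(all(e$ko == truthKo[tid]))
  }
})

test_that("multi-k scenarios are deterministic and record a consistent truth", {
  catalog <- simulateCatalog(30, c(120, 400), 0.6, seed = 19)
  s1 <- simulateMultikScenario(catalog, kValues = c(19L, 33L, 47L), seed = 23)
  s2 <- simulateMultikScenario(catalog, kValues = c(19L, 33L, 47L), seed = 23)
  expect_identical(lapply(s1$assemblies, contigIds), lapply(s2$assemblies, contigIds))
  expect_identical(s1$truth$koiUnion, s2$truth$koiUnion)
  expect_identical(s1$truth$koiUnion,
                   sort(unique(unlist(lapply(s1$tables, koiSet), use.names = FALSE))))
  # per-k unique KOIs are truly unique to their assembly
  for (l in names(s1$truth$perKUnique)) {
    others <- unlist(s1$truth$perKKois[setdiff(names(s1$truth$perKKois), l)],
                     use.names = FALSE)
    expect_identical(intersect(s1$truth$perKUnique[[l]], others), character(0))
  }
})

test_that("planted losses are absent from the CA annotation but present in singles", {
  catalog <- simulateCatalog(30, c(120, 400), 0.6, seed = 29)
  sc <- simulateMultikScenario(catalog, kValues = c(19L, 33L, 47L, 63L),
                               plantLosses = 3L, seed = 29)
  expect_identical(length(sc$truth$plantedLostKois), 3L)
  expect_true(all(sc$truth$plantedLostKois %in% sc$truth$koiUnion))
  for (c0 in c(0.9, 0.95, 1.0)) {
    ca <- buildCA(sc$assemblies, ClusterParams(c0))
    caKois <- koiSet(projectAnnotations(representatives(ca), sc$tables))
    expect_identical(intersect(sc$truth$plantedLostKois, caKois), character(0))
  }
})

test_that("contig counts fall with k under the default capture schedule", {
  lowK <- 0
  highK <- 0
  for (seed in 1:20) {
    catalog <- simulateCatalog(30, c(120, 400), 0.6, seed = seed)
    sc <- simulateMultikScenario(catalog, kValues = c(19L, 63L), plantLosses = 0L,
                                 seed = seed)
    lowK <- lowK + length(sc$assemblies$k19)
    highK <- highK + length(sc$assemblies$k63)
  }
  expect_gt(lowK, highK)
})

test_that("simulateAlignments emits exactly readsPerContig reads per contig", {
  set.seed(31)
  asm <- Assembly("k19", seqsOfLengths(c(150, 60, 300)))
  al <- simulateAlignments(asm, readsPerContig = 7, readLength = 99, seed = 3)
  expect_identical(length(al$reads), 21L)
  expect_identical(as.vector(table(al$refNames)[contigIds(asm)]), rep(7L, 3))
  # contigs shorter than the read length yield themselves
  short <- readSequences(al$reads)[grepl("^c2_", names(readSequences(al$reads)))]
  expect_true(all(as.character(short) == as.character(contigs(asm))[["c2"]]))
  # reads are genuine substrings of their contig
  r1 <- as.character(readSequences(al$reads)[["c1_r1"]])
  expect_true(grepl(r1, as.character(contigs(asm))[["c1"]], fixed = TRUE))
  # zero reads: empty outputs
  none <- simulateAlignments(asm, readsPerContig = 0, seed = 3)
  expect_identical(length(none$reads), 0L)
  expect_identical(none$refNames, character(0))
})
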