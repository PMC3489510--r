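# Independent brute-force oracles, kept free of the package's C++ kernels.

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

revcompChr <- function(chars) rev(unname(DNA_COMP[chars]))

# gap-free containment identity: max matching bases over every ungapped
# placement of the shorter within the longer, / shorter length; N never matches
oracleIdentity <- function(a, b, bothStrands = TRUE) {
  ach <- strsplit(a, "", fixed = TRUE)[[1L]]
  bch <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(ach) > length(bch)) {
    tmp <- ach; ach <- bch; bch <- tmp
  }
  S <- length(ach)
  L <- length(bch)
  variants <- list(ach)
  if (bothStrands) variants <- c(variants, list(revcompChr(ach)))
  best <- 0L
  for (v in variants) {
    ok <- v != "N"
    for (off in 0:(L - S)) {
      w <- bch[(off + 1L):(off + S)]
      m <- sum(v == w & ok & w != "N")
      if (m > best) best <- m
    }
  }
  best / S
}

# greedy longest-first first-fit clustering, all pairs scored with the oracle
# identity (no word prefilter); replicates the own-representative rule for
# contigs shorter than the word size
oracleCluster <- function(seqs, c0, bothStrands = TRUE, wordSize = 8L) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]
  ids <- ids[ord]
  reps <- integer()
  repOf <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    if (nchar(seqs[i]) >= wordSize) {
      for (r in reps) {
        m <- oracleIdentity(seqs[i], seqs[r], bothStrands) * nchar(seqs[i])
        if (m >= c0 * nchar(seqs[i]) - 1e-9) {
          hit <- r
          break
        }
      }
    }
    if (hit) {
      repOf[i] <- hit
    } else {
      reps <- c(reps, i)
      repOf[i] <- i
    }
  }
  list(repIds = sort(ids[reps]), repOf = setNames(ids[repOf], ids))
}

# sort-and-prefix-sum length-weighted quantile
oracleNStat <- function(lengths, fraction) {
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= fraction * sum(s))[1L]]
}

# a random pool with planted duplicates, substrings, near-copies and
# reverse-complement copies, as clustering inputs
randomPool <- function(nBase, lenRange, nDerived = nBase) {
  seqs <- vapply(sample(lenRange[1L]:lenRange[2L], nBase, replace = TRUE),
                 randomSeq, "")
  names(seqs) <- sprintf("b%03d", seq_len(nBase))
  for (j in seq_len(nDerived)) {
    src <- seqs[[sample.int(nBase, 1L)]]
    kind <- sample(c("dup", "sub", "edit", "rc"), 1L)
    L <- nchar(src)
    out <- switch(kind,
      dup = src,
      sub = {
        a <- sample.int(max(1L, L - 10L), 1L)
        substr(src, a, min(L, a + sample(10:60, 1L)))
      },
      edit = {
        ch <- strsplit(src, "", fixed = TRUE)[[1L]]
        k <- max(1L, round(L * runif(1, 0.01, 0.15)))
        pos <- sample.int(L, k)
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        paste(ch, collapse = "")
      },
      rc = paste(revcompChr(strsplit(src, "", fixed = TRUE)[[1L]]), collapse = "")
    )
    seqs[sprintf("d%03d", j)] <- out
  }
  seqs
}

randomKoiFamily <- function(nSets, maxKois = 50L) {
  universe <- sprintf("K%05d", 1:80)
  sets <- lapply(seq_len(nSets), function(i) {
    sort(sample(universe, sample.int(maxKois, 1L)))
  })
  names(sets) <- sprintf("k%d", seq(19L, by = 2L, length.out = nSets))
  sets
}

# convenience: named character vector of n sequences with the given lengths
seqsOfLengths <- function(lengths, prefix = "c") {
  setNames(vapply(lengths, randomSeq, ""), paste0(prefix, seq_along(lengths)))
}
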