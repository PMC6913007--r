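## Shared fixture builders. Everything is generated in code; no data files.

BASES <- c("A", "C", "G", "T")

rndSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

flipBase <- function(b) setdiff(BASES, b)[1]

## point-mutate a sequence at the given rate (substitutions only)
mutateSeq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < rate)
  v[i] <- vapply(v[i], flipBase, "")
  paste(v, collapse = "")
}

## a subject that aligns to q's first 80 bp with exactly 16 mismatches
## (identity 0.80, coverage 0.80 of a 100-bp query, 80 aligned columns):
## mismatches every 4th base over the first 64 bp, clean 16-bp tail so a
## 13-mer seed exists, clean first two bases so extension reaches column 1
subject808080 <- function(q) {
  stopifnot(nchar(q) == 100)
  v <- strsplit(substr(q, 1, 80), "")[[1]]
  mm <- seq(3, 63, by = 4)
  v[mm] <- vapply(v[mm], flipBase, "")
  paste(v, collapse = "")
}

## a small TELibrary from named character sequences with RM-style headers
lib <- function(...) {
  x <- c(...)
  TELibrary(Biostrings::DNAStringSet(x))
}

## genome from named character vector
genome <- function(...) Biostrings::DNAStringSet(c(...))

## quick annotation from vectors (1-based closed)
ann <- function(seqId, start, end, class = "LTR", name = "t",
                resolved = NA) {
  cls <- unname(c(LTR = "LTR", TIR = "DNA", Helitron = "DNA/Helitron",
                  nonLTR = "nonLTR", nonTE = "Unknown")[class])
  TEAnnotation(GenomicRanges::GRanges(
    seqId, IRanges::IRanges(start, end),
    Name = rep_len(name, length(start)),
    teClass = rep_len(class, length(start)),
    classification = rep_len(cls, length(start))), resolved = resolved)
}

## brute-force per-base confusion oracle on one chromosome of length L
bruteConfusion <- function(L, curStart, curEnd, curTarget,
                           testStart, testEnd) {
  Tv <- logical(L); Pv <- logical(L)
  for (i in seq_along(curStart))
    if (curTarget[i]) Tv[curStart[i]:curEnd[i]] <- TRUE
  for (i in seq_along(testStart)) Pv[testStart[i]:testEnd[i]] <- TRUE
  c(tp = sum(Tv & Pv), fp = sum(!Tv & Pv), fn = sum(Tv & !Pv),
    tn = sum(!Tv & !Pv))
}

## the shared corrupted-simulation study conditions (500 kb, 5 families
## per class, 10% divergence, >= 10 of each corruption type); computed at
## most once per test run and cached
corruptedSim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simConfig(seed = 1,
                     corruption = list(tandem = 12L, short = 12L,
                                       helitronMotif = 12L, mislabel = 12L,
                                       nestedSpan = 8L, boundaryShift = 8L))
    ex <- makeExemplars(cfg)
    sim <- simulateGenome(ex, cfg)
    cands <- makeNoisyCandidates(sim$genome, sim$truth, cfg)
    s0 <- runStage0(cands, sim$genome)
    s1 <- suppressWarnings(runStage1(s0$candidates, sim$genome))
    cache <<- list(cfg = cfg, exemplars = ex, genome = sim$genome,
                   truth = sim$truth, candidates = cands,
                   stage0 = s0, stage1 = s1)
    cache
  }
})
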