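smallCfg <- function(seed, ...) {
  simConfig(seed = seed, chromLength = 120000L,
            families = list(LTR = 1L, TIR = 2L, Helitron = 1L, nonLTR = 2L),
            copies = c(4L, 6L), miteFraction = 0.5, ...)
}

test_that("exemplars carry the class-diagnostic terminal structures", {
  cfg <- simConfig(seed = 1, chromLength = 60000L)
  ex <- makeExemplars(cfg)
  info <- libInfo(ex)
  sq <- as.character(seqs(ex))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))

  for (i in which(info$class == "Helitron"))
    expect_match(sq[i], "^TC.*CT[AG][AG]$")
  ## GC-rich reverse-complement stem within the final 30 bp
  for (i in which(info$class == "Helitron")) {
    tail30 <- substr(sq[i], nchar(sq[i]) - 29, nchar(sq[i]))
    found <- FALSE
    for (w in 6:10) for (st in 1:(30 - w)) {
      stem <- substr(tail30, st, st + w - 1)
      if (grepl(rc(stem), substr(tail30, st + w, 30), fixed = TRUE) &&
          mean(strsplit(stem, "")[[1]] %in% c("G", "C")) >= 0.6)
        found <- TRUE
    }
    expect_true(found)
  }
  for (i in which(info$class == "LTR")) {
    expect_match(sq[i], "^TG.*CA$")
    ## identical terminal repeats of at least 100 bp at both ends
    L <- nchar(sq[i])
    reps <- vapply(100:350, function(w)
      substr(sq[i], 1, w) == substr(sq[i], L - w + 1, L), logical(1))
    expect_true(any(reps))
  }
  for (i in which(info$class == "TIR")) {
    ok <- any(vapply(12:28, function(w)
      substr(sq[i], 1, w) == rc(substr(sq[i], nchar(sq[i]) - w + 1,
                                       nchar(sq[i]))), logical(1)))
    expect_true(ok)
    if (info$isMITE[i]) expect_lt(nchar(sq[i]), 600)
  }
  for (i in which(info$class == "nonLTR"))
    expect_match(sq[i], "AAAAAAAA$")

  ## determinism: same seed gives byte-identical libraries
  ex2 <- makeExemplars(simConfig(seed = 1, chromLength = 60000L))
  expect_identical(as.character(seqs(ex2)), as.character(seqs(ex)))
})

test_that("LTR insertions duplicate a 5-bp target site around TG...CA copies", {
  cfg <- simConfig(seed = 3, chromLength = 20000L,
                   families = list(LTR = 1L, TIR = 0L, Helitron = 0L,
                                   nonLTR = 0L),
                   copies = c(1L, 1L), divergence = 0, indelRate = 0,
                   nestingProb = 0, fragmentationProb = 0)
  sim <- simulateGenome(makeExemplars(cfg), cfg)
  gr <- granges(sim$truth@annotation)
  expect_length(gr, 1)
  g <- as.character(sim$genome[[1]])
  st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
  expect_equal(substr(g, st, st + 1), "TG")
  expect_equal(substr(g, en - 1, en), "CA")
  expect_equal(substr(g, st - 5, st - 1), substr(g, en + 1, en + 5))
})

test_that("Helitron insertions sit in AT or TT target sites without a TSD", {
  cfg <- simConfig(seed = 4, chromLength = 30000L,
                   families = list(LTR = 0L, TIR = 0L, Helitron = 2L,
                                   nonLTR = 0L),
                   copies = c(2L, 3L), divergence = 0, indelRate = 0,
                   nestingProb = 0, fragmentationProb = 0)
  sim <- simulateGenome(makeExemplars(cfg), cfg)
  gr <- granges(sim$truth@annotation)
  g <- as.character(sim$genome[[1]])
  for (i in seq_along(gr)) {
    st <- BiocGenerics::start(gr)[i]; en <- BiocGenerics::end(gr)[i]
    expect_true(substr(g, st - 1, st - 1) %in% c("A", "T"))
    expect_equal(substr(g, en + 1, en + 1), "T")
  }
  expect_equal(sim$truth@tsdBases, 0)
})

test_that("forced nesting splits the host record and excision rejoins it", {
  cfg <- simConfig(seed = 5, chromLength = 30000L,
                   families = list(LTR = 2L, TIR = 0L, Helitron = 0L,
                                   nonLTR = 0L),
                   copies = c(1L, 1L), divergence = 0, indelRate = 0,
                   nestingProb = 1, fragmentationProb = 0)
  sim <- simulateGenome(makeExemplars(cfg), cfg)
  gr <- granges(sim$truth@annotation)
  mc <- S4Vectors::mcols(gr)
  split <- table(mc$insertionId)
  hostId <- as.integer(names(split)[split == 2])
  expect_length(hostId, 1)  # second insertion nests into the first
  pieces <- gr[mc$insertionId == hostId]
  g <- as.character(sim$genome[[1]])
  rejoined <- paste0(
    substr(g, BiocGenerics::start(pieces)[1], BiocGenerics::end(pieces)[1]),
    substr(g, BiocGenerics::start(pieces)[2], BiocGenerics::end(pieces)[2]))
  hostEntry <- mc$Name[mc$insertionId == hostId][1]
  ## at zero divergence, excising the nested insert reconstructs the host copy
  expect_equal(rejoined,
               as.character(seqs(sim$truth@exemplars)[[hostEntry]]))
})

test_that("planted bases are conserved and exact at zero divergence", {
  cfg <- smallCfg(seed = 6, divergence = 0, indelRate = 0,
                  fragmentationProb = 0)
  ex <- makeExemplars(cfg)
  sim <- simulateGenome(ex, cfg)
  gr <- granges(sim$truth@annotation)
  ## conservation: truth bp == genome growth minus TSD bookkeeping,
  ## computed independently from the sequence lengths
  expect_equal(sum(BiocGenerics::width(gr)),
               sum(BiocGenerics::width(sim$genome)) -
                 cfg$nChromosomes * cfg$chromLength - sim$truth@tsdBases)
  ## intact unsplit copies are exact substrings of their exemplar
  mc <- S4Vectors::mcols(gr)
  splitIds <- unique(mc$insertionId[duplicated(mc$insertionId)])
  g <- as.character(sim$genome[[1]])
  for (i in which(mc$intact & !(mc$insertionId %in% splitIds))) {
    copy <- substr(g, BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])
    expect_equal(copy, as.character(seqs(ex)[[mc$Name[i]]]))
  }
})

test_that("simulation is reproducible under the seed", {
  cfg <- smallCfg(seed = 7, corruption = list(tandem = 3L, mislabel = 2L))
  r1 <- simulateGenome(makeExemplars(cfg), cfg)
  r2 <- simulateGenome(makeExemplars(cfg), cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(granges(r1$truth@annotation),
                   granges(r2$truth@annotation))
  c1 <- makeNoisyCandidates(r1$genome, r1$truth, cfg)
  c2 <- makeNoisyCandidates(r2$genome, r2$truth, cfg)
  expect_identical(as.character(seqs(entries(c1))),
                   as.character(seqs(entries(c2))))
})

test_that("corrupted candidates carry their construction tags", {
  cfg <- smallCfg(seed = 8,
                  corruption = list(tandem = 3L, short = 4L,
                                    helitronMotif = 3L, mislabel = 2L,
                                    boundaryShift = 2L, shiftBp = 10L))
  sim <- simulateGenome(makeExemplars(cfg), cfg)
  cands <- makeNoisyCandidates(sim$genome, sim$truth, cfg)
  a <- anchors(cands)
  info <- libInfo(entries(cands))
  sq <- as.character(seqs(entries(cands)))
  tags <- table(a$corruption)
  expect_equal(unname(tags["tandem"]), 3)
  expect_equal(unname(tags["short"]), 4)
  expect_equal(unname(tags["helitron_motif"]), 3)
  expect_equal(unname(tags["mislabel"]), 2)

  ## tandem candidates really are short-period arrays
  for (i in which(a$corruption == "tandem")) {
    expect_gte(nchar(sq[i]), 200)
    expect_gte(tandemFraction(sq[i]), 0.95)
  }
  ## short fragments are below the TIR minimum
  expect_true(all(nchar(sq[a$corruption == "short"]) < 80))
  ## mislabels: sequence matches a truth copy of a different class
  for (i in which(a$corruption == "mislabel")) {
    src <- a$sourceEntry[i]
    expect_false(info$class[i] ==
                   libInfo(sim$truth@exemplars)$class[
                     match(src, names(sim$truth@exemplars))])
  }
  ## motif violators do not satisfy the Helitron terminal signature
  for (i in which(a$corruption == "helitron_motif"))
    expect_false(substr(sq[i], 1, 2) == "TC" && grepl("CT[AG][AG]$", sq[i]))
  ## boundary-shifted candidates differ from every truth interval on
  ## exactly one side by shiftBp
  gr <- granges(sim$truth@annotation)
  for (i in which(a$corruption == "boundary_shift")) {
    d <- abs(cbind(BiocGenerics::start(gr) - a$start[i],
                   BiocGenerics::end(gr) - a$end[i]))
    expect_true(any(rowSums(d == 0) == 1 & rowSums(d) == cfg$corruption$shiftBp))
  }
})
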