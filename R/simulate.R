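## TE genome simulator: exemplar libraries with class-specific structure,
## genomes with planted (diverged, truncated, possibly nested) insertions
## and exact ground truth, and deliberately corrupted candidate sets.
## One pseudo-random stream per operation, seeded deterministically from
## the config seed (exemplars: seed, genome: seed + 1, candidates:
## seed + 2), with all draws in a fixed documented order.

.CODE2CHR <- c(65L, 67L, 71L, 84L)  # A C G T

## sample() treats a length-one numeric vector as 1:n; these helpers are
## safe for degenerate ranges
.pick1 <- function(x) x[sample.int(length(x), 1L)]
.pickN <- function(x, n) x[sample.int(length(x), n)]

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.randCodes <- function(n, gc) {
  sample.int(4L, n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.codesToString <- function(v) intToUtf8(.CODE2CHR[v])

.stringToCodes <- function(s) {
  map <- integer(128)
  map[c(65L, 67L, 71L, 84L)] <- 1:4
  map[utf8ToInt(s)]
}

#' Simulation configuration
#'
#' Defines the conditions of a simulated TE landscape. Defaults emulate a
#' compact plant-like genome segment: 500 kb, GC content 0.43, five
#' families per TE class with 3-8 copies each, 10% sequence divergence
#' (well below the 40% ceiling the masker tolerates), 1% indels, 10%
#' nesting and 20% truncation probability per insertion.
#'
#' @param seed mandatory integer seed; all randomness flows from it.
#' @param nChromosomes,chromLength number and length (bp) of chromosomes.
#' @param gcContent background GC fraction.
#' @param families named integer list: number of families per class
#'   (`LTR`, `TIR`, `Helitron`, `nonLTR`).
#' @param copies two integers: uniform range of copy number per family.
#' @param elementLength named list of length ranges (bp) per structural
#'   type (`LTR`, `TIR`, `MITE`, `Helitron`, `LINE`, `SINE`).
#' @param ltrLength range of the long terminal repeat length for LTR
#'   exemplars (identical repeats at both ends, `TG...CA` termini).
#' @param miteFraction fraction of TIR families that are MITEs (< 600 bp).
#' @param divergence expected per-base substitution fraction of planted
#'   copies, in \[0, 0.4\].
#' @param indelRate expected per-base indel fraction of planted copies.
#' @param nestingProb probability that an insertion lands inside a
#'   previously placed TE, splitting its truth record.
#' @param fragmentationProb probability that a copy is truncated (a
#'   uniform 20-80% removed from one end) before insertion.
#' @param maxNestingDepth maximum nesting depth (default 2).
#' @param preserveTermini keep class-diagnostic terminal bases (LTR
#'   `TG`/`CA`, Helitron `TC`/`CTRR`, nonLTR poly-A tail) free of
#'   substitutions, emulating the ascertainment of structure-based
#'   detectors whose candidates necessarily carry intact termini.
#' @param corruption named list of corrupted-candidate counts for
#'   [makeNoisyCandidates()]: `tandem`, `short`, `helitronMotif`,
#'   `mislabel`, `boundaryShift`, `nestedSpan`, plus `shiftBp` (boundary
#'   shift magnitude, bp).
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(seed,
                      nChromosomes = 1L,
                      chromLength = 500000L,
                      gcContent = 0.43,
                      families = list(LTR = 5L, TIR = 5L, Helitron = 5L,
                                      nonLTR = 5L),
                      copies = c(3L, 8L),
                      elementLength = list(LTR = c(1000L, 3000L),
                                           TIR = c(700L, 1500L),
                                           MITE = c(100L, 500L),
                                           Helitron = c(600L, 1500L),
                                           LINE = c(2000L, 4000L),
                                           SINE = c(150L, 400L)),
                      ltrLength = c(100L, 350L),
                      miteFraction = 0.4,
                      divergence = 0.10,
                      indelRate = 0.01,
                      nestingProb = 0.10,
                      fragmentationProb = 0.20,
                      maxNestingDepth = 2L,
                      preserveTermini = TRUE,
                      corruption = list(tandem = 0L, short = 0L,
                                        helitronMotif = 0L, mislabel = 0L,
                                        boundaryShift = 0L, nestedSpan = 0L,
                                        shiftBp = 10L)) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory")
  probs <- c(gcContent, divergence, indelRate, nestingProb,
             fragmentationProb, miteFraction)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must be in [0, 1]")
  if (divergence > 0.4)
    stop("divergence must not exceed 0.4, the masker's divergence ceiling")
  for (cl in names(elementLength))
    if (elementLength[[cl]][1] > elementLength[[cl]][2])
      stop("infeasible length range for ", cl)
  if (elementLength$MITE[2] >= 600L)
    stop("MITE lengths must stay below 600 bp")
  defaults <- list(tandem = 0L, short = 0L, helitronMotif = 0L,
                   mislabel = 0L, boundaryShift = 0L, nestedSpan = 0L,
                   shiftBp = 10L)
  for (nm in names(defaults))
    if (is.null(corruption[[nm]])) corruption[[nm]] <- defaults[[nm]]
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              chromLength = as.integer(chromLength), gcContent = gcContent,
              families = families, copies = as.integer(copies),
              elementLength = elementLength,
              ltrLength = as.integer(ltrLength),
              miteFraction = miteFraction, divergence = divergence,
              indelRate = indelRate, nestingProb = nestingProb,
              fragmentationProb = fragmentationProb,
              maxNestingDepth = as.integer(maxNestingDepth),
              preserveTermini = isTRUE(preserveTermini),
              corruption = corruption)
  class(cfg) <- "SimConfig"
  cfg
}

## TIR superfamilies cycled over TIR families, with their TSD lengths.
.TIR_SUPERFAMILIES <- c(hAT = 8L, CACTA = 3L, Mutator = 9L, PIF = 3L,
                        Tc1 = 2L)
.MITE_SUPERFAMILIES <- c(Tourist = 3L, Stowaway = 2L)

#' Generate a structurally faithful exemplar library
#'
#' Builds one exemplar per family with the class-diagnostic structure:
#' LTR exemplars begin `TG` and end `CA` with identical terminal repeats
#' (>= 100 bp) at both ends and a 5-bp TSD on insertion; TIR exemplars
#' carry exact reverse-complement terminal inverted repeats of 12-28 bp
#' and superfamily-specific TSDs; MITE exemplars are TIR-structured and
#' shorter than 600 bp; Helitron exemplars start `TC`, end `CTRR`
#' (R = A or G) and carry a GC-rich reverse-complement stem (>= 6 bp)
#' within the final 30 bp; LINE/SINE exemplars end in a poly-A tail
#' (>= 8 bp). Internal sequence is i.i.d. at the configured GC.
#' Deterministic under the config seed.
#'
#' @param config a [simConfig()] object.
#' @return a [TELibrary] with `tsdLength` structural metadata.
#' @export
makeExemplars <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed, {
    gc <- config$gcContent
    seqsL <- character(0)
    rows <- list()
    addEntry <- function(name, class, subclass, superfamily, isMITE, tsd,
                         seq) {
      seqsL[[name]] <<- seq
      rows[[length(rows) + 1L]] <<- DataFrame(
        name = name, class = class, subclass = subclass,
        superfamily = superfamily, isMITE = isMITE,
        classification = NA_character_, stage = "exemplar",
        tsdLength = tsd, score = NA_real_)
    }
    rnd <- function(n) .codesToString(.randCodes(n, gc))
    rcStr <- function(s)
      as.character(reverseComplement(DNAString(s)))

    for (i in seq_len(config$families$LTR)) {
      sf <- c("Gypsy", "Copia")[(i %% 2L) + 1L]
      total <- .pick1(config$elementLength$LTR[1]:config$elementLength$LTR[2])
      ltrLen <- .pick1(config$ltrLength[1]:
                         min(config$ltrLength[2], (total - 100L) %/% 2L))
      ltr <- paste0("TG", rnd(ltrLen - 4L), "CA")
      internal <- rnd(total - 2L * ltrLen)
      addEntry(paste0("simLTR", i), "LTR", NA_character_, sf, FALSE, 5L,
               paste0(ltr, internal, ltr))
    }
    nT <- config$families$TIR
    nMITE <- round(config$miteFraction * nT)
    for (i in seq_len(nT)) {
      isMITE <- i > nT - nMITE
      sfs <- if (isMITE) .MITE_SUPERFAMILIES else .TIR_SUPERFAMILIES
      j <- ((i - 1L) %% length(sfs)) + 1L
      lens <- if (isMITE) config$elementLength$MITE else
        config$elementLength$TIR
      total <- .pick1(lens[1]:lens[2])
      tirLen <- .pick1(12:28)
      tir <- rnd(tirLen)
      addEntry(paste0(if (isMITE) "simMITE" else "simTIR", i), "TIR",
               NA_character_, names(sfs)[j], isMITE, unname(sfs[j]),
               paste0(tir, rnd(total - 2L * tirLen), rcStr(tir)))
    }
    for (i in seq_len(config$families$Helitron)) {
      total <- .pick1(config$elementLength$Helitron[1]:
                        config$elementLength$Helitron[2])
      stem <- .codesToString(sample.int(4L, 7L, replace = TRUE,
                                        prob = c(.05, .45, .45, .05)))
      tail <- paste0(stem, rnd(4L), rcStr(stem), rnd(3L),
                     "CT", .codesToString(sample(c(1L, 3L), 2L, TRUE)))
      addEntry(paste0("simHEL", i), "Helitron", NA_character_,
               NA_character_, FALSE, NA_integer_,
               paste0("TC", rnd(total - 2L - nchar(tail)), tail))
    }
    nNL <- config$families$nonLTR
    nSINE <- nNL %/% 2L
    for (i in seq_len(nNL)) {
      isSINE <- i > nNL - nSINE
      lens <- if (isSINE) config$elementLength$SINE else
        config$elementLength$LINE
      total <- .pick1(lens[1]:lens[2])
      polyA <- strrep("A", .pick1(8:15))
      addEntry(paste0(if (isSINE) "simSINE" else "simLINE", i), "nonLTR",
               if (isSINE) "SINE" else "LINE",
               if (isSINE) "tRNA" else "L1", FALSE, NA_integer_,
               paste0(rnd(total - nchar(polyA)), polyA))
    }
    info <- do.call(rbind, rows)
    info$classification <- rmClassification(info)
    TELibrary(DNAStringSet(unlist(seqsL)), info = info)
  })
}

## Substitutions (outside masked positions) then indels on a code vector.
.mutateCodes <- function(v, subRate, indelRate, mask = integer(0)) {
  n <- length(v)
  if (subRate > 0) {
    i <- which(stats::runif(n) < subRate)
    i <- setdiff(i, mask)
    if (length(i))
      v[i] <- ((v[i] - 1L + sample.int(3L, length(i), replace = TRUE)) %% 4L) +
        1L
  }
  if (indelRate > 0) {
    j <- which(stats::runif(n) < indelRate)
    j <- setdiff(j, mask)
    if (length(j)) {
      isDel <- stats::runif(length(j)) < 0.5
      keep <- rep(TRUE, n)
      keep[j[isDel]] <- FALSE
      insAt <- j[!isDel]
      insBase <- sample.int(4L, length(insAt), replace = TRUE)
      if (length(insAt)) {
        pieces <- vector("list", 2L * length(insAt) + 1L)
        prev <- 1L
        for (t in seq_along(insAt)) {
          pieces[[2L * t - 1L]] <- v[seq.int(prev, insAt[t])[keep[prev:insAt[t]]]]
          pieces[[2L * t]] <- insBase[t]
          prev <- insAt[t] + 1L
        }
        pieces[[2L * length(insAt) + 1L]] <-
          if (prev <= n) v[seq.int(prev, n)[keep[prev:n]]] else integer(0)
        v <- unlist(pieces)
      } else v <- v[keep]
    }
  }
  v
}

## positions never substituted when preserveTermini is on
.terminalMask <- function(class, len) {
  switch(class,
         LTR = c(1L, 2L, len - 1L, len),
         Helitron = c(1L, 2L, (len - 3L):len),
         nonLTR = (len - 7L):len,
         integer(0))
}

#' Simulate a genome with planted TE insertions and full ground truth
#'
#' Generates i.i.d. background chromosomes and plants each family's copies
#' sequentially: a copy is substituted at `divergence` and indel-mutated at
#' `indelRate`, possibly truncated, then inserted either into background or
#' (with `nestingProb`) inside a previously placed TE, whose truth record
#' is split in two. Target-site duplications are class specific (LTR 5 bp;
#' TIR superfamily length; Helitron none, but the host dinucleotide
#' straddling the insertion is forced to `A|T` or `T|T`). The TSD copy is
#' duplicated exactly, then subjected to the same substitution process as
#' the element. Deterministic under the config seed.
#'
#' @param exemplars a [TELibrary] from [makeExemplars()].
#' @param config the [simConfig()] object.
#' @return a list with elements `genome` (a `DNAStringSet`) and `truth`
#'   (a [GroundTruth]).
#' @export
simulateGenome <- function(exemplars, config) {
  stopifnot(inherits(config, "SimConfig"), length(exemplars) > 0)
  .withSeed(config$seed + 1L, {
    info <- libInfo(exemplars)
    exCodes <- lapply(as.character(seqs(exemplars)), .stringToCodes)

    plan <- list()
    for (i in seq_len(nrow(info))) {
      ncopy <- .pick1(config$copies[1]:config$copies[2])
      for (cp in seq_len(ncopy)) plan[[length(plan) + 1L]] <- i
    }
    plan <- unlist(plan)[sample.int(length(unlist(plan)))]
    need <- sum(lengths(exCodes)[plan])
    capacity <- config$nChromosomes * config$chromLength
    if (need > 0.7 * capacity)
      stop("genome too small for requested copies: need at least ",
           ceiling(need / 0.7), " bp of background")

    chroms <- lapply(seq_len(config$nChromosomes), function(i)
      .randCodes(config$chromLength, config$gcContent))
    names(chroms) <- paste0("chr", seq_len(config$nChromosomes))
    bgLength <- sum(lengths(chroms))

    recs <- data.frame(seqId = character(), start = integer(),
                       end = integer(), insertionId = integer(),
                       depth = integer(), stringsAsFactors = FALSE)
    meta <- list()
    tsdBases <- 0L

    for (id in seq_along(plan)) {
      fi <- plan[id]
      cls <- info$class[fi]
      v <- exCodes[[fi]]
      mask <- if (config$preserveTermini)
        .terminalMask(cls, length(v)) else integer(0)
      v <- .mutateCodes(v, config$divergence, config$indelRate, mask)
      intact <- TRUE
      if (stats::runif(1) < config$fragmentationProb) {
        frac <- stats::runif(1, 0.2, 0.8)
        cut <- max(1L, round(frac * length(v)))
        if (length(v) - cut >= 50L) {
          v <- if (stats::runif(1) < 0.5) v[-seq_len(cut)] else
            v[seq_len(length(v) - cut)]
          intact <- FALSE
        }
      }
      t <- if (cls == "LTR") 5L else if (cls == "TIR")
        info$tsdLength[fi] else 0L

      chromPick <- .pick1(names(chroms))
      L <- length(chroms[[chromPick]])
      onChrom <- recs$seqId == chromPick
      nestedIn <- NA_integer_
      pos <- NA_integer_
      if (stats::runif(1) < config$nestingProb) {
        hostable <- which(onChrom & recs$depth < config$maxNestingDepth &
                            recs$end - recs$start >= 20L &
                            recs$start >= t + 1L)
        if (length(hostable) > 0) {
          hi <- hostable[sample.int(length(hostable), 1L)]
          pos <- .pick1(seq.int(max(recs$start[hi], t + 1L),
                                recs$end[hi] - 1L))
          nestedIn <- recs$insertionId[hi]
        }
      }
      if (is.na(pos)) {
        free <- IRanges::setdiff(
          IRanges(max(t + 1L, 1L), L - 1L),
          if (any(onChrom)) IRanges(recs$start[onChrom], recs$end[onChrom])
          else IRanges())
        if (length(free) == 0) stop("no insertion space left on ", chromPick)
        ri <- sample.int(length(free), 1L, prob = width(free))
        pos <- start(free)[ri] + sample.int(width(free)[ri], 1L) - 1L
      }

      chrom <- chroms[[chromPick]]
      if (cls == "Helitron") {
        # force the host dinucleotide straddling the insertion to A|T or T|T
        if (!chrom[pos] %in% c(1L, 4L))
          chrom[pos] <- sample(c(1L, 4L), 1L)
        chrom[pos + 1L] <- 4L
      }
      tsdCopy <- integer(0)
      if (t > 0) {
        tsdCopy <- .mutateCodes(chrom[(pos - t + 1L):pos],
                                config$divergence, 0)
        tsdBases <- tsdBases + t
      }
      ins <- c(v, tsdCopy)
      m <- length(ins)
      chroms[[chromPick]] <- c(chrom[seq_len(pos)], ins,
                               chrom[seq.int(pos + 1L, length(chrom))])

      # shift / split existing records
      if (any(onChrom)) {
        idx <- which(onChrom)
        shift <- idx[recs$start[idx] > pos]
        recs$start[shift] <- recs$start[shift] + m
        recs$end[shift] <- recs$end[shift] + m
        host <- idx[recs$start[idx] <= pos & recs$end[idx] > pos]
        for (hi in host) {
          right <- recs[hi, ]
          right$start <- pos + m + 1L
          right$end <- right$end + m
          recs$end[hi] <- pos
          recs <- rbind(recs, right)
        }
      }
      depth <- if (is.na(nestedIn)) 0L else
        meta[[nestedIn]]$depth + 1L
      recs <- rbind(recs, data.frame(
        seqId = chromPick, start = pos + 1L, end = pos + length(v),
        insertionId = id, depth = depth, stringsAsFactors = FALSE))
      meta[[id]] <- list(insertionId = id, entry = info$name[fi],
                         class = cls, seqId = chromPick, intact = intact,
                         nestedIn = nestedIn, tsdLength = t,
                         insertedLength = length(v), depth = depth)
    }

    genome <- DNAStringSet(vapply(chroms, .codesToString, character(1)))
    insertions <- DataFrame(
      insertionId = vapply(meta, `[[`, integer(1), "insertionId"),
      entry = vapply(meta, `[[`, character(1), "entry"),
      class = vapply(meta, `[[`, character(1), "class"),
      seqId = vapply(meta, `[[`, character(1), "seqId"),
      intact = vapply(meta, `[[`, logical(1), "intact"),
      nestedIn = vapply(meta, `[[`, integer(1), "nestedIn"),
      tsdLength = vapply(meta, `[[`, integer(1), "tsdLength"),
      insertedLength = vapply(meta, `[[`, integer(1), "insertedLength"),
      depth = vapply(meta, `[[`, integer(1), "depth"))

    m <- match(recs$insertionId, insertions$insertionId)
    fm <- match(insertions$entry[m], info$name)
    gr <- GRanges(recs$seqId, IRanges(recs$start, recs$end), strand = "+",
                  Name = insertions$entry[m], teClass = info$class[fm],
                  classification = info$classification[fm],
                  identity = 1 - config$divergence, score = NA_real_,
                  insertionId = recs$insertionId,
                  intact = insertions$intact[m])
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    truth <- new("GroundTruth", exemplars = exemplars,
                 annotation = TEAnnotation(gr, resolved = TRUE),
                 insertions = insertions,
                 tsdBases = as.numeric(tsdBases))
    stopifnot(sum(width(gr)) ==
                sum(width(genome)) - bgLength - tsdBases)
    list(genome = genome, truth = truth)
  })
}

#' Derive a deliberately corrupted raw candidate set
#'
#' Emits one candidate per intact, uninterrupted planted copy (the output a
#' well-behaved structural detector would produce), then plants the
#' configured corruptions: boundary-shifted copies, cross-class mislabeled
#' copies, pure tandem-repeat sequences, short (< 80 bp) fragments,
#' terminal-motif-violating Helitron candidates cut from random genomic
#' intervals, and candidates spanning a nested pair. Every candidate is
#' tagged with its corruption type (`"true"` for faithful ones) so filter
#' behaviour can be asserted against the tags. Deterministic under the
#' config seed. Mislabels are drawn from distinct families with at least
#' four intact copies, reflecting that abundant families are the usual
#' source of cross-class misclassification.
#'
#' @param genome,truth output of [simulateGenome()].
#' @param config the [simConfig()] object.
#' @return a [CandidateSet].
#' @export
makeNoisyCandidates <- function(genome, truth, config) {
  stopifnot(inherits(config, "SimConfig"), is(truth, "GroundTruth"))
  .withSeed(config$seed + 2L, {
    gstr <- lapply(as.character(genome), identity)
    gr <- granges(truth@annotation)
    mc <- mcols(granges(truth@annotation))
    ins <- truth@insertions
    exInfo <- libInfo(truth@exemplars)
    co <- config$corruption

    splitIds <- unique(mc$insertionId[duplicated(mc$insertionId)])
    usable <- ins[ins$intact & !(ins$insertionId %in% splitIds), ,
                  drop = FALSE]

    seqsL <- character(0)
    rows <- list()
    anch <- list()
    addCand <- function(name, class, subclass, superfamily, isMITE, score,
                        seqId, start, end, corruption, sourceEntry,
                        seqOverride = NULL) {
      seq <- if (!is.null(seqOverride)) seqOverride else
        substr(gstr[[seqId]], start, end)
      fl <- if (!is.na(seqId))
        extractFlanks(genome, seqId, start, end, 60L) else
        list(left = "", right = "")
      seqsL[[name]] <<- seq
      rows[[length(rows) + 1L]] <<- DataFrame(
        name = name, class = class, subclass = subclass,
        superfamily = superfamily, isMITE = isMITE,
        classification = NA_character_, stage = "raw",
        tsdLength = NA_integer_, score = score)
      anch[[length(anch) + 1L]] <<- DataFrame(
        seqId = seqId, start = as.integer(start), end = as.integer(end),
        leftFlank = fl$left, rightFlank = fl$right,
        corruption = corruption, sourceEntry = sourceEntry,
        verdict = NA_character_)
    }
    entryRow <- function(entry) exInfo[match(entry, exInfo$name), ]

    recOf <- gr[match(usable$insertionId, mc$insertionId)]
    for (i in seq_len(nrow(usable))) {
      e <- entryRow(usable$entry[i])
      score <- if (e$class == "Helitron") sample(12:30, 1L) else NA_real_
      addCand(paste0("cand", usable$insertionId[i], "_", e$name),
              e$class, e$subclass, e$superfamily, e$isMITE, score,
              usable$seqId[i], start(recOf)[i], end(recOf)[i],
              "true", e$name)
    }
    trueIdx <- seq_along(rows)

    # boundary-shifted copies: one side moved by shiftBp
    if (co$boundaryShift > 0 && length(trueIdx) > 0) {
      pick <- .pickN(trueIdx, min(co$boundaryShift, length(trueIdx)))
      for (j in seq_along(pick)) {
        a <- anch[[pick[j]]]
        L <- nchar(gstr[[a$seqId]])
        sh <- co$shiftBp * sample(c(-1L, 1L), 1L)
        st <- a$start; en <- a$end
        if (j %% 2L == 0L) st <- max(1L, min(st + sh, en - 30L)) else
          en <- min(L, max(en + sh, st + 30L))
        r <- rows[[pick[j]]]
        addCand(paste0("shift", j, "_", r$name), r$class, r$subclass,
                r$superfamily, r$isMITE, r$score, a$seqId, st, en,
                "boundary_shift", a$sourceEntry)
      }
    }

    # cross-class mislabels from distinct abundant families
    if (co$mislabel > 0) {
      tab <- table(unlist(lapply(trueIdx, function(i)
        anch[[i]]$sourceEntry)))
      rich <- names(tab)[tab >= 4L]
      rich <- rich[order(-tab[rich])]
      other <- c(LTR = "TIR", TIR = "LTR", Helitron = "LTR",
                 nonLTR = "TIR")
      nm <- 0L
      for (fam in rep(rich, length.out = max(co$mislabel, length(rich)))) {
        if (nm >= co$mislabel) break
        famIdx <- trueIdx[vapply(trueIdx, function(i)
          anch[[i]]$sourceEntry == fam, logical(1))]
        src <- famIdx[sample.int(length(famIdx), 1L)]
        a <- anch[[src]]; r <- rows[[src]]
        newClass <- other[[r$class]]
        nm <- nm + 1L
        addCand(paste0("mislabel", nm, "_", fam), newClass,
                NA_character_, NA_character_, FALSE,
                if (newClass == "Helitron") sample(12:30, 1L) else NA_real_,
                a$seqId, a$start, a$end, "mislabel", a$sourceEntry)
      }
    }

    # pure tandem-repeat candidates (unanchored)
    if (co$tandem > 0) {
      for (j in seq_len(co$tandem)) {
        motif <- .codesToString(.randCodes(.pick1(2:6), config$gcContent))
        reps <- ceiling(.pick1(200:400) / nchar(motif))
        cls <- sample(c("LTR", "TIR", "Helitron"), 1L)
        addCand(paste0("tandem", j), cls, NA_character_, NA_character_,
                FALSE, NA_real_, NA_character_, NA_integer_, NA_integer_,
                "tandem", NA_character_, seqOverride = strrep(motif, reps))
      }
    }

    # short (< 80 bp) fragments of true copies
    if (co$short > 0 && length(trueIdx) > 0) {
      for (j in seq_len(co$short)) {
        src <- .pick1(trueIdx)
        a <- anch[[src]]; r <- rows[[src]]
        len <- .pick1(40:79)
        st <- a$start + sample.int(max(1L, a$end - a$start - len), 1L) - 1L
        addCand(paste0("short", j, "_", r$name), r$class, r$subclass,
                r$superfamily, r$isMITE, NA_real_, a$seqId, st,
                st + len - 1L, "short", a$sourceEntry)
      }
    }

    # terminal-motif-violating Helitron candidates from random intervals
    if (co$helitronMotif > 0) {
      for (j in seq_len(co$helitronMotif)) {
        for (try in 1:50) {
          sq <- .pick1(names(genome))
          L <- nchar(gstr[[sq]])
          len <- .pick1(300:800)
          st <- sample.int(L - len - 120L, 1L) + 60L
          sg <- substr(gstr[[sq]], st, st + len - 1L)
          okMotif <- substr(sg, 1L, 2L) == "TC" &&
            grepl("CT[AG][AG]$", sg)
          if (!okMotif) break
        }
        addCand(paste0("badhel", j), "Helitron", NA_character_,
                NA_character_, FALSE, sample(12:30, 1L), sq, st,
                st + len - 1L, "helitron_motif", NA_character_)
      }
    }

    # candidates spanning a nested pair (host + insert)
    if (co$nestedSpan > 0 && length(splitIds) > 0) {
      hosts <- .pickN(splitIds, min(co$nestedSpan, length(splitIds)))
      for (j in seq_along(hosts)) {
        pieces <- gr[mc$insertionId == hosts[j]]
        e <- entryRow(ins$entry[match(hosts[j], ins$insertionId)])
        addCand(paste0("nestspan", j, "_", e$name), e$class, e$subclass,
                e$superfamily, e$isMITE,
                if (e$class == "Helitron") sample(12:30, 1L) else NA_real_,
                as.character(seqnames(pieces))[1],
                min(start(pieces)), max(end(pieces)),
                "nested_span", e$name)
      }
    }

    info <- do.call(rbind, rows)
    info$classification <- rmClassification(info)
    ent <- TELibrary(DNAStringSet(unlist(seqsL)), info = info)
    CandidateSet(ent, do.call(rbind, anch))
  })
}
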