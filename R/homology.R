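## Homology engine: k-mer seeded masking of a genome with a TE library,
## genome-wide copy-number counting, the 80-80-80 redundancy test, and
## tandem / simple-sequence-repeat detectors. The seed-and-extend core
## lives in src/seed_extend.cpp; everything here works on its hit tables.

#' Masking parameters
#'
#' Parameters of the k-mer seeded homology masker. The defaults mirror
#' common repeat-annotation practice: hits up to 40% divergence
#' (`maxDivergence = 0.4`), minimum reported hit length 80 bp, and a score
#' threshold on `matches - penalty * (mismatches + gaps)`, where the
#' penalty `(1 - maxDivergence) / maxDivergence` breaks even exactly at
#' the divergence ceiling, so that any sufficiently long hit within the
#' ceiling scores positively (as a repeat masker's divergence-adjusted
#' matrices do). The default `minScore` is calibrated so that an 80 bp
#' hit at exactly 80% identity passes (inclusive); its job is to reject
#' short noisy hits, not long diverged ones. Collinear hits to the same
#' entry separated by at most `mergeGap` bp are merged before scoring.
#'
#' @param kmerSize exact seed length in bp (8-15).
#' @param maxDivergence maximum divergence of reported hits, in (0, 1).
#' @param minHitLength minimum genomic span of a reported hit, bp.
#' @param minScore minimum hit score; `NULL` (default) calibrates it to
#'   the 80 bp / 80% identity boundary case.
#' @param bothStrands also search the reverse complement of the library.
#' @param mergeGap merge collinear fragments separated by at most this many
#'   bp (both in the genome and in the library entry).
#' @param xdrop stop extending when the running score falls this far below
#'   its maximum; the hit is trimmed back to the maximum.
#' @return a validated list of class `MaskParams`.
#' @export
maskParams <- function(kmerSize = 13L, maxDivergence = 0.4,
                       minHitLength = 80L, minScore = NULL,
                       bothStrands = TRUE, mergeGap = 50L, xdrop = 25) {
  stopifnot(kmerSize >= 8, kmerSize <= 15,
            maxDivergence > 0, maxDivergence < 1,
            minHitLength >= 1, mergeGap >= 0, xdrop > 0)
  p <- list(kmerSize = as.integer(kmerSize), maxDivergence = maxDivergence,
            minHitLength = as.integer(minHitLength), minScore = minScore,
            bothStrands = isTRUE(bothStrands), mergeGap = as.integer(mergeGap),
            xdrop = xdrop,
            mismatchPenalty = (1 - maxDivergence) / maxDivergence)
  p$gapPenalty <- p$mismatchPenalty + 1
  if (is.null(p$minScore))  # 80 bp at 80% identity sits exactly on the bar
    p$minScore <- 64 - 16 * p$mismatchPenalty
  class(p) <- "MaskParams"
  p
}

.asCharSeqs <- function(x) {
  if (is(x, "TELibrary")) x <- seqs(x)
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is(x, "DNAString")) {
    out <- setNames(as.character(x), "query")
  } else out <- x
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

## Raw seed-and-extend hits of queries against subjects, both strands.
## Query coordinates for "-" hits are in the reverse-complemented query
## frame (coverage widths are orientation-invariant).
.seedHits <- function(subjects, queries, params) {
  empty <- data.frame(seqId = character(), qname = character(),
                      sStart = integer(), sEnd = integer(),
                      qStart = integer(), qEnd = integer(),
                      matches = integer(), mismatches = integer(),
                      gaps = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (length(subjects) == 0 || length(queries) == 0) return(empty)
  run <- function(qs, strand) {
    h <- .seed_extend_cpp(unname(subjects), unname(qs), params$kmerSize,
                          params$mismatchPenalty, params$gapPenalty,
                          params$xdrop)
    if (nrow(h) == 0) return(empty)
    data.frame(seqId = names(subjects)[h$subject],
               qname = names(qs)[h$query],
               sStart = h$sStart, sEnd = h$sEnd,
               qStart = h$qStart, qEnd = h$qEnd,
               matches = h$matches, mismatches = h$mismatches,
               gaps = h$gaps, strand = strand, stringsAsFactors = FALSE)
  }
  out <- run(queries, "+")
  if (params$bothStrands) {
    rc <- as.character(reverseComplement(DNAStringSet(queries)))
    names(rc) <- names(queries)
    out <- rbind(out, run(rc, "-"))
  }
  out
}

## Merge collinear hits of the same (subject, query, strand) separated by
## at most maxGap bp on both sequences into chains, and derive per-chain
## statistics. identity is computed over aligned columns
## (matches + mismatches + gaps), not over unaligned chain gaps.
.chainHits <- function(hits, maxGap, scorePenalty = 1.5) {
  if (nrow(hits) == 0) {
    return(cbind(hits[, c("seqId", "qname", "strand")],
                 data.frame(sStart = integer(), sEnd = integer(),
                            qStart = integer(), qEnd = integer(),
                            matches = integer(), mismatches = integer(),
                            gaps = integer(), alnCols = integer(),
                            identity = numeric(), score = numeric(),
                            nfrag = integer())))
  }
  key <- paste(hits$seqId, hits$qname, hits$strand, sep = "\r")
  parts <- split(seq_len(nrow(hits)), key)
  res <- vector("list", length(parts))
  for (pi in seq_along(parts)) {
    idx <- parts[[pi]]
    h <- hits[idx[order(hits$sStart[idx], hits$qStart[idx])], , drop = FALSE]
    n <- nrow(h)
    chains <- list()
    cur <- h[1, ]
    for (i in seq_len(n)[-1]) {
      sGap <- h$sStart[i] - cur$sEnd - 1L
      qGap <- h$qStart[i] - cur$qEnd - 1L
      if (sGap <= maxGap && sGap >= -20L && qGap <= maxGap && qGap >= -20L) {
        cur$sEnd <- max(cur$sEnd, h$sEnd[i])
        cur$qEnd <- max(cur$qEnd, h$qEnd[i])
        cur$matches <- cur$matches + h$matches[i]
        cur$mismatches <- cur$mismatches + h$mismatches[i]
        cur$gaps <- cur$gaps + h$gaps[i]
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- h[i, ]
      }
    }
    chains[[length(chains) + 1L]] <- cur
    res[[pi]] <- do.call(rbind, chains)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$alnCols <- out$matches + out$mismatches + out$gaps
  out$identity <- pmin(1, out$matches / out$alnCols)
  out$score <- out$matches - scorePenalty * (out$mismatches + out$gaps)
  out$nfrag <- 1L  # informational; collapsed chains keep aggregate counts
  out
}

## Chains of library-vs-subject homology, filtered to the masker thresholds.
.maskChains <- function(subjects, queries, params) {
  ch <- .chainHits(.seedHits(subjects, queries, params), params$mergeGap,
                   params$mismatchPenalty)
  keep <- ch$identity >= 1 - params$maxDivergence &
    (ch$sEnd - ch$sStart + 1L) >= params$minHitLength &
    ch$score >= params$minScore
  ch[keep, , drop = FALSE]
}

#' Annotate (mask) a genome with a TE library
#'
#' Finds all homologous copies of the library entries in the genome with
#' k-mer seeded greedy extension (both strands), merges collinear fragments,
#' and resolves overlaps into a flat annotation: the higher-scoring hit
#' wins, ties go to the longer hit and then to the lexicographically
#' smaller entry name; losing hits are trimmed to their non-overlapping
#' remainder and kept only if still at least `minHitLength` bp. Whitelisted
#' intervals receive no records.
#'
#' @param genome a `DNAStringSet`.
#' @param library a [TELibrary].
#' @param params a [maskParams()] list.
#' @param whitelist optional `GRanges` of intervals excluded from masking.
#' @return a resolved [TEAnnotation]; records carry entry name, class,
#'   identity and score, with strand `-` for reverse-complement hits
#'   (coordinates always refer to the forward strand).
#' @export
maskGenome <- function(genome, library, params = maskParams(),
                       whitelist = NULL) {
  stopifnot(is(library, "TELibrary"), length(library) > 0)
  if (min(width(seqs(library))) < params$kmerSize)
    stop("kmerSize (", params$kmerSize,
         ") exceeds the shortest library entry")
  emptyAnn <- TEAnnotation(GRanges(), resolved = TRUE)
  if (length(genome) == 0) return(emptyAnn)
  ch <- .maskChains(.asCharSeqs(genome), .asCharSeqs(library), params)
  if (nrow(ch) == 0) return(emptyAnn)

  info <- libInfo(library)
  ord <- order(-ch$score, -(ch$sEnd - ch$sStart + 1L), ch$qname)
  ch <- ch[ord, , drop = FALSE]
  wl <- list()
  if (!is.null(whitelist)) {
    wgr <- if (is(whitelist, "TEAnnotation")) granges(whitelist) else whitelist
    wl <- split(IRanges(start(wgr), end(wgr)), as.character(seqnames(wgr)))
  }
  covered <- list()
  recs <- list()
  for (i in seq_len(nrow(ch))) {
    sq <- ch$seqId[i]
    ir <- IRanges(ch$sStart[i], ch$sEnd[i])
    if (!is.null(wl[[sq]]))
      ir <- IRanges::setdiff(ir, wl[[sq]])
    if (!is.null(covered[[sq]]))
      ir <- IRanges::setdiff(ir, covered[[sq]])
    ir <- ir[width(ir) >= params$minHitLength]
    if (length(ir) == 0) next
    covered[[sq]] <- IRanges::reduce(c(if (is.null(covered[[sq]]))
      IRanges() else covered[[sq]], ir))
    recs[[length(recs) + 1L]] <- data.frame(
      seqId = sq, start = start(ir), end = end(ir),
      qname = ch$qname[i], strand = ch$strand[i],
      identity = ch$identity[i], score = ch$score[i],
      stringsAsFactors = FALSE)
  }
  if (length(recs) == 0) return(emptyAnn)
  tab <- do.call(rbind, recs)
  m <- match(tab$qname, info$name)
  gr <- GRanges(tab$seqId, IRanges(tab$start, tab$end), strand = tab$strand,
                Name = tab$qname, teClass = info$class[m],
                classification = info$classification[m],
                identity = tab$identity, score = tab$score)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  TEAnnotation(gr, resolved = TRUE)
}

#' Count full-length genomic copies of query sequences
#'
#' Counts non-overlapping genomic hits that cover at least `minCoverage`
#' of the query at `minIdentity` or better, searching both strands.
#' Vectorized over queries (a single genome scan serves all of them).
#'
#' @param genome a `DNAStringSet`.
#' @param queries a named character vector, `DNAStringSet`, or [TELibrary];
#'   each query must be at least `kmerSize` long.
#' @param minIdentity minimum alignment identity (default 0.8).
#' @param minCoverage minimum fraction of the query covered (default 0.95).
#' @param params a [maskParams()] list.
#' @return a named integer vector of copy counts, one per query.
#' @export
copyNumber <- function(genome, queries, minIdentity = 0.8,
                       minCoverage = 0.95, params = maskParams()) {
  qs <- .asCharSeqs(queries)
  if (any(nchar(qs) < params$kmerSize))
    stop("all queries must be at least kmerSize (", params$kmerSize, ") bp")
  counts <- setNames(integer(length(qs)), names(qs))
  ch <- .chainHits(.seedHits(.asCharSeqs(genome), qs, params),
                   params$mergeGap)
  if (nrow(ch) == 0) return(counts)
  qlen <- nchar(qs)
  keep <- ch$identity >= minIdentity &
    (ch$qEnd - ch$qStart + 1L) >= minCoverage * qlen[ch$qname]
  ch <- ch[keep, , drop = FALSE]
  for (qn in unique(ch$qname)) {
    sub <- ch[ch$qname == qn, , drop = FALSE]
    total <- 0L
    for (sq in unique(sub$seqId)) {
      s2 <- sub[sub$seqId == sq, , drop = FALSE]
      # greedy interval scheduling by end point: maximal non-overlapping set
      o <- order(s2$sEnd)
      lastEnd <- -1L
      for (j in o) {
        if (s2$sStart[j] > lastEnd) {
          total <- total + 1L
          lastEnd <- s2$sEnd[j]
        }
      }
    }
    counts[qn] <- total
  }
  counts
}

#' The 80-80-80 homology test
#'
#' Tests whether a query sequence is homologous to any subject under the
#' classic redundancy criterion: at least `minCoverage` (default 80%) of
#' the query aligned at `minIdentity` (default 80%) or better, with an
#' aligned length of at least `minLength` bp (default 80). All thresholds
#' are inclusive. Coverage may accumulate over collinear non-overlapping
#' local alignments to the same subject (fragmented homology is the norm
#' for diverged TEs). A subject with the same name as the query is ignored.
#'
#' @param query a single sequence (character, `DNAString`, or a
#'   length-one [TELibrary]).
#' @param subjects the subject library ([TELibrary], `DNAStringSet` or
#'   named character vector).
#' @param minCoverage,minIdentity,minLength the three 80s, inclusive.
#' @param chainGap maximum unaligned gap (bp) bridged when accumulating
#'   collinear local alignments.
#' @param params a [maskParams()] list.
#' @return `TRUE` or `FALSE`.
#' @export
matches808080 <- function(query, subjects, minCoverage = 0.8,
                          minIdentity = 0.8, minLength = 80L,
                          chainGap = 100L, params = maskParams()) {
  q <- .asCharSeqs(query)
  stopifnot(length(q) == 1)
  subj <- .asCharSeqs(subjects)
  subj <- subj[names(subj) != names(q)]
  if (length(subj) == 0) return(FALSE)
  ch <- .chainHits(.seedHits(subj, q, params), chainGap)
  if (nrow(ch) == 0) return(FALSE)
  qlen <- nchar(q)
  any(ch$identity >= minIdentity & ch$alnCols >= minLength &
        (ch$qEnd - ch$qStart + 1L) >= minCoverage * qlen)
}

## All qualifying homology chains among the entries of one library:
## rows are (subject entry, query entry) chains with identity/coverage
## statistics. Self pairs excluded. Used by the redundancy, richness and
## nested-excision filters.
.pairChains <- function(lib, minIdentity = 0.8, minLength = 80L,
                        chainGap = 100L, params = maskParams()) {
  sq <- .asCharSeqs(lib)
  ch <- .chainHits(.seedHits(sq, sq, params), chainGap)
  ch <- ch[ch$seqId != ch$qname, , drop = FALSE]
  ch <- ch[ch$identity >= minIdentity & ch$alnCols >= minLength, ,
           drop = FALSE]
  ch$qCov <- (ch$qEnd - ch$qStart + 1L) / nchar(sq)[ch$qname]
  ch$sCov <- (ch$sEnd - ch$sStart + 1L) / nchar(sq)[ch$seqId]
  ch
}

#' Fraction of a sequence covered by tandem repeats
#'
#' Detects tandem arrays of period 1-500 bp with at least two copies and
#' array identity of 80% or more, by k-mer self-distance periodicity
#' detection: candidate periods come from the distances between repeated
#' k-mers (all periods up to 12 bp are always tested), and for each period
#' `p` the positions where a `max(p, 12)`-wide window of the lag-`p`
#' self-match profile reaches 80% matches mark a tandem array covering
#' window plus period. Returns the fraction of bases covered by any array.
#'
#' @param seq a sequence (character or `DNAString`).
#' @param maxPeriod maximum array period in bp (default 500).
#' @param minIdentity minimum array identity (default 0.8).
#' @return a fraction in \[0, 1\].
#' @examples
#' tandemFraction(strrep("TA", 200))  # ~1
#' @export
tandemFraction <- function(seq, maxPeriod = 500L, minIdentity = 0.8) {
  s <- utf8ToInt(toupper(as.character(seq)[1]))
  n <- length(s)
  if (n < 13L) return(0)
  periods <- seq_len(min(12L, n %/% 2L))
  k <- 8L
  if (n >= 3L * k) {
    km <- s[1:(n - k + 1)]
    for (j in 1:(k - 1)) km <- km * 5L + s[(1 + j):(n - k + 1 + j)]
    pos <- split(seq_along(km), km)
    pos <- pos[lengths(pos) >= 2L]
    if (length(pos) > 0) {
      d <- unlist(lapply(pos, diff), use.names = FALSE)
      d <- d[d <= min(maxPeriod, n %/% 2L)]
      if (length(d) > 0) {
        votes <- table(d)
        periods <- sort(unique(c(periods,
          as.integer(names(votes)[votes >= 2L]))))
      }
    }
  }
  cov <- logical(n)
  for (p in periods) {
    W <- max(p, 12L)
    if (n - p < W) next
    m <- s[1:(n - p)] == s[(p + 1):n]
    cs <- c(0, cumsum(m))
    nm <- n - p
    wsum <- cs[(W + 1):(nm + 1)] - cs[1:(nm - W + 1)]
    flag <- which(wsum >= minIdentity * W)
    for (i in flag) cov[i:min(n, i + W + p - 1L)] <- TRUE
  }
  mean(cov)
}

#' Bases of a short window covered by simple sequence repeats
#'
#' Counts the bases covered by perfect repeat arrays of motif length 1 to
#' `maxPeriod` with at least 3 copies and at least 6 bp total length;
#' overlapping arrays are merged.
#'
#' @param window a short sequence (at most a few hundred bp).
#' @param maxPeriod maximum motif length (default 6).
#' @return integer bp covered.
#' @examples
#' ssrSpan("ATATATATATATATATATAT")  # 20
#' ssrSpan("AAAAAAGCGTACGATCGTAC")  # 6
#' @export
ssrSpan <- function(window, maxPeriod = 6L) {
  s <- utf8ToInt(toupper(as.character(window)[1]))
  n <- length(s)
  if (n < 6L) return(0L)
  cov <- logical(n)
  for (p in seq_len(min(maxPeriod, n - 1L))) {
    m <- s[1:(n - p)] == s[(p + 1):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= 2L * p & (r$lengths + p) >= 6L
    for (j in which(ok)) cov[starts[j]:(ends[j] + p)] <- TRUE
  }
  sum(cov)
}

## Intervals of a sequence covered by perfect SSR arrays (same rule as
## ssrSpan), as an IRanges; used for terminal trimming.
.ssrRanges <- function(x, maxPeriod = 6L) {
  s <- utf8ToInt(toupper(as.character(x)[1]))
  n <- length(s)
  if (n < 6L) return(IRanges())
  out <- IRanges()
  for (p in seq_len(min(maxPeriod, n - 1L))) {
    m <- s[1:(n - p)] == s[(p + 1):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= 2L * p & (r$lengths + p) >= 6L
    if (any(ok))
      out <- c(out, IRanges(starts[ok], ends[ok] + p))
  }
  IRanges::reduce(out)
}
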