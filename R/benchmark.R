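## Base-pair-resolution benchmarking of a test TE annotation against a
## curated one: confusion counts over the whole genome, the six derived
## metrics, complete/fragmented copy classification, and classification
## consistency (misclassification) rates.

#' @rdname ConfusionCounts-class
#' @param tp,fp,fn,tn non-negative base counts.
#' @export
ConfusionCounts <- function(tp, fp, fn, tn)
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (bp): TP", object@tp, " FP", object@fp,
      " FN", object@fn, " TN", object@tn, "\n")
})

#' @rdname ConfusionCounts-class
#' @param x a `ConfusionCounts`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ConfusionCounts", function(x, ...)
  data.frame(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))

setMethod("show", "MetricSet", function(object) {
  v <- as.data.frame(object)
  cat("MetricSet:\n")
  print(round(v, 4))
})

#' @rdname MetricSet-class
#' @param x a `MetricSet`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "MetricSet", function(x, ...)
  data.frame(sensitivity = x@sensitivity, specificity = x@specificity,
             accuracy = x@accuracy, precision = x@precision,
             fdr = x@fdr, f1 = x@f1))

## per-chromosome reduced IRanges of an annotation (optionally class subset)
.reducedByChrom <- function(ann, classes = NULL) {
  gr <- if (is(ann, "TEAnnotation")) granges(ann) else ann
  if (!is.null(classes))
    gr <- gr[mcols(gr)$teClass %in% classes]
  lst <- split(IRanges(start(gr), end(gr)), as.character(seqnames(gr)))
  lapply(lst, IRanges::reduce)
}

#' Base-pair confusion counts of a test annotation against a curated one
#'
#' The curated annotation restricted to `targetClasses` defines the target
#' base set T; the test annotation (all records) defines the predicted set
#' P. Then `tp = |T intersect P|`, `fn = |T \ P|`, `fp = |P \ T|`, and
#' `tn` is the remainder of the genome, all in bp and strand-insensitive.
#' The four counts always sum to the genome length.
#'
#' @param curated the curated [TEAnnotation] (ground truth).
#' @param test the test [TEAnnotation].
#' @param targetClasses character vector of target classes (subset of
#'   `LTR`, `nonLTR`, `TIR`, `Helitron`, `nonTE`); default all four TE
#'   classes.
#' @param genome a `DNAStringSet` (defines total length and bounds).
#' @return a [ConfusionCounts].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 100)))
#' cur <- TEAnnotation(GenomicRanges::GRanges("chr1:11-30",
#'   Name = "t", teClass = "LTR"))
#' tst <- TEAnnotation(GenomicRanges::GRanges("chr1:21-40",
#'   Name = "t", teClass = "LTR"))
#' as.data.frame(confusionCounts(cur, tst, "LTR", g))  # 10/10/10/70
#' @export
confusionCounts <- function(curated, test,
                            targetClasses = c("LTR", "nonLTR", "TIR",
                                              "Helitron"),
                            genome) {
  .checkBounds(granges(curated), genome)
  .checkBounds(granges(test), genome)
  total <- sum(as.numeric(width(genome)))
  Tr <- .reducedByChrom(curated, targetClasses)
  Pr <- .reducedByChrom(test)
  tp <- fn <- fp <- 0
  for (sq in union(names(Tr), names(Pr))) {
    t1 <- if (is.null(Tr[[sq]])) IRanges() else Tr[[sq]]
    p1 <- if (is.null(Pr[[sq]])) IRanges() else Pr[[sq]]
    tp <- tp + sum(width(IRanges::intersect(t1, p1)))
    fn <- fn + sum(width(IRanges::setdiff(t1, p1)))
    fp <- fp + sum(width(IRanges::setdiff(p1, t1)))
  }
  ConfusionCounts(tp, fp, fn, total - tp - fn - fp)
}

#' Derive the six benchmarking metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP); accuracy =
#' (TP+TN)/total; precision = TP/(TP+FP); FDR = FP/(TP+FP); F1 = the
#' harmonic mean of precision and sensitivity. Any 0/0 ratio is undefined
#' and propagates as `NA` (serialized as "NA", never as 0).
#'
#' @param counts a [ConfusionCounts].
#' @return a [MetricSet].
#' @examples
#' as.data.frame(computeMetrics(ConfusionCounts(10, 10, 10, 70)))
#' @export
computeMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  acc <- rat(tp + tn, tp + fp + fn + tn)
  prec <- rat(tp, tp + fp)
  fdr <- rat(fp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  new("MetricSet", sensitivity = sens, specificity = spec, accuracy = acc,
      precision = prec, fdr = fdr, f1 = f1)
}

#' Classify annotated copies of each library entry as complete or fragmented
#'
#' Records attributed to the same entry and separated by at most
#' `mergeGap` bp are merged into regions; a region whose aligned bases
#' exceed `completeThreshold` (strictly more than 80% by default) of the
#' entry length counts as a complete copy, otherwise as fragmented.
#'
#' @param library the curated [TELibrary] the annotation refers to.
#' @param annotation a [TEAnnotation]; a record referencing an entry
#'   absent from `library` is an error.
#' @param mergeGap region merge distance in bp (default 50, matching the
#'   masker's merge distance).
#' @param completeThreshold strict lower bound on the covered fraction for
#'   a complete copy (default 0.8).
#' @return a data.frame with columns `entry`, `complete`, `fragmented`.
#' @export
classifyCopies <- function(library, annotation, mergeGap = 50L,
                           completeThreshold = 0.8) {
  gr <- granges(annotation)
  nm <- mcols(gr)$Name
  unknown <- setdiff(unique(nm), names(library))
  if (length(unknown) > 0)
    stop("annotation references unknown entries: ",
         paste(unknown, collapse = ", "))
  lens <- setNames(width(seqs(library)), names(library))
  out <- data.frame(entry = names(library),
                    complete = 0L, fragmented = 0L,
                    stringsAsFactors = FALSE)
  for (en in unique(nm)) {
    sub <- gr[nm == en]
    for (sq in unique(as.character(seqnames(sub)))) {
      ir <- IRanges(start(sub)[as.character(seqnames(sub)) == sq],
                    end(sub)[as.character(seqnames(sub)) == sq])
      regions <- IRanges::reduce(ir, min.gapwidth = mergeGap + 1L)
      ov <- IRanges::findOverlaps(ir, regions)
      aligned <- tapply(width(ir)[S4Vectors::queryHits(ov)],
                        S4Vectors::subjectHits(ov), sum)
      complete <- sum(aligned > completeThreshold * lens[en])
      i <- match(en, out$entry)
      out$complete[i] <- out$complete[i] + complete
      out$fragmented[i] <- out$fragmented[i] + length(regions) - complete
    }
  }
  out
}

#' TE classification consistency (misclassification) rates
#'
#' Misclassification is defined at the base-pair level as TE sequence
#' annotated with inconsistent subclasses (LTR retrotransposon, TIR
#' transposon, Helitron, non-LTR). Two modes:
#'
#' * reference mode (`reference` supplied): a base annotated in both
#'   annotations is inconsistent iff the two class labels differ. The
#'   per-class rate divides inconsistent bases of a reference class by the
#'   total reference bases of that class; the overall rate divides total
#'   inconsistent bases by the bases annotated in both.
#' * self mode (`reference = NULL`): within one (unresolved) annotation,
#'   bases covered by overlapping records of different classes are
#'   inconsistent; the overall rate divides them by all annotated bases.
#'
#' @param annotation the [TEAnnotation] under evaluation.
#' @param reference optional reference [TEAnnotation] with trusted class
#'   labels.
#' @return a list with `perClass` (named numeric, reference mode only) and
#'   `overall`; `mode` records which definition was used.
#' @export
misclassificationRate <- function(annotation, reference = NULL) {
  classes <- c("LTR", "nonLTR", "TIR", "Helitron")
  if (!is.null(reference)) {
    refBy <- lapply(classes, function(cl)
      .reducedByChrom(reference, cl))
    names(refBy) <- classes
    testBy <- lapply(classes, function(cl)
      .reducedByChrom(annotation, cl))
    names(testBy) <- classes
    inter <- function(a, b) {
      tot <- 0
      for (sq in intersect(names(a), names(b)))
        tot <- tot + sum(width(IRanges::intersect(a[[sq]], b[[sq]])))
      tot
    }
    perClass <- setNames(numeric(length(classes)), classes)
    incTot <- 0; bothTot <- 0
    for (rc in classes) {
      inc <- 0; both <- 0
      for (tc in classes) {
        bp <- inter(refBy[[rc]], testBy[[tc]])
        both <- both + bp
        if (tc != rc) inc <- inc + bp
      }
      perClass[rc] <- if (both > 0) inc / both else NA_real_
      incTot <- incTot + inc; bothTot <- bothTot + both
    }
    list(perClass = perClass,
         overall = if (bothTot > 0) incTot / bothTot else NA_real_,
         mode = "reference")
  } else {
    gr <- granges(annotation)
    allBy <- .reducedByChrom(annotation)
    classBy <- lapply(classes, function(cl) .reducedByChrom(annotation, cl))
    names(classBy) <- classes
    incTot <- 0
    annTot <- sum(vapply(allBy, function(x) sum(width(x)), numeric(1)))
    pairs <- utils::combn(classes, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- classBy[[pairs[1, j]]]; b <- classBy[[pairs[2, j]]]
      for (sq in intersect(names(a), names(b)))
        incTot <- incTot +
          sum(width(IRanges::intersect(a[[sq]], b[[sq]])))
    }
    list(perClass = NULL,
         overall = if (annTot > 0) incTot / annTot else NA_real_,
         mode = "self")
  }
}
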