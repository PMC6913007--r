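#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom BiocGenerics width start end strand as.data.frame
#' @importFrom IRanges IRanges reduce
#' @importFrom GenomicRanges GRanges granges seqnames
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet subseq replaceAmbiguities
NULL

## Top-level TE classification used throughout: the five benchmark categories.
TE_CLASSES <- c("LTR", "nonLTR", "TIR", "Helitron", "nonTE")

#' TELibrary: a set of named TE exemplar sequences with classification
#'
#' A `TELibrary` holds TE consensus/exemplar sequences (a
#' [Biostrings::DNAStringSet]) together with per-entry classification and
#' structural metadata. The classification follows the five-way top level
#' used for benchmarking (`LTR`, `nonLTR`, `TIR`, `Helitron`, `nonTE`),
#' with optional subclass (e.g. `LINE`, `SINE`), superfamily (e.g. `hAT`)
#' and a MITE flag (miniature inverted-repeat element, a short non-autonomous
#' TIR element). Serialized FASTA headers follow the RepeatMasker convention
#' `name#Class/Subclass`.
#'
#' @slot seqs a `DNAStringSet` of exemplar sequences (alphabet ACGTN).
#' @slot info a [S4Vectors::DataFrame] with one row per entry and columns
#'   `name`, `class`, `subclass`, `superfamily`, `isMITE`, `stage`
#'   (`raw`, `stage0`, `stage1` or `final`), `tsdLength` (target-site
#'   duplication length in bp, `NA` if unknown/none) and `score`
#'   (detector prediction score, `NA` if absent).
#'
#' @seealso [TELibrary()], [readTELibrary()], [parseRMName()]
#' @exportClass TELibrary
setClass("TELibrary", representation(seqs = "DNAStringSet", info = "DataFrame"))

setValidity("TELibrary", function(object) {
  msg <- NULL
  n <- length(object@seqs)
  if (nrow(object@info) != n)
    msg <- c(msg, "info must have one row per sequence")
  req <- c("name", "class", "subclass", "superfamily", "isMITE", "stage",
           "tsdLength", "score")
  if (!all(req %in% colnames(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(object@info$name))
      msg <- c(msg, "entry names must be unique")
    if (!all(object@info$class %in% TE_CLASSES))
      msg <- c(msg, paste("class must be one of:",
                          paste(TE_CLASSES, collapse = ", ")))
    if (any(object@info$isMITE & object@info$class != "TIR"))
      msg <- c(msg, "MITE flag implies class TIR")
  }
  if (n > 0 && any(width(object@seqs) < 1))
    msg <- c(msg, "all sequences must be non-empty")
  if (is.null(msg)) TRUE else msg
})

#' TEAnnotation: genomic intervals attributed to TE library entries
#'
#' Wraps a [GenomicRanges::GRanges] whose metadata columns carry the library
#' entry each interval is attributed to (`Name`), its top-level class
#' (`teClass`), the full `Class/Subclass` classification string
#' (`classification`), the alignment `identity` (fraction, `NA` when
#' unknown) and a `score`. Coordinates are 1-based closed (the
#' GRanges convention); BED (0-based half-open) and GFF3 conversion happen
#' only at the I/O boundary ([readAnnotation()], [writeAnnotation()]).
#'
#' @slot gr the underlying `GRanges`.
#' @slot resolved `TRUE` when no two records on the same sequence overlap.
#'
#' @seealso [TEAnnotation()], [maskGenome()], [confusionCounts()]
#' @exportClass TEAnnotation
setClass("TEAnnotation",
         representation(gr = "GRanges", resolved = "logical"))

setValidity("TEAnnotation", function(object) {
  msg <- NULL
  req <- c("Name", "teClass", "classification", "identity", "score")
  if (!all(req %in% colnames(mcols(object@gr))))
    msg <- c(msg, paste("gr metadata must have columns:",
                        paste(req, collapse = ", ")))
  if (length(object@resolved) != 1L || is.na(object@resolved))
    msg <- c(msg, "resolved must be TRUE or FALSE")
  else if (isTRUE(object@resolved) && length(object@gr) > 1L) {
    cov <- sum(width(reduce(granges(object@gr), ignore.strand = TRUE)))
    if (cov != sum(width(object@gr)))
      msg <- c(msg, "resolved annotation must have non-overlapping records")
  }
  if (is.null(msg)) TRUE else msg
})

#' CandidateSet: raw TE candidates anchored to genomic coordinates
#'
#' Couples candidate entries (a [TELibrary] at stage `raw`) with their
#' genomic anchor and up to 60 bp of flanking sequence on each side, so
#' terminal-structure and target-site filters can inspect the insertion
#' context. Candidates without a genomic anchor (e.g. constructed
#' tandem-repeat contaminants) have `NA` coordinates and empty flanks.
#'
#' @slot entries a [TELibrary] of candidate sequences.
#' @slot anchors a `DataFrame` with columns `seqId`, `start`, `end`
#'   (1-based closed, `NA` when unanchored), `leftFlank`, `rightFlank`
#'   (character, possibly shorter than requested at contig edges),
#'   `corruption` (simulator tag: `"true"`, `"boundary_shift"`,
#'   `"mislabel"`, `"tandem"`, `"short"`, `"helitron_motif"`,
#'   `"nested_span"`), `sourceEntry` (truth entry the sequence derives
#'   from, `NA` for constructed junk) and `verdict` (filled by
#'   [terminalCopyFilter()]).
#' @exportClass CandidateSet
setClass("CandidateSet",
         representation(entries = "TELibrary", anchors = "DataFrame"))

setValidity("CandidateSet", function(object) {
  msg <- NULL
  if (nrow(object@anchors) != length(object@entries@seqs))
    msg <- c(msg, "anchors must have one row per candidate entry")
  req <- c("seqId", "start", "end", "leftFlank", "rightFlank",
           "corruption", "sourceEntry", "verdict")
  if (!all(req %in% colnames(object@anchors)))
    msg <- c(msg, paste("anchors must have columns:",
                        paste(req, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' ConfusionCounts: base-pair level confusion matrix of two annotations
#'
#' Genome-wide base counts comparing a test annotation against a curated
#' annotation restricted to a target class subset: `tp` (curated target
#' bases that are test-annotated), `fp` (test-annotated bases outside the
#' target), `fn` (missed target bases) and `tn` (the remainder). The four
#' counts always sum to the genome length.
#'
#' @slot tp,fp,fn,tn non-negative base counts.
#' @seealso [confusionCounts()], [computeMetrics()]
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
         representation(tp = "numeric", fp = "numeric",
                        fn = "numeric", tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4L || anyNA(v) || any(v < 0))
    "tp, fp, fn, tn must be single non-negative numbers"
  else TRUE
})

#' MetricSet: the six benchmarking metrics
#'
#' Sensitivity, specificity, accuracy, precision, FDR and F1 derived from a
#' [ConfusionCounts] object. A metric whose defining ratio is 0/0 is
#' undefined and stored as `NA` (never coerced to 0).
#'
#' @slot sensitivity,specificity,accuracy,precision,fdr,f1 numbers in
#'   \[0, 1\] or `NA` when undefined.
#' @seealso [computeMetrics()]
#' @exportClass MetricSet
setClass("MetricSet",
         representation(sensitivity = "numeric", specificity = "numeric",
                        accuracy = "numeric", precision = "numeric",
                        fdr = "numeric", f1 = "numeric"))

#' GroundTruth: simulated exemplars, truth annotation and insertion metadata
#'
#' The complete ground truth of a simulated genome: the exemplar library the
#' copies were drawn from, the resolved truth annotation (nested insertions
#' split their host record in two), and per-insertion metadata.
#'
#' @slot exemplars the [TELibrary] of family exemplars.
#' @slot annotation the resolved truth [TEAnnotation]; its `insertionId`
#'   metadata column links split host records back to one insertion event.
#' @slot insertions a `DataFrame` with one row per insertion event:
#'   `insertionId`, `entry`, `class`, `seqId`, `intact` (FALSE when
#'   truncated), `nestedIn` (host insertionId or `NA`), `tsdLength`,
#'   `insertedLength` (element bases placed, post-mutation).
#' @slot tsdBases total bases added as target-site duplications (host
#'   bookkeeping, used by conservation checks).
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(exemplars = "TELibrary", annotation = "TEAnnotation",
                        insertions = "DataFrame", tsdBases = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  nm <- mcols(object@annotation@gr)$Name
  if (!all(nm %in% object@exemplars@info$name))
    msg <- c(msg, "every truth record must reference an exemplar entry")
  if (is.null(msg)) TRUE else msg
})
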