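## Sequence and annotation I/O: FASTA via Biostrings, BED/GFF3 via
## rtracklayer, RepeatMasker-style `name#Class/Subclass` header convention.
## Internal coordinates are 1-based closed everywhere (the GRanges
## convention); BED's 0-based half-open system exists only at the I/O
## boundary.

#' Parse RepeatMasker-style library headers
#'
#' Splits a FASTA header at the first `#` and maps the RepeatMasker
#' classification string onto the five-way top-level taxonomy used for
#' benchmarking: `LTR/*` to LTR; `LINE/*` and `SINE/*` to nonLTR;
#' `DNA/*`, `TIR/*` and `MITE/*` to TIR (with `MITE/*` setting the MITE
#' flag); `DNA/Helitron` and `RC/Helitron` to Helitron. A header without
#' `#`, or with an unrecognized classification, maps to `nonTE/Unknown` —
#' parsing is deliberately lenient and never errors.
#'
#' @param headers character vector of header strings (without the `>`).
#' @return a [S4Vectors::DataFrame] with columns `name`, `class`,
#'   `subclass`, `superfamily`, `isMITE` and `classification` (the raw
#'   string after `#`, normalized to `Unknown` when absent).
#' @examples
#' parseRMName(c("fam1#LTR/Gypsy", "mite1#MITE/Tourist", "seqA"))
#' @export
parseRMName <- function(headers) {
  headers <- as.character(headers)
  stopifnot(all(nzchar(headers)))
  hash <- regexpr("#", headers, fixed = TRUE)
  name <- ifelse(hash > 0, substr(headers, 1L, hash - 1L), headers)
  cls <- ifelse(hash > 0, substring(headers, hash + 1L), "Unknown")
  cls[!nzchar(cls)] <- "Unknown"
  slash <- regexpr("/", cls, fixed = TRUE)
  top <- ifelse(slash > 0, substr(cls, 1L, slash - 1L), cls)
  sub <- ifelse(slash > 0, substring(cls, slash + 1L), NA_character_)

  class <- rep("nonTE", length(headers))
  subclass <- rep(NA_character_, length(headers))
  superfamily <- rep(NA_character_, length(headers))
  isMITE <- rep(FALSE, length(headers))

  is_hel <- (top %in% c("DNA", "RC") & !is.na(sub) & sub == "Helitron") |
    top == "Helitron"
  class[is_hel] <- "Helitron"
  is_ltr <- !is_hel & top == "LTR"
  class[is_ltr] <- "LTR"
  superfamily[is_ltr] <- sub[is_ltr]
  is_nl <- !is_hel & top %in% c("LINE", "SINE", "nonLTR")
  class[is_nl] <- "nonLTR"
  subclass[is_nl] <- ifelse(top[is_nl] == "nonLTR", sub[is_nl], top[is_nl])
  superfamily[is_nl & top != "nonLTR"] <- sub[is_nl & top != "nonLTR"]
  is_tir <- !is_hel & top %in% c("DNA", "TIR", "MITE")
  class[is_tir] <- "TIR"
  superfamily[is_tir] <- sub[is_tir]
  isMITE[top == "MITE"] <- TRUE

  cls[class == "nonTE"] <- "Unknown"
  subclass[class == "nonTE"] <- "Unknown"
  DataFrame(name = name, class = class, subclass = subclass,
            superfamily = superfamily, isMITE = isMITE, classification = cls)
}

#' Serialize entry classification to a RepeatMasker-style header suffix
#'
#' Inverse of [parseRMName()] on the classification part: returns the
#' `Class/Subclass` string so that the full header is
#' `paste0(name, "#", rmClassification(info))`.
#'
#' @param info a DataFrame with columns `class`, `subclass`, `superfamily`,
#'   `isMITE` (as in [libInfo()]).
#' @return character vector of classification strings.
#' @export
rmClassification <- function(info) {
  n <- nrow(info)
  out <- character(n)
  for (i in seq_len(n)) {
    cl <- info$class[i]; sf <- info$superfamily[i]
    out[i] <- switch(cl,
      LTR = if (is.na(sf)) "LTR" else paste0("LTR/", sf),
      Helitron = "DNA/Helitron",
      TIR = {
        top <- if (isTRUE(info$isMITE[i])) "MITE" else "DNA"
        if (is.na(sf)) top else paste0(top, "/", sf)
      },
      nonLTR = {
        sub <- info$subclass[i]
        if (is.na(sub) || !sub %in% c("LINE", "SINE")) "nonLTR"
        else if (is.na(sf)) sub else paste0(sub, "/", sf)
      },
      "Unknown")
  }
  out
}

#' Construct a TELibrary
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector) of
#'   exemplar sequences; names are parsed with [parseRMName()] unless
#'   `info` is supplied.
#' @param info optional classification DataFrame (see [TELibrary-class]);
#'   missing metadata columns are filled with defaults.
#' @param stage library stage label (`raw`, `stage0`, `stage1`, `final`).
#' @return a [TELibrary].
#' @examples
#' lib <- TELibrary(c("fam1#LTR/Gypsy" = "TGACGTACGTCA", "m1#MITE/Tourist" = "CAGTTTAAACTG"))
#' teClass(lib)
#' @export
TELibrary <- function(seqs, info = NULL, stage = "raw") {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  if (is.null(info)) {
    if (is.null(names(seqs)))
      stop("sequences must be named when no info is supplied")
    info <- parseRMName(names(seqs))
  }
  info <- DataFrame(info)
  if (is.null(info$classification))
    info$classification <- rmClassification(info)
  if (is.null(info$stage)) info$stage <- stage
  if (is.null(info$tsdLength)) info$tsdLength <- NA_integer_
  if (is.null(info$score)) info$score <- NA_real_
  if (is.null(info$isMITE)) info$isMITE <- FALSE
  if (is.null(info$subclass)) info$subclass <- NA_character_
  if (is.null(info$superfamily)) info$superfamily <- NA_character_
  names(seqs) <- info$name
  new("TELibrary", seqs = seqs, info = info)
}

#' @rdname TELibrary-class
#' @export
setMethod("seqs", "TELibrary", function(x) x@seqs)

#' @rdname TELibrary-class
#' @export
setMethod("libInfo", "TELibrary", function(x) x@info)

#' @rdname TELibrary-class
#' @export
setMethod("teClass", "TELibrary", function(x)
  setNames(x@info$class, x@info$name))

#' @rdname TELibrary-class
#' @export
setMethod("stage", "TELibrary", function(x) x@info$stage)

#' @rdname TELibrary-class
#' @export
setReplaceMethod("stage", "TELibrary", function(x, value) {
  x@info$stage <- value
  x
})

#' @rdname TELibrary-class
#' @export
setMethod("length", "TELibrary", function(x) length(x@seqs))

#' @rdname TELibrary-class
#' @export
setMethod("names", "TELibrary", function(x) x@info$name)

#' @rdname TELibrary-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TELibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$name)
  initialize(x, seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

#' Concatenate TE libraries
#' @param x,... TELibrary objects.
#' @return a combined [TELibrary].
#' @export
setMethod("c", "TELibrary", function(x, ...) {
  libs <- c(list(x), list(...))
  new("TELibrary",
      seqs = do.call(c, lapply(libs, seqs)),
      info = do.call(rbind, lapply(libs, libInfo)))
})

setMethod("show", "TELibrary", function(object) {
  cat("TELibrary with", length(object), "entries\n")
  tab <- table(factor(object@info$class, levels = TE_CLASSES))
  cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  if (length(object) > 0)
    cat("  lengths: ", min(width(object@seqs)), "-",
        max(width(object@seqs)), " bp; stage: ",
        paste(unique(object@info$stage), collapse = ","), "\n", sep = "")
})

## ---- Genome FASTA ----------------------------------------------------------

.readFastaStrict <- function(path) {
  # Biostrings silently drops residues outside the IUPAC alphabet with a
  # warning; promote that to the format error the contract requires
  withCallingHandlers(
    tryCatch(readDNAStringSet(path),
             error = function(e)
               stop("FASTA format error in ", path, ": ",
                    conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("FASTA format error in ", path, ": ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

.normalizeDNA <- function(x, what = "sequence") {
  up <- DNAStringSet(toupper(as.character(x)))
  folded <- replaceAmbiguities(up, new = "N")
  n_folded <- sum(as.numeric(Biostrings::letterFrequency(up, "RYSWKMBDHV")))
  if (n_folded > 0)
    warning(n_folded, " IUPAC ambiguity bases folded to N in ", what)
  folded
}

#' Read a genome FASTA
#'
#' Reads a (possibly gzip-compressed) multi-record DNA FASTA. Sequences are
#' uppercased; IUPAC ambiguity codes other than N are folded to N with a
#' warning; any other residue is a format error. Sequence ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to the FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- .readFastaStrict(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicated sequence ids in ", path)
  if (any(width(x) == 0)) stop("empty sequence in ", path)
  .normalizeDNA(x, basename(path))
}

#' Read a TE library FASTA with RepeatMasker-style headers
#'
#' @param path path to the FASTA file; headers follow the
#'   `name#Class/Subclass` convention ([parseRMName()]).
#' @param stage stage label recorded on the entries.
#' @return a [TELibrary].
#' @export
readTELibrary <- function(path, stage = "raw") {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- .readFastaStrict(path)
  names(x) <- sub("\\s.*$", "", names(x))
  TELibrary(.normalizeDNA(x, basename(path)), stage = stage)
}

#' Write a TE library (or genome) FASTA
#'
#' Library entries are written with `name#Class/Subclass` headers, wrapped
#' at 60 columns.
#'
#' @param x a [TELibrary] or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLibraryFasta <- function(x, path) {
  if (is(x, "TELibrary")) {
    out <- seqs(x)
    names(out) <- paste0(libInfo(x)$name, "#", rmClassification(libInfo(x)))
  } else out <- x
  writeXStringSet(out, path, width = 60L)
  invisible(path)
}

## ---- Annotations (BED / GFF3) ---------------------------------------------

#' Construct a TEAnnotation
#'
#' @param gr a `GRanges`; missing metadata columns (`Name`, `teClass`,
#'   `classification`, `identity`, `score`) are filled with defaults.
#' @param resolved logical; when `NA` (default) it is computed from the
#'   ranges (TRUE iff no two records on the same sequence overlap).
#' @return a [TEAnnotation].
#' @export
TEAnnotation <- function(gr = GRanges(), resolved = NA) {
  mc <- mcols(gr)
  n <- length(gr)
  if (is.null(mc$Name)) mc$Name <- rep(NA_character_, n)
  if (is.null(mc$teClass)) mc$teClass <- rep("nonTE", n)
  if (is.null(mc$classification)) mc$classification <- rep("Unknown", n)
  if (is.null(mc$identity)) mc$identity <- rep(NA_real_, n)
  if (is.null(mc$score)) mc$score <- rep(NA_real_, n)
  req <- c("Name", "teClass", "classification", "identity", "score")
  mcols(gr) <- mc[, c(req, setdiff(colnames(mc), req)), drop = FALSE]
  if (is.na(resolved)) {
    cov <- sum(width(reduce(granges(gr), ignore.strand = TRUE)))
    resolved <- cov == sum(width(gr))
  }
  new("TEAnnotation", gr = gr, resolved = resolved)
}

#' @rdname TEAnnotation-class
#' @export
setMethod("granges", "TEAnnotation", function(x, ...) x@gr)

#' @rdname TEAnnotation-class
#' @export
setMethod("isResolved", "TEAnnotation", function(x) x@resolved)

#' @rdname TEAnnotation-class
#' @export
setMethod("length", "TEAnnotation", function(x) length(x@gr))

setMethod("show", "TEAnnotation", function(object) {
  cat("TEAnnotation with", length(object@gr), "records",
      if (object@resolved) "(resolved)" else "(unresolved)", "\n")
  if (length(object@gr) > 0) {
    bp <- tapply(width(object@gr), mcols(object@gr)$teClass, sum)
    cat("  bp by class:", paste(names(bp), bp, sep = ":", collapse = " "),
        "\n")
  }
})

.checkBounds <- function(gr, genome) {
  if (is.null(genome)) return(invisible(TRUE))
  lens <- setNames(width(genome), names(genome))
  sq <- as.character(seqnames(gr))
  bad <- !(sq %in% names(lens)) | start(gr) < 1 |
    end(gr) > lens[sq]
  if (any(bad)) {
    i <- which(bad)[1]
    stop("record out of genome bounds: ", sq[i], ":", start(gr)[i], "-",
         end(gr)[i])
  }
  invisible(TRUE)
}

#' Read a TE annotation (BED6 or GFF3)
#'
#' BED input is 0-based half-open on disk and converted to the internal
#' 1-based closed convention; the BED name column carries
#' `name#Class/Subclass`. GFF3 input is 1-based closed with attributes
#' `Name`, `Classification` and `Identity`. Gzip-compressed files are
#' accepted.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"BED"` or `"GFF3"`.
#' @param genome optional `DNAStringSet` for coordinate validation; a
#'   record outside the genome raises a bounds error naming it.
#' @return a [TEAnnotation].
#' @export
readAnnotation <- function(path, format = c("auto", "BED", "GFF3"),
                           genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "BED"
      else if (grepl("\\.(gff3?|gff)$", base, ignore.case = TRUE)) "GFF3"
      else stop("cannot guess annotation format of ", path)
  }
  if (format == "BED") {
    gr <- rtracklayer::import(path, format = "BED")
    info <- parseRMName(ifelse(is.na(gr$name), "unknown", gr$name))
    mcols(gr) <- DataFrame(Name = info$name, teClass = info$class,
                           classification = info$classification,
                           identity = NA_real_,
                           score = as.numeric(gr$score))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    mc <- mcols(gr)
    idn <- if (!is.null(mc$Identity)) suppressWarnings(as.numeric(mc$Identity))
           else NA_real_
    cls <- if (!is.null(mc$Classification)) as.character(mc$Classification)
           else "Unknown"
    nm <- if (is.null(mc$Name)) rep("unknown", length(gr)) else
      as.character(mc$Name)
    info <- parseRMName(paste0(nm, "#", cls))
    mcols(gr) <- DataFrame(Name = info$name, teClass = info$class,
                           classification = info$classification,
                           identity = idn, score = as.numeric(mc$score))
  }
  .checkBounds(gr, genome)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  TEAnnotation(gr)
}

#' Write a TE annotation to BED6 or GFF3
#'
#' The BED name column is `name#Class/Subclass` and coordinates are
#' converted to 0-based half-open; GFF3 carries `Name`, `Classification`
#' and `Identity` attributes and stays 1-based closed.
#'
#' @param ann a [TEAnnotation].
#' @param path output path.
#' @param format `"auto"` (by extension), `"BED"` or `"GFF3"`.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(ann, path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED"
      else if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "GFF3"
      else stop("cannot guess annotation format of ", path)
  gr <- granges(ann)
  mc <- mcols(ann@gr)
  if (format == "BED") {
    out <- gr
    mcols(out) <- DataFrame(
      name = paste0(mc$Name, "#", mc$classification),
      score = ifelse(is.na(mc$score), 0, mc$score))
    rtracklayer::export(out, path, format = "BED")
  } else {
    out <- gr
    mcols(out) <- DataFrame(
      source = "TEforge", type = "dispersed_repeat",
      score = mc$score, phase = NA_integer_,
      ID = paste0("rec", seq_along(out)),
      Name = mc$Name, Classification = mc$classification,
      Identity = mc$identity)
    rtracklayer::export(out, path, format = "GFF3")
  }
  invisible(path)
}

## ---- Flanks and candidate sets --------------------------------------------

#' Extract flanking sequences of a genomic interval
#'
#' Returns up to `flank` bases on each side of the 1-based closed interval
#' `[start, end]`, truncated at the sequence edges; the element itself is
#' never included.
#'
#' @param genome a `DNAStringSet`.
#' @param seqId sequence id within `genome`.
#' @param start,end 1-based closed interval.
#' @param flank maximum flank length in bp (default 60).
#' @return a list with character elements `left` and `right`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAAACCCCGGGG"))
#' extractFlanks(g, "chr1", 5, 8, flank = 4)  # list(left="AAAA", right="GGGG")
#' @export
extractFlanks <- function(genome, seqId, start, end, flank = 60L) {
  if (!seqId %in% names(genome)) stop("unknown sequence id: ", seqId)
  L <- length(genome[[seqId]])
  if (is.na(start) || is.na(end) || start < 1 || end > L || start > end)
    stop("invalid interval [", start, ",", end, "] on ", seqId,
         " (length ", L, ")")
  left <- if (start == 1) "" else
    as.character(subseq(genome[[seqId]], max(1L, start - flank), start - 1L))
  right <- if (end == L) "" else
    as.character(subseq(genome[[seqId]], end + 1L, min(L, end + flank)))
  list(left = left, right = right)
}

#' Construct a CandidateSet
#'
#' @param entries a [TELibrary] of candidate sequences (stage `raw`).
#' @param anchors a DataFrame of genomic anchors and flanks (see
#'   [CandidateSet-class]); missing columns are filled with defaults.
#' @return a [CandidateSet].
#' @export
CandidateSet <- function(entries, anchors = NULL) {
  n <- length(entries)
  if (is.null(anchors)) anchors <- DataFrame(seqId = rep(NA_character_, n))
  anchors <- DataFrame(anchors)
  defaults <- list(seqId = NA_character_, start = NA_integer_,
                   end = NA_integer_, leftFlank = NA_character_,
                   rightFlank = NA_character_, corruption = NA_character_,
                   sourceEntry = NA_character_, verdict = NA_character_)
  for (col in names(defaults))
    if (is.null(anchors[[col]])) anchors[[col]] <- rep(defaults[[col]], n)
  new("CandidateSet", entries = entries, anchors = anchors)
}

#' @rdname CandidateSet-class
#' @export
setMethod("entries", "CandidateSet", function(x) x@entries)

#' @rdname CandidateSet-class
#' @export
setMethod("anchors", "CandidateSet", function(x) x@anchors)

#' @rdname CandidateSet-class
#' @export
setMethod("length", "CandidateSet", function(x) length(x@entries))

#' @rdname CandidateSet-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CandidateSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@entries))
  if (is.logical(i)) i <- which(i)
  initialize(x, entries = x@entries[i],
             anchors = x@anchors[i, , drop = FALSE])
})

setMethod("show", "CandidateSet", function(object) {
  cat("CandidateSet with", length(object), "candidates\n")
  tab <- table(object@anchors$corruption, useNA = "ifany")
  if (length(tab) > 0)
    cat("  tags:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})
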