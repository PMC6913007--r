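#' @rdname TELibrary-class
#' @param x a TEforge object.
#' @export
setGeneric("seqs", function(x) standardGeneric("seqs"))

#' @rdname TELibrary-class
#' @export
setGeneric("libInfo", function(x) standardGeneric("libInfo"))

#' @rdname TELibrary-class
#' @export
setGeneric("teClass", function(x) standardGeneric("teClass"))

#' @rdname TELibrary-class
#' @param value replacement value.
#' @export
setGeneric("stage<-", function(x, value) standardGeneric("stage<-"))

#' @rdname TELibrary-class
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname TEAnnotation-class
#' @param x a TEforge object.
#' @export
setGeneric("isResolved", function(x) standardGeneric("isResolved"))

#' @rdname CandidateSet-class
#' @param x a `CandidateSet`.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname CandidateSet-class
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
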