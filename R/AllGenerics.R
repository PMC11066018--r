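#' Accessors for SynIDPDesign classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("motifTable", function(x) standardGeneric("motifTable"))
#' @rdname accessors
#' @export
setMethod("motifTable", "MotifLibrary", function(x) x@motifs)

#' @rdname accessors
#' @export
setGeneric("motifSpec", function(x) standardGeneric("motifSpec"))
#' @rdname accessors
#' @export
setMethod("motifSpec", "MotifLibrary", function(x) x@spec)

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname accessors
#' @export
setMethod("peptides", "MotifLibrary", function(x) x@motifs$peptide)

#' @rdname accessors
#' @export
setGeneric("oligoSeq", function(x) standardGeneric("oligoSeq"))
#' @rdname accessors
#' @export
setMethod("oligoSeq", "OligoDesign", function(x) x@ntSeq)

#' @rdname accessors
#' @export
setGeneric("encodedUnit", function(x) standardGeneric("encodedUnit"))
#' @rdname accessors
#' @export
setMethod("encodedUnit", "OligoDesign", function(x) x@encodedUnit)

#' @rdname accessors
#' @export
setGeneric("repeatScore", function(x) standardGeneric("repeatScore"))
#' @rdname accessors
#' @export
setMethod("repeatScore", "OligoDesign", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("profileQ", function(x) standardGeneric("profileQ"))
#' @rdname accessors
#' @export
setMethod("profileQ", "ScatteringProfile", function(x) x@q)

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setMethod("intensity", "ScatteringProfile", function(x) x@intensity)

#' @rdname accessors
#' @export
setGeneric("sigmaUnc", function(x) standardGeneric("sigmaUnc"))
#' @rdname accessors
#' @export
setMethod("sigmaUnc", "ScatteringProfile", function(x) x@sigma)

#' @rdname accessors
#' @export
setGeneric("pevRg", function(x) standardGeneric("pevRg"))
#' @rdname accessors
#' @export
setMethod("pevRg", "PEVFit", function(x) x@Rg)

#' @rdname accessors
#' @export
setGeneric("pevNu", function(x) standardGeneric("pevNu"))
#' @rdname accessors
#' @export
setMethod("pevNu", "PEVFit", function(x) x@nu)
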