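#' @import methods
#' @useDynLib ProbeSieve, .registration=TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom S4Vectors DataFrame SimpleList isSingleString metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq
NULL

#' GeneModel: a coding sequence with its exon/intron structure
#'
#' A \code{GeneModel} is the coordinate authority for one CDS: an ordered set
#' of exon intervals on a contig, the strand, and one EST-confirmation flag
#' per intron.  All coordinates are stored in \emph{coding orientation}: for a
#' minus-strand gene the contig is conceptually reverse-complemented and
#' positions mirrored (\code{pos' = contigLength - pos + 1}) once at read
#' time, so every downstream rule (distances from the 3' end, intron
#' adjacency) works 5' to 3' of the coding strand and no other code ever
#' inspects the strand.
#'
#' Introns are derived, not stored: intron \code{k} lies strictly between
#' exon \code{k} and exon \code{k + 1}.  Each intron is described by the
#' coordinate \code{x} of the last exonic base before its 5' end and the
#' coordinate \code{y} of the first exonic base after its 3' end, both in
#' coding orientation.
#'
#' @slot cdsId single character, the CDS identifier.
#' @slot contigId single character, the contig the gene lies on.
#' @slot strand \code{"+"} or \code{"-"} (orientation on the original contig).
#' @slot contigLength integer length of the contig (needed to undo the
#'   minus-strand mirror when writing annotation back out).
#' @slot exons an \link[IRanges]{IRanges} of exon intervals in coding
#'   orientation, sorted in transcription order, non-overlapping, separated
#'   by at least 2 nt (so every intron is non-empty).
#' @slot estConfirmed logical vector, one flag per intron.
#'
#' @examples
#' gm <- GeneModel("g1", "chr1", "+", 400L,
#'                 IRanges::IRanges(start = c(1, 201), end = c(100, 300)))
#' cdsLength(gm)   # 200
#' introns(gm)     # x = 100, y = 201
#' @export
setClass("GeneModel",
  representation(
    cdsId        = "character",
    contigId     = "character",
    strand       = "character",
    contigLength = "integer",
    exons        = "IRanges",
    estConfirmed = "logical"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@cdsId) != 1L || !nzchar(object@cdsId))
    msg <- c(msg, "'cdsId' must be a single non-empty string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "'strand' must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L)
    msg <- c(msg, "a GeneModel needs at least one exon")
  if (length(ex) >= 1L && any(IRanges::width(ex) < 1L))
    msg <- c(msg, "exons must have positive width")
  if (length(ex) >= 2L) {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    if (any(diff(s) <= 0))
      msg <- c(msg, "exons must be sorted in transcription order")
    if (any(s[-1L] < e[-length(e)] + 2L))
      msg <- c(msg, "consecutive exons must be separated by a non-empty intron")
  }
  if (length(object@estConfirmed) != max(length(ex) - 1L, 0L))
    msg <- c(msg, "'estConfirmed' needs one flag per intron")
  if (max(IRanges::end(ex)) > object@contigLength)
    msg <- c(msg, "exons extend past the end of the contig")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneModel-class
#' @param cdsId,contigId,strand,contigLength,exons,estConfirmed see slots.
#' @export
GeneModel <- function(cdsId, contigId, strand, contigLength, exons,
                      estConfirmed = logical(max(length(exons) - 1L, 0L))) {
  new("GeneModel",
      cdsId = as.character(cdsId), contigId = as.character(contigId),
      strand = as.character(strand), contigLength = as.integer(contigLength),
      exons = exons, estConfirmed = as.logical(estConfirmed))
}

#' A list of GeneModel objects keyed by CDS id
#'
#' @export
setClass("GeneModelSet", contains = "SimpleList",
         prototype = prototype(elementType = "GeneModel"))

#' @rdname GeneModelSet-class
#' @param models a list of \linkS4class{GeneModel} objects.
#' @export
GeneModelSet <- function(models = list()) {
  obj <- new("GeneModelSet", S4Vectors::SimpleList(models))
  names(obj) <- vapply(models, function(m) m@cdsId, character(1))
  obj
}

#' ProbeSet: candidate probes with CDS-relative coordinates
#'
#' Probes are stored with the coordinate every scoring rule is phrased in:
#' the 1-based position of the probe's 5'-most base on its target CDS
#' (coding orientation); contig coordinates are derived on demand from the
#' target's \linkS4class{GeneModel}.  Probe sequences are identical to the
#' coding strand.
#'
#' @slot probeData a \link[S4Vectors]{DataFrame} with columns
#'   \code{probe_id}, \code{cds_id}, \code{cds_start} and a
#'   \link[Biostrings]{DNAStringSet} column \code{sequence}.
#' @export
setClass("ProbeSet", representation(probeData = "DataFrame"))

setValidity("ProbeSet", function(object) {
  pd <- object@probeData
  need <- c("probe_id", "cds_id", "cds_start", "sequence")
  if (!all(need %in% colnames(pd)))
    return(paste("probeData needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(pd$probe_id))
    return("probe ids must be unique")
  if (any(pd$cds_start < 1L))
    return("cds_start must be >= 1")
  bad <- grepl("[^ACGT]", as.character(pd$sequence))
  if (any(bad))
    return(paste0("probe sequences must be over {A,C,G,T}; offending probe: ",
                  pd$probe_id[which(bad)[1L]]))
  TRUE
})

#' @rdname ProbeSet-class
#' @param probe_id,cds_id character vectors.
#' @param cds_start integer vector, 1-based CDS position of the 5'-most base.
#' @param sequence character vector or \code{DNAStringSet} of probe sequences.
#' @export
ProbeSet <- function(probe_id, cds_id, cds_start, sequence) {
  if (!is(sequence, "DNAStringSet"))
    sequence <- Biostrings::DNAStringSet(as.character(sequence))
  names(sequence) <- probe_id
  new("ProbeSet", probeData = S4Vectors::DataFrame(
    probe_id = as.character(probe_id), cds_id = as.character(cds_id),
    cds_start = as.integer(cds_start), sequence = sequence))
}

#' SelectionReport: terminal verdicts, per-CDS elections, deficiencies
#'
#' @slot verdicts per-probe \code{DataFrame} of QC metrics and flags.
#' @slot elections per-CDS \code{DataFrame} with the elected probe and how it
#'   was chosen (\code{qualified}, \code{rescued}, \code{bypass} or
#'   \code{none}).
#' @slot deficient character vector of probe-deficient CDS ids.
#' @export
setClass("SelectionReport",
  representation(verdicts = "DataFrame", elections = "DataFrame",
                 deficient = "character"))

## ---- accessors -------------------------------------------------------------

#' @rdname GeneModel-class
#' @param object,x a \code{GeneModel}.
#' @export
setGeneric("cdsId", function(x) standardGeneric("cdsId"))
#' @rdname GeneModel-class
#' @export
setMethod("cdsId", "GeneModel", function(x) x@cdsId)

#' @rdname GeneModel-class
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname GeneModel-class
#' @export
setMethod("exons", "GeneModel", function(x) x@exons)

#' @rdname GeneModel-class
#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))
#' @rdname GeneModel-class
#' @export
setMethod("cdsLength", "GeneModel",
          function(x) sum(IRanges::width(x@exons)))

#' @rdname GeneModel-class
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' Intron records of a gene model
#'
#' Returns one row per intron with the coding-orientation coordinates
#' \code{x} (last exonic base before the intron) and \code{y} (first exonic
#' base after it), plus the EST-confirmation flag.
#' @rdname GeneModel-class
#' @export
setMethod("introns", "GeneModel", function(x) {
  ex <- x@exons
  n <- length(ex)
  if (n < 2L)
    return(S4Vectors::DataFrame(x = integer(), y = integer(),
                                est_confirmed = logical()))
  S4Vectors::DataFrame(
    x = IRanges::end(ex)[-n],
    y = IRanges::start(ex)[-1L],
    est_confirmed = x@estConfirmed)
})

#' @rdname ProbeSet-class
#' @param x,object a \code{ProbeSet}.
#' @export
setGeneric("probeData", function(x) standardGeneric("probeData"))
#' @rdname ProbeSet-class
#' @export
setMethod("probeData", "ProbeSet", function(x) x@probeData)

#' @rdname ProbeSet-class
#' @export
setMethod("length", "ProbeSet", function(x) nrow(x@probeData))

#' @rdname ProbeSet-class
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "ProbeSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, probeData = x@probeData[i, , drop = FALSE])
})

#' @rdname ProbeSet-class
#' @export
setMethod("as.data.frame", "ProbeSet", function(x, ...) {
  pd <- x@probeData
  data.frame(probe_id = pd$probe_id, cds_id = pd$cds_id,
             cds_start = pd$cds_start,
             sequence = as.character(pd$sequence),
             stringsAsFactors = FALSE)
})

#' @rdname SelectionReport-class
#' @param x a \code{SelectionReport}.
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
#' @rdname SelectionReport-class
#' @export
setMethod("verdicts", "SelectionReport", function(x) x@verdicts)
#' @rdname SelectionReport-class
#' @export
setGeneric("elections", function(x) standardGeneric("elections"))
#' @rdname SelectionReport-class
#' @export
setMethod("elections", "SelectionReport", function(x) x@elections)
#' @rdname SelectionReport-class
#' @export
setGeneric("deficientCds", function(x) standardGeneric("deficientCds"))
#' @rdname SelectionReport-class
#' @export
setMethod("deficientCds", "SelectionReport", function(x) x@deficient)

## ---- show methods ----------------------------------------------------------

setMethod("show", "GeneModel", function(object) {
  ni <- max(length(object@exons) - 1L, 0L)
  cat("GeneModel ", object@cdsId, " (", object@contigId, object@strand,
      "): ", length(object@exons), " exon(s), ", ni, " intron(s), CDS ",
      cdsLength(object), " nt\n", sep = "")
  if (ni > 0L) {
    iv <- introns(object)
    cat("  introns (x,y|EST): ",
        paste0(iv$x, ",", iv$y, "|",
               ifelse(iv$est_confirmed, "yes", "no"), collapse = "  "),
        "\n", sep = "")
  }
})

setMethod("show", "ProbeSet", function(object) {
  pd <- object@probeData
  cat("ProbeSet with ", nrow(pd), " probe(s) on ",
      length(unique(pd$cds_id)), " CDS\n", sep = "")
  if (nrow(pd))
    cat("  lengths: ", paste(range(Biostrings::width(pd$sequence)),
                             collapse = "-"), " nt\n", sep = "")
})

setMethod("show", "SelectionReport", function(object) {
  el <- object@elections
  cat("SelectionReport\n")
  cat("  probes assessed:   ", nrow(object@verdicts), "\n", sep = "")
  cat("  CDS with election: ", sum(el$status != "none"), "\n", sep = "")
  if (nrow(el))
    print(table(status = el$status))
  cat("  probe-deficient CDS: ", length(object@deficient), "\n", sep = "")
})
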