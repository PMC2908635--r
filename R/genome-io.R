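## Genome / annotation I/O and the coordinate model.
##
## All interval arithmetic is 1-based inclusive (GFF3 convention).  Gene
## models are converted to coding orientation exactly once, here; no other
## module ever sees a strand.

#' Read gene models from GFF3 + genome FASTA
#'
#' Builds one \linkS4class{GeneModel} per CDS from the exon features of a
#' GFF3 file.  Exons are grouped by their \code{Parent} attribute (falling
#' back to \code{ID} when no \code{Parent} is present).  Minus-strand genes
#' are mirrored into coding orientation (\code{pos' = contigLength - pos + 1})
#' so that downstream position and intron logic is strand-free.
#'
#' @param annotation path to a GFF3 file with \code{exon} features (or
#'   \code{CDS} features if no exons are present).
#' @param genome a \link[Biostrings]{DNAStringSet} or path to a genome FASTA;
#'   contigs referenced by the annotation must be present.
#' @return a \linkS4class{GeneModelSet} named by CDS id.
#' @examples
#' fix <- simulateGenome(fixtureSpec(seed = 1, nGenes = 4))
#' tmp <- tempfile(); dirg <- tempfile()
#' dir.create(dirg)
#' writeFixture <- writeGeneModels(fix$models, file.path(dirg, "ann.gff3"))
#' models <- readGeneModels(file.path(dirg, "ann.gff3"), fix$genome)
#' @export
readGeneModels <- function(annotation, genome) {
  genome <- .asGenome(genome)
  gr <- rtracklayer::import(annotation, format = "gff3")
  type <- as.character(gr$type)
  feat <- gr[type == "exon"]
  if (length(feat) == 0L)
    feat <- gr[type == "CDS"]
  if (length(feat) == 0L)
    stop("annotation contains no exon or CDS features")
  parent <- as.character(S4Vectors::mcols(feat)$Parent)
  if (is.null(S4Vectors::mcols(feat)$Parent) || all(is.na(parent)) ||
      all(parent == "character(0)"))
    parent <- as.character(S4Vectors::mcols(feat)$ID)
  parent <- sub("^(mRNA|cds|gene):", "", parent)
  if (anyNA(parent) || any(!nzchar(parent)))
    stop("every exon feature needs a Parent (or ID) attribute")
  contigLens <- stats::setNames(Biostrings::width(genome), names(genome))
  idx <- split(seq_along(feat), parent)
  models <- lapply(names(idx), function(id) {
    f <- feat[idx[[id]]]
    contig <- as.character(GenomeInfoDb::seqnames(f))
    if (length(unique(contig)) != 1L)
      stop("gene '", id, "' has exons on more than one contig")
    contig <- contig[1L]
    if (!contig %in% names(genome))
      stop("contig '", contig, "' referenced by gene '", id,
           "' is missing from the genome FASTA")
    strand <- as.character(BiocGenerics::strand(f))
    if (length(unique(strand)) != 1L || !strand[1L] %in% c("+", "-"))
      stop("gene '", id, "' must have a single defined strand")
    strand <- strand[1L]
    s <- BiocGenerics::start(f); e <- BiocGenerics::end(f)
    if (length(s) > 1L && any(diff(s) <= 0))
      stop("exon features of gene '", id,
           "' are out of order (starts must increase along the contig)")
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("exon features of gene '", id, "' overlap")
    L <- contigLens[[contig]]
    if (strand == "-") {       # mirror into coding orientation
      s2 <- L - e + 1L; e2 <- L - s + 1L
      ord <- order(s2); s <- s2[ord]; e <- e2[ord]
    }
    GeneModel(id, contig, strand, L, IRanges::IRanges(start = s, end = e))
  })
  GeneModelSet(models)
}

#' Write gene models back to GFF3
#'
#' Inverse of \code{\link{readGeneModels}}: coding-orientation coordinates
#' are mirrored back to contig-forward GFF3 coordinates for minus-strand
#' genes.  Emits one \code{gene} feature and its \code{exon} children per
#' CDS, so a written file round-trips through the reader without loss.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param path output GFF3 path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m@exons
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    if (m@strand == "-") {
      s2 <- m@contigLength - e + 1L
      e2 <- m@contigLength - IRanges::start(ex) + 1L
      ord <- order(s2); s <- s2[ord]; e <- e2[ord]
    }
    data.frame(
      contig = m@contigId,
      type = c("gene", rep("exon", length(ex))),
      start = c(min(s), s), end = c(max(e), e),
      strand = m@strand,
      ID = c(m@cdsId, paste0(m@cdsId, ".exon", seq_along(ex))),
      Parent = c(NA_character_, rep(m@cdsId, length(ex))),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$contig,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- IRanges::CharacterList(lapply(tab$Parent, function(p)
    if (is.na(p)) character() else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.asGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  stop("'genome' must be a DNAStringSet or a FASTA path")
}

## Coding-orientation contig sequence for a model's contig.
.codingContig <- function(model, genome) {
  ctg <- genome[[model@contigId]]
  if (model@strand == "-") Biostrings::reverseComplement(ctg) else ctg
}

#' Spliced CDS sequences
#'
#' Extracts the spliced (exon-concatenated) CDS sequence of each gene model,
#' 5' to 3' of the coding strand.
#'
#' @param models a \linkS4class{GeneModelSet} (or single
#'   \linkS4class{GeneModel}).
#' @param genome genome \code{DNAStringSet} or FASTA path.
#' @return a \code{DNAStringSet} named by CDS id.
#' @export
splicedCds <- function(models, genome) {
  genome <- .asGenome(genome)
  if (is(models, "GeneModel")) models <- GeneModelSet(list(models))
  seqs <- lapply(models, function(m) {
    ctg <- .codingContig(m, genome)
    unlist(Biostrings::DNAStringSet(Biostrings::extractAt(ctg, m@exons)))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(models)
  out
}

#' Distance of a probe's 5'-most base from the CDS 3' end
#'
#' The probe position criterion and both selection-round exclusions are
#' phrased in nucleotides numbered from the CDS 3' end: a probe starting at
#' CDS position \code{cds_start} on a CDS of length \code{cds_length} lies
#' at distance \code{d = cds_length - cds_start + 1} (so the last base of
#' the CDS is at distance 1).
#'
#' @param cds_start integer vector of 1-based probe start positions.
#' @param cds_length integer vector (recycled) of CDS lengths.
#' @return integer vector of distances.
#' @examples
#' distanceFrom3Prime(1000, 1000)  # 1
#' distanceFrom3Prime(701, 1000)   # 300
#' @export
distanceFrom3Prime <- function(cds_start, cds_length) {
  cds_start <- as.integer(cds_start)
  cds_length <- as.integer(cds_length)
  if (any(cds_start < 1L | cds_start > cds_length))
    stop("probe start outside [1, cds_length]")
  cds_length - cds_start + 1L
}

#' Map CDS positions to coding-orientation contig coordinates
#'
#' @param model a \linkS4class{GeneModel}.
#' @param positions integer vector of 1-based spliced-CDS positions.
#' @return integer vector of contig positions (coding orientation).
#' @export
cdsToGenomic <- function(model, positions) {
  positions <- as.integer(positions)
  w <- IRanges::width(model@exons)
  cums <- cumsum(w)
  L <- cums[length(cums)]
  if (any(positions < 1L | positions > L))
    stop("CDS position outside [1, ", L, "] for '", model@cdsId, "'")
  exIdx <- findInterval(positions - 1L, c(0L, cums[-length(cums)]))
  before <- c(0L, cums)[exIdx]
  IRanges::start(model@exons)[exIdx] + (positions - before - 1L)
}

## Contiguous genomic span of a probe footprint (coding orientation).  A
## junction-spanning probe's span swallows the intervening intron(s), which
## is exactly what the intron-overlap classification needs.
.probeSpan <- function(model, cds_start, probe_length) {
  g <- cdsToGenomic(model, c(cds_start, cds_start + probe_length - 1L))
  c(start = g[1L], end = g[2L])
}

#' Check that probes match their target CDS sequence
#'
#' Verifies the probe-set invariant that every probe sequence equals the
#' spliced CDS of its target at its declared location (probes are identical
#' to the coding strand).
#'
#' @param probes a \linkS4class{ProbeSet}.
#' @param models a \linkS4class{GeneModelSet}.
#' @param genome genome \code{DNAStringSet} or FASTA path.
#' @return invisibly \code{TRUE}; stops with the offending probe otherwise.
#' @export
validateProbes <- function(probes, models, genome) {
  cds <- splicedCds(models, genome)
  pd <- probeData(probes)
  for (i in seq_len(nrow(pd))) {
    id <- pd$cds_id[i]
    if (!id %in% names(cds))
      stop("probe '", pd$probe_id[i], "' targets unknown CDS '", id, "'")
    len <- Biostrings::width(pd$sequence)[i]
    if (pd$cds_start[i] + len - 1L > length(cds[[id]]))
      stop("probe '", pd$probe_id[i], "' extends past the end of its CDS")
    ref <- as.character(Biostrings::subseq(cds[[id]], pd$cds_start[i],
                                           width = len))
    if (ref != as.character(pd$sequence[[i]]))
      stop("probe '", pd$probe_id[i],
           "' does not match its target CDS at cds_start ", pd$cds_start[i])
  }
  invisible(TRUE)
}

## ---- flat-file tables ------------------------------------------------------

#' Read / write a probe table
#'
#' Tab-separated with columns \code{probe_id}, \code{cds_id},
#' \code{cds_start}, \code{sequence}.
#'
#' @param path file path.
#' @return \code{readProbeTable}: a \linkS4class{ProbeSet}.
#' @export
readProbeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "cds_id", "cds_start", "sequence")
  if (!all(need %in% colnames(tab)))
    stop("probe table needs columns: ", paste(need, collapse = ", "))
  ProbeSet(tab$probe_id, tab$cds_id, tab$cds_start, tab$sequence)
}

#' @rdname readProbeTable
#' @param probes a \linkS4class{ProbeSet}.
#' @export
writeProbeTable <- function(probes, path) {
  utils::write.table(as.data.frame(probes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read EST intron confirmations and apply them to gene models
#'
#' The confirmation table is tab-separated with columns \code{cds_id},
#' \code{intron_index} (1-based, in transcription order) and
#' \code{est_confirmed} (TRUE/FALSE).  Introns not listed keep their current
#' flag (default unconfirmed).
#'
#' @param path TSV path.
#' @param models a \linkS4class{GeneModelSet}.
#' @return the updated \code{GeneModelSet}.
#' @export
readEstConfirmations <- function(path, models) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cds_id", "intron_index", "est_confirmed")
  if (!all(need %in% colnames(tab)))
    stop("EST table needs columns: ", paste(need, collapse = ", "))
  applyEstConfirmations(models, tab)
}

#' @rdname readEstConfirmations
#' @param confirmations a data frame as described above.
#' @export
applyEstConfirmations <- function(models, confirmations) {
  for (i in seq_len(nrow(confirmations))) {
    id <- confirmations$cds_id[i]
    if (!id %in% names(models))
      stop("EST confirmation refers to unknown CDS '", id, "'")
    m <- models[[id]]
    k <- as.integer(confirmations$intron_index[i])
    if (k < 1L || k > length(m@estConfirmed))
      stop("CDS '", id, "' has no intron ", k)
    m@estConfirmed[k] <- as.logical(confirmations$est_confirmed[i])
    models[[id]] <- m
  }
  models
}

#' Write a plain TSV (helper used by all report writers)
#' @noRd
.writeTsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
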