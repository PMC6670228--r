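#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet DNAString AAStringSet
NULL

#' GliadinGeneSet: a set of intronless gliadin coding sequences
#'
#' Container for gliadin coding sequences (one intronless CDS per gene, coding
#' strand) together with per-gene metadata: family (alpha/gamma/omega),
#' subgenome label (A/B/D, known only for diploid-relative accessions),
#' subgroup label when generated synthetically, species, and the planted
#' pseudogene flag for generator output. Derived quantities (protein,
#' pseudogene call) are computed on demand by the annotation functions, never
#' stored, so they can always be recomputed from the DNA.
#'
#' @slot sequences a \link[Biostrings]{DNAStringSet}, one CDS per gene.
#' @slot geneData a \link[S4Vectors]{DataFrame} with one row per gene and at
#'   least columns \code{gene_id}, \code{family}, \code{genome},
#'   \code{subgroup}, \code{species}, \code{planted_pseudogene}.
#'
#' @export
setClass("GliadinGeneSet",
  representation(sequences = "DNAStringSet", geneData = "DataFrame"),
  validity = function(object) {
    msg <- character()
    n <- length(object@sequences)
    if (nrow(object@geneData) != n)
      msg <- c(msg, "geneData must have one row per sequence")
    need <- c("gene_id", "family", "genome", "subgroup", "species",
              "planted_pseudogene")
    miss <- setdiff(need, colnames(object@geneData))
    if (length(miss))
      msg <- c(msg, paste0("geneData lacks column(s): ",
                           paste(miss, collapse = ", ")))
    if (!length(msg)) {
      if (anyDuplicated(object@geneData$gene_id))
        msg <- c(msg, "gene_id values must be unique")
      bad <- !object@geneData$family %in% c("alpha", "gamma", "omega", "unknown")
      if (any(bad)) msg <- c(msg, "family must be alpha/gamma/omega/unknown")
      badg <- !object@geneData$genome %in% c("A", "B", "D", "unknown")
      if (any(badg)) msg <- c(msg, "genome must be A/B/D/unknown")
      if (n && any(grepl("[^ACGT]", as.character(object@sequences))))
        msg <- c(msg, "sequences must contain only A,C,G,T")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GliadinGeneSet
#'
#' @param sequences a \code{DNAStringSet} (or character vector) of coding
#'   sequences.
#' @param geneData a \code{DataFrame}/\code{data.frame} of per-gene metadata;
#'   missing standard columns are filled with \code{"unknown"}/\code{NA}.
#' @return a \code{GliadinGeneSet}.
#' @export
GliadinGeneSet <- function(sequences, geneData) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (is.data.frame(geneData)) geneData <- DataFrame(geneData)
  defaults <- list(family = "unknown", genome = "unknown",
                   subgroup = NA_character_, species = "unknown",
                   planted_pseudogene = NA)
  for (col in names(defaults))
    if (!col %in% colnames(geneData))
      geneData[[col]] <- rep(defaults[[col]], nrow(geneData))
  if (!"gene_id" %in% colnames(geneData))
    stop("geneData must contain a gene_id column")
  names(sequences) <- geneData$gene_id
  new("GliadinGeneSet", sequences = sequences, geneData = geneData)
}

#' LocusModel: a tandem array of gliadin genes on one strand
#'
#' One haploid locus (e.g. an alpha-gliadin Gli-2 array): the concatenated
#' genomic sequence, and the position of every gene as an \code{IRanges}
#' (1-based closed, Bioconductor convention; TSV export is 0-based
#' half-open). All genes lie on the plus strand of the stored sequence.
#'
#' @slot locusId single string.
#' @slot genome subgenome label, one of A/B/D.
#' @slot sequence a \code{DNAString} with the full locus sequence.
#' @slot geneRanges an \code{IRanges}, one range per gene, named by gene id,
#'   sorted, non-overlapping, within the sequence bounds.
#'
#' @export
setClass("LocusModel",
  representation(locusId = "character", genome = "character",
                 sequence = "DNAString", geneRanges = "IRanges"),
  validity = function(object) {
    msg <- character()
    if (length(object@locusId) != 1L) msg <- c(msg, "locusId must be length 1")
    if (!object@genome %in% c("A", "B", "D"))
      msg <- c(msg, "genome must be A, B or D")
    rng <- object@geneRanges
    if (length(rng)) {
      if (is.null(names(rng)) || anyDuplicated(names(rng)))
        msg <- c(msg, "geneRanges must be uniquely named by gene id")
      if (is.unsorted(IRanges::start(rng)))
        msg <- c(msg, "geneRanges must be sorted by start")
      if (min(IRanges::start(rng)) < 1L ||
          max(IRanges::end(rng)) > length(object@sequence))
        msg <- c(msg, "geneRanges must lie within the locus sequence")
      if (length(rng) > 1L) {
        s <- IRanges::start(rng)[-1L]
        e <- IRanges::end(rng)[-length(rng)]
        if (any(s <= e)) msg <- c(msg, "geneRanges must not overlap")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' RepairPolicy: stochastic model of double-strand-break resolution
#'
#' Governs how simulated Cas9 cuts resolve. Two co-occurring cuts excise the
#' intervening segment with probability \code{pSegmentDeletion} (deleting
#' fully contained genes and fusing the two flanking cut genes). A single cut
#' re-ligates unchanged with probability \code{pPerfectRepair}, otherwise an
#' indel is drawn: a deletion (probability \code{pDeletion}) with size from
#' \code{delSizes}/\code{delWeights}, or an insertion of random bases with
#' size from \code{insSizes}/\code{insWeights}.
#'
#' @slot pSegmentDeletion,pPerfectRepair,pDeletion probabilities in [0,1].
#' @slot delSizes,insSizes integer vectors of indel sizes (nt).
#' @slot delWeights,insWeights normalised sampling weights.
#'
#' @export
setClass("RepairPolicy",
  representation(pSegmentDeletion = "numeric", pPerfectRepair = "numeric",
                 pDeletion = "numeric",
                 delSizes = "integer", delWeights = "numeric",
                 insSizes = "integer", insWeights = "numeric"),
  validity = function(object) {
    msg <- character()
    for (p in c("pSegmentDeletion", "pPerfectRepair", "pDeletion")) {
      v <- slot(object, p)
      if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
        msg <- c(msg, paste(p, "must be a single probability in [0,1]"))
    }
    if (length(object@delSizes) != length(object@delWeights))
      msg <- c(msg, "delSizes and delWeights lengths differ")
    if (length(object@insSizes) != length(object@insWeights))
      msg <- c(msg, "insSizes and insWeights lengths differ")
    if (length(object@delSizes) && any(object@delSizes < 1L))
      msg <- c(msg, "deletion sizes must be >= 1")
    if (length(object@insSizes) && any(object@insSizes < 1L))
      msg <- c(msg, "insertion sizes must be >= 1")
    if (length(object@delWeights) &&
        abs(sum(object@delWeights) - 1) > 1e-8)
      msg <- c(msg, "delWeights must sum to 1")
    if (length(object@insWeights) &&
        abs(sum(object@insWeights) - 1) > 1e-8)
      msg <- c(msg, "insWeights must sum to 1")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a RepairPolicy
#'
#' Defaults: deletions of 1-10 nt (uniform) with probability 0.7, insertions
#' of 1-3 nt (uniform) with probability 0.3, perfect re-ligation probability
#' 0.2, segment-deletion probability 0.5 for co-occurring cuts. These are
#' configuration, not biological constants; see the package vignette.
#'
#' @param pSegmentDeletion probability that an adjacent cut pair excises the
#'   intervening segment.
#' @param pPerfectRepair probability a single cut re-ligates unchanged.
#' @param pDeletion probability an imperfect single-cut repair is a deletion
#'   (otherwise an insertion).
#' @param delSizes,delWeights deletion size support and weights.
#' @param insSizes,insWeights insertion size support and weights.
#' @return a \code{RepairPolicy}.
#' @examples
#' repairPolicy(pSegmentDeletion = 1, pPerfectRepair = 0)
#' @export
repairPolicy <- function(pSegmentDeletion = 0.5, pPerfectRepair = 0.2,
                         pDeletion = 0.7,
                         delSizes = 1:10, delWeights = NULL,
                         insSizes = 1:3, insWeights = NULL) {
  delSizes <- as.integer(delSizes)
  insSizes <- as.integer(insSizes)
  if (is.null(delWeights))
    delWeights <- rep(1 / length(delSizes), length(delSizes))
  if (is.null(insWeights))
    insWeights <- rep(1 / length(insSizes), length(insSizes))
  new("RepairPolicy", pSegmentDeletion = pSegmentDeletion,
      pPerfectRepair = pPerfectRepair, pDeletion = pDeletion,
      delSizes = delSizes, delWeights = delWeights / sum(delWeights),
      insSizes = insSizes, insWeights = insWeights / sum(insWeights))
}
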