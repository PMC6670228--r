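#' @include AllClasses.R
NULL

#' Accessors for GliadinGeneSet and LocusModel
#'
#' \code{geneSequences} returns the coding sequences; \code{geneInfo} the
#' per-gene metadata; \code{geneIds}, \code{geneFamily}, \code{genomeLabel},
#' \code{subgroupLabel} the corresponding metadata columns.
#' \code{locusSequence}, \code{geneRanges} and \code{locusId} access a
#' \code{LocusModel}.
#'
#' @param x a \code{GliadinGeneSet} or \code{LocusModel}.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSequences", function(x) standardGeneric("geneSequences"))
#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("geneFamily", function(x) standardGeneric("geneFamily"))
#' @rdname accessors
#' @export
setGeneric("genomeLabel", function(x) standardGeneric("genomeLabel"))
#' @rdname accessors
#' @export
setGeneric("subgroupLabel", function(x) standardGeneric("subgroupLabel"))
#' @rdname accessors
#' @export
setGeneric("locusSequence", function(x) standardGeneric("locusSequence"))
#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname accessors
setMethod("geneSequences", "GliadinGeneSet", function(x) x@sequences)
#' @rdname accessors
setMethod("geneInfo", "GliadinGeneSet", function(x) x@geneData)
#' @rdname accessors
setMethod("geneIds", "GliadinGeneSet", function(x) x@geneData$gene_id)
#' @rdname accessors
setMethod("geneFamily", "GliadinGeneSet", function(x) x@geneData$family)
#' @rdname accessors
setMethod("genomeLabel", "GliadinGeneSet", function(x) x@geneData$genome)
#' @rdname accessors
setMethod("subgroupLabel", "GliadinGeneSet", function(x) x@geneData$subgroup)
#' @rdname accessors
setMethod("locusSequence", "LocusModel", function(x) x@sequence)
#' @rdname accessors
setMethod("geneRanges", "LocusModel", function(x) x@geneRanges)
#' @rdname accessors
setMethod("locusId", "LocusModel", function(x) x@locusId)
#' @rdname accessors
setMethod("genomeLabel", "LocusModel", function(x) x@genome)

#' @describeIn accessors number of genes in the set.
#' @export
setMethod("length", "GliadinGeneSet", function(x) length(x@sequences))

#' Subset a GliadinGeneSet
#'
#' @param x a \code{GliadinGeneSet}.
#' @param i logical, integer or character (gene id) index.
#' @param j,...,drop ignored.
#' @return a \code{GliadinGeneSet} with the selected genes.
#' @export
setMethod("[", "GliadinGeneSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@geneData$gene_id)
  new("GliadinGeneSet", sequences = x@sequences[i],
      geneData = x@geneData[i, , drop = FALSE])
})

setMethod("show", "GliadinGeneSet", function(object) {
  n <- length(object)
  fam <- table(object@geneData$family)
  cat("GliadinGeneSet with", n, "genes (",
      paste(names(fam), fam, sep = ":", collapse = ", "), ")\n")
  if (n) {
    w <- Biostrings::width(object@sequences)
    cat("  CDS length:", min(w), "-", max(w), "nt\n")
    ps <- object@geneData$planted_pseudogene
    if (!all(is.na(ps)))
      cat("  planted pseudogenes:", sum(ps, na.rm = TRUE), "\n")
  }
  invisible(object)
})

setMethod("show", "LocusModel", function(object) {
  cat("LocusModel", object@locusId, "(genome", object@genome, "):",
      length(object@sequence), "nt,", length(object@geneRanges), "genes\n")
  invisible(object)
})

setMethod("show", "RepairPolicy", function(object) {
  cat("RepairPolicy: P(segment deletion) =", object@pSegmentDeletion,
      "| P(perfect repair) =", object@pPerfectRepair,
      "| P(deletion | indel) =", object@pDeletion, "\n")
  cat("  deletion sizes:", paste(object@delSizes, collapse = ","),
      " insertion sizes:", paste(object@insSizes, collapse = ","), "\n")
  invisible(object)
})
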