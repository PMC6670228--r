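#' @include AllClasses.R
#' @importFrom Biostrings writeXStringSet readDNAStringSet
#' @importFrom utils write.table
NULL

#' Read and write gliadin gene FASTA
#'
#' DNA FASTA, one record per gene, with pipe-delimited header fields
#' \code{id|family|genome|subgroup|pseudogene_flag}. The flag records the
#' generator's planted pseudogene status (\code{1}/\code{0}; \code{NA} for
#' genes of unknown provenance). \code{generateFamily} output survives a
#' write/read round trip with identical sequences and metadata.
#'
#' @param genes a \code{GliadinGeneSet}.
#' @param path FASTA file path.
#' @return \code{readGeneFasta} returns a \code{GliadinGeneSet};
#'   \code{writeGeneFasta} returns \code{path} invisibly.
#' @export
writeGeneFasta <- function(genes, path) {
  stopifnot(is(genes, "GliadinGeneSet"))
  info <- geneInfo(genes)
  flag <- ifelse(is.na(info$planted_pseudogene), "NA",
                 as.integer(info$planted_pseudogene))
  headers <- paste(info$gene_id, info$family, info$genome, info$subgroup,
                   flag, sep = "|")
  seqs <- geneSequences(genes)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeGeneFasta
#' @export
readGeneFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    stop("FASTA headers must have 5 pipe-delimited fields: ",
         "id|family|genome|subgroup|pseudogene_flag")
  gd <- DataFrame(
    gene_id = vapply(parts, `[`, "", 1L),
    family = vapply(parts, `[`, "", 2L),
    genome = vapply(parts, `[`, "", 3L),
    subgroup = vapply(parts, `[`, "", 4L),
    species = "unknown",
    planted_pseudogene = suppressWarnings(
      as.logical(as.integer(vapply(parts, `[`, "", 5L)))))
  names(seqs) <- gd$gene_id
  GliadinGeneSet(seqs, gd)
}

#' Write a locus manifest TSV
#'
#' One row per gene: locus, gene_id, start, end, strand. Coordinates are
#' 0-based half-open (the package's external file convention; in-memory
#' ranges are 1-based IRanges).
#'
#' @param loci a \code{LocusModel} or list of them.
#' @param path TSV path.
#' @return \code{path}, invisibly.
#' @export
writeLocusManifest <- function(loci, path) {
  if (is(loci, "LocusModel")) loci <- list(loci)
  rows <- lapply(loci, function(loc) {
    rng <- geneRanges(loc)
    data.frame(locus = locusId(loc), gene_id = names(rng),
               start = IRanges::start(rng) - 1L, end = IRanges::end(rng),
               strand = "+")
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
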