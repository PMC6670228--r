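#' @include AllClasses.R
#' @importFrom Biostrings AAString subseq width
#' @importFrom utils read.delim
NULL

#' Translate an intronless coding sequence
#'
#' Standard-genetic-code translation of frame 0, the reading frame of an
#' ATG-anchored intronless gliadin CDS. Stop codons are retained as
#' \code{'*'} so downstream pseudogene calling can locate premature stops. A
#' trailing incomplete codon is ignored with a warning; non-ACGT characters
#' are an error naming the offending position. No ORF search is performed.
#'
#' @param dna a single DNA string (character or \code{DNAString}),
#'   length >= 3.
#' @return the amino-acid string, length \code{floor(nchar(dna)/3)}.
#' @examples
#' translateCds("ATGTAAGGG")  # "M*G"
#' @export
translateCds <- function(dna) {
  dna <- as.character(dna)
  if (length(dna) != 1L || is.na(dna)) stop("dna must be a single string")
  dna <- toupper(dna)
  assertACGT(dna, "dna")
  n <- nchar(dna)
  if (n < 3L) stop("dna must be at least one codon (3 nt) long")
  if (n %% 3L != 0L) {
    warning(sprintf("trailing incomplete codon (%d nt) ignored", n %% 3L))
    dna <- substr(dna, 1L, n - n %% 3L)
  }
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Call a gliadin pseudogene from its protein sequence
#'
#' Gliadin pseudogenes are gene copies harbouring an in-frame premature stop
#' codon. A protein is called a pseudogene iff \code{'*'} occurs at any
#' position other than the last. A protein with no terminal stop at all is
#' not a pseudogene, but the result carries attribute
#' \code{no_terminal_stop = TRUE} (typically a CDS truncated at the 3' end).
#'
#' @param protein a single amino-acid string as returned by
#'   \code{\link{translateCds}}.
#' @return logical scalar, with attribute \code{no_terminal_stop}.
#' @examples
#' callPseudogene("MQPF*")  # FALSE
#' callPseudogene("M*QPF")  # TRUE
#' @export
callPseudogene <- function(protein) {
  protein <- as.character(protein)
  if (length(protein) != 1L || is.na(protein) || !nzchar(protein))
    stop("protein must be a single non-empty string")
  stops <- gregexpr("*", protein, fixed = TRUE)[[1L]]
  n <- nchar(protein)
  hasInternal <- any(stops > 0L & stops < n)
  structure(hasInternal,
            no_terminal_stop = substr(protein, n, n) != "*")
}

#' Read or load a coeliac-disease epitope catalogue
#'
#' The catalogue is an editable TSV with columns \code{name},
#' \code{peptide} (the canonical genomically encoded 9-mer, Q-form) and
#' \code{families} (comma-separated subset of alpha/gamma/omega).
#' \code{cdEpitopes()} loads the catalogue shipped with the package.
#'
#' @param path path to a catalogue TSV.
#' @return a \code{data.frame} with columns \code{name}, \code{peptide},
#'   \code{families}.
#' @examples
#' head(cdEpitopes())
#' @export
readEpitopeCatalogue <- function(path) {
  cat <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "peptide", "families")
  if (!all(need %in% colnames(cat)))
    stop("catalogue must have columns name, peptide, families")
  if (anyDuplicated(cat$name)) stop("epitope names must be unique")
  if (any(nchar(cat$peptide) != 9L))
    stop("epitope peptides must be exactly 9 residues")
  cat
}

#' @rdname readEpitopeCatalogue
#' @export
cdEpitopes <- function() {
  readEpitopeCatalogue(system.file("extdata", "epitopes.tsv",
                                   package = "gliadinCRISPR", mustWork = TRUE))
}

#' Locate coeliac-disease epitopes in a protein
#'
#' Exact 9-mer window scan of a protein against an epitope catalogue.
#' Every match is reported, including mutually overlapping ones (canonical
#' CD epitopes often overlap). With \code{qeEquivalence = TRUE}, glutamine
#' and glutamate are treated as equal during comparison, so deamidated
#' epitope forms in the catalogue also match their genomically encoded
#' Q-form occurrences.
#'
#' @param protein a single amino-acid string.
#' @param catalogue an epitope catalogue \code{data.frame}
#'   (default \code{\link{cdEpitopes}()}).
#' @param qeEquivalence treat Q and E as equivalent (deamidation-aware).
#' @return \code{data.frame(epitope_name, position)} with 1-based positions
#'   of the first residue, sorted by position; zero rows when nothing
#'   matches.
#' @examples
#' scanEpitopes("MPFPQPQLPYA",
#'              data.frame(name = "e1", peptide = "PFPQPQLPY",
#'                         families = "alpha"))
#' @export
scanEpitopes <- function(protein, catalogue = cdEpitopes(),
                         qeEquivalence = FALSE) {
  protein <- as.character(protein)
  if (length(protein) != 1L) stop("protein must be a single string")
  if (nrow(catalogue) == 0L) stop("catalogue must be non-empty")
  subject <- if (qeEquivalence) chartr("E", "Q", protein) else protein
  res <- lapply(seq_len(nrow(catalogue)), function(i) {
    pep <- catalogue$peptide[i]
    if (qeEquivalence) pep <- chartr("E", "Q", pep)
    if (nchar(subject) < nchar(pep)) return(NULL)
    m <- Biostrings::matchPattern(Biostrings::AAString(pep),
                                  Biostrings::AAString(subject))
    if (!length(m)) return(NULL)
    data.frame(epitope_name = catalogue$name[i], position = IRanges::start(m))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(epitope_name = character(), position = integer()))
  out <- out[order(out$position, match(out$epitope_name, catalogue$name)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment a gliadin protein into domains
#'
#' Splits a gliadin protein (up to its first stop) into the signal peptide
#' (first \code{signalLength} residues), the repetitive/epitope region (the
#' span from the first to the last epitope hit), and the flanking segments.
#' Coordinates are 1-based inclusive protein positions. The gap between
#' signal peptide and first epitope is labelled \code{epitope_upstream} so
#' the segments are contiguous and cover the protein. Proteins shorter than
#' the signal peptide yield a single-segment map with a warning.
#'
#' @param protein a single amino-acid string.
#' @param hits epitope hits for this protein, as from
#'   \code{\link{scanEpitopes}}.
#' @param signalLength signal peptide length in residues (default 20).
#' @return \code{data.frame(domain, start, end)}.
#' @export
segmentDomains <- function(protein, hits, signalLength = 20L) {
  protein <- as.character(protein)
  firstStop <- regexpr("*", protein, fixed = TRUE)
  lim <- if (firstStop > 0L) firstStop - 1L else nchar(protein)
  if (lim < 1L) stop("protein has no residues before the first stop")
  if (lim <= signalLength) {
    warning("protein shorter than the signal peptide; single-segment map")
    return(data.frame(domain = "signal_peptide", start = 1L, end = lim))
  }
  hits <- hits[hits$position + 8L <= lim, , drop = FALSE]
  seg <- function(domain, start, end) {
    if (end < start) NULL else data.frame(domain = domain, start = start,
                                          end = end)
  }
  if (nrow(hits) == 0L) {
    out <- rbind(seg("signal_peptide", 1L, signalLength),
                 seg("downstream", signalLength + 1L, lim))
  } else {
    epStart <- min(hits$position)
    epEnd <- min(max(hits$position) + 8L, lim)
    sigEnd <- min(signalLength, epStart - 1L)
    out <- rbind(seg("signal_peptide", 1L, sigEnd),
                 seg("epitope_upstream", sigEnd + 1L, epStart - 1L),
                 seg("epitope_region", epStart, epEnd),
                 seg("downstream", epEnd + 1L, lim))
  }
  rownames(out) <- NULL
  out
}

#' Annotate a set of gliadin genes
#'
#' Runs the full annotation stage on a \code{GliadinGeneSet}: translation,
#' pseudogene calls, epitope scanning and domain segmentation.
#'
#' @param genes a \code{GliadinGeneSet}.
#' @param catalogue epitope catalogue (default \code{\link{cdEpitopes}()}).
#' @param signalLength signal peptide length in residues.
#' @param qeEquivalence passed to \code{\link{scanEpitopes}}.
#' @return a list with elements \code{proteins} (named character),
#'   \code{pseudogene} (named logical), \code{hits}
#'   (\code{data.frame(gene_id, epitope_name, position)}) and \code{domains}
#'   (\code{data.frame(gene_id, domain, start, end)}).
#' @examples
#' fam <- generateFamily(defaultAlphaSpec(nCopies = 6,
#'                                        pseudogeneFraction = 0, seed = 1))
#' ann <- annotateGenes(fam)
#' table(ann$pseudogene)
#' @export
annotateGenes <- function(genes, catalogue = cdEpitopes(),
                          signalLength = 20L, qeEquivalence = FALSE) {
  stopifnot(is(genes, "GliadinGeneSet"))
  ids <- geneIds(genes)
  prot <- vapply(as.character(geneSequences(genes)), translateCds, "",
                 USE.NAMES = FALSE)
  names(prot) <- ids
  pseudo <- vapply(prot, function(p) as.logical(callPseudogene(p)), TRUE)
  hitList <- lapply(ids, function(id) {
    h <- scanEpitopes(prot[[id]], catalogue, qeEquivalence)
    if (nrow(h)) cbind(gene_id = id, h) else NULL
  })
  hits <- do.call(rbind, hitList)
  if (is.null(hits))
    hits <- data.frame(gene_id = character(), epitope_name = character(),
                       position = integer())
  domList <- lapply(ids, function(id) {
    h <- hits[hits$gene_id == id, c("epitope_name", "position"), drop = FALSE]
    cbind(gene_id = id,
          suppressWarnings(segmentDomains(prot[[id]], h, signalLength)))
  })
  domains <- do.call(rbind, domList)
  rownames(domains) <- NULL
  list(proteins = prot, pseudogene = pseudo, hits = hits, domains = domains)
}
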