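#' @include AllClasses.R utils.R
NULL

# Synonymous codon choices, standard genetic code.
CODON_CHOICES <- split(names(Biostrings::GENETIC_CODE),
                       unname(Biostrings::GENETIC_CODE))

# 20-residue gliadin-like signal peptide used by all default subgroup
# templates (the real signal length is not critical; 20 aa is typical).
DEFAULT_SIGNAL <- "MKTFLILALLAIVATTATTA"

#' Reverse-translate a peptide with seeded synonymous codon jitter
#'
#' Each residue is encoded by a codon drawn uniformly among its synonymous
#' codons, so repeated calls yield DNA copies that differ at synonymous
#' sites while remaining protein-faithful -- the structure of real gliadin
#' paralogs. Uses the current RNG stream; seed outside.
#'
#' @param peptide amino-acid string ('*' allowed, encoded as a stop codon).
#' @return a DNA string of length \code{3*nchar(peptide)}.
#' @export
revTranslate <- function(peptide) {
  aas <- strsplit(as.character(peptide), "")[[1L]]
  bad <- setdiff(aas, names(CODON_CHOICES))
  if (length(bad)) stop("cannot encode residue(s): ",
                        paste(unique(bad), collapse = ","))
  paste(vapply(aas, function(a) {
    ch <- CODON_CHOICES[[a]]
    ch[sample.int(length(ch), 1L)]
  }, ""), collapse = "")
}

# Build a protospacer+PAM cassette, in frame (length a multiple of 3) and
# free of in-frame stop codons. Antisense cassettes carry the protospacer
# reverse-complemented on the coding strand with the CCN PAM complement
# immediately 5', so the guide finds an NGG match on the minus strand.
makeCassette <- function(protospacer, antisense = TRUE) {
  assertACGT(protospacer, "protospacer")
  core <- function(n1) {
    if (antisense) paste0("CC", n1, revComp(protospacer))
    else paste0(protospacer, n1, "GG")
  }
  padLen <- (3L - nchar(core("A")) %% 3L) %% 3L
  pads <- if (padLen == 0L) "" else
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), padLen)), 1L, paste,
          collapse = "")
  for (n1 in c("A", "C", "G", "T")) for (pad in pads) {
    cand <- paste0(core(n1), pad)
    if (!grepl("\\*", translateCds(cand))) return(cand)
  }
  stop("protospacer cannot be embedded without creating an in-frame stop: ",
       protospacer)
}

#' Define a synthetic gliadin subgroup
#'
#' A subgroup is a protein template: signal peptide, upstream scaffold, an
#' epitope block (each listed epitope repeated \code{copies} times,
#' separated by an 'AS' spacer so no spurious epitope windows arise at the
#' junctions), and a downstream scaffold. Guide target sites are embedded as
#' in-frame protospacer+PAM cassettes at the requested region.
#'
#' @param label subgroup label (unique within a family spec).
#' @param genome subgenome of origin: "A", "B" or "D".
#' @param epitopes \code{data.frame(name, copies)}; names must exist in the
#'   epitope catalogue used downstream, copies >= 1.
#' @param guideSites optional \code{data.frame(protospacer, region, times,
#'   antisense)} with region in post_signal_peptide / epitope_upstream /
#'   epitope_internal / epitope_downstream.
#' @param signal signal peptide (amino acids).
#' @param scaffoldUp,scaffoldDown non-epitope scaffold peptides (no Q or P,
#'   so they can never harbour a catalogue epitope).
#' @return a \code{SubgroupDef} (list).
#' @export
subgroupDef <- function(label, genome, epitopes, guideSites = NULL,
                        signal = DEFAULT_SIGNAL,
                        scaffoldUp = strrep("LTSIAGVNAR", 3),
                        scaffoldDown = strrep("VSTHAGLNRI", 4)) {
  if (!genome %in% c("A", "B", "D")) stop("genome must be A, B or D")
  if (!is.data.frame(epitopes) ||
      !all(c("name", "copies") %in% colnames(epitopes)))
    stop("epitopes must be a data.frame with columns name, copies")
  if (any(epitopes$copies < 1L)) stop("epitope copies must be >= 1")
  if (grepl("[QP]", paste0(signal, scaffoldUp, scaffoldDown)))
    stop("signal/scaffold peptides must not contain Q or P")
  if (!is.null(guideSites)) {
    if (!all(c("protospacer", "region") %in% colnames(guideSites)))
      stop("guideSites must have columns protospacer, region")
    if (is.null(guideSites$times)) guideSites$times <- 1L
    if (is.null(guideSites$antisense)) guideSites$antisense <- TRUE
    ok <- c("post_signal_peptide", "epitope_upstream", "epitope_internal",
            "epitope_downstream")
    if (!all(guideSites$region %in% ok))
      stop("guideSites region must be one of: ", paste(ok, collapse = ", "))
  }
  structure(list(label = label, genome = genome, epitopes = epitopes,
                 guideSites = guideSites, signal = signal,
                 scaffoldUp = scaffoldUp, scaffoldDown = scaffoldDown),
            class = "SubgroupDef")
}

#' Define a synthetic gliadin family
#'
#' Study-condition defaults live in \code{\link{defaultAlphaSpec}},
#' \code{\link{defaultGammaSpec}} and \code{\link{defaultOmegaSpec}}.
#'
#' @param family "alpha", "gamma" or "omega".
#' @param nCopies total gene copies to generate (>= number of subgroups).
#' @param pseudogeneFraction probability that a copy is pseudogenised.
#' @param subgroups list of \code{\link{subgroupDef}} objects, at least one
#'   per represented genome.
#' @param lociPerGenome tandem loci per subgenome (used by locus assembly).
#' @param diploidFraction fraction of each subgroup's members labelled as
#'   originating from a diploid relative (known subgenome), at least one
#'   per subgroup.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return a \code{FamilySpec} (list).
#' @export
familySpec <- function(family, nCopies, pseudogeneFraction, subgroups,
                       lociPerGenome = 1L, diploidFraction = 0.3,
                       seed = 1L) {
  if (!family %in% c("alpha", "gamma", "omega"))
    stop("family must be one of alpha, gamma, omega")
  assertCount(nCopies, "nCopies")
  assertProbability(pseudogeneFraction, "pseudogeneFraction")
  assertProbability(diploidFraction, "diploidFraction")
  assertCount(lociPerGenome, "lociPerGenome")
  if (!length(subgroups)) stop("subgroups must be non-empty")
  labs <- vapply(subgroups, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("subgroup labels must be unique")
  if (nCopies < length(subgroups))
    stop("nCopies must be >= number of subgroups")
  structure(list(family = family, nCopies = as.integer(nCopies),
                 pseudogeneFraction = pseudogeneFraction,
                 subgroups = subgroups,
                 lociPerGenome = as.integer(lociPerGenome),
                 diploidFraction = diploidFraction,
                 seed = as.integer(seed)),
            class = "FamilySpec")
}

# Assemble one gene as a list of (role, dna) segments. Codon jitter uses the
# current RNG stream; cassettes come pre-built so guide target sites are
# identical across the subgroup's members.
assembleGene <- function(sg, catalogue, cassettes) {
  segs <- list()
  add <- function(role, dna) segs[[length(segs) + 1L]] <<- list(role = role,
                                                                dna = dna)
  addSites <- function(region) {
    gs <- sg$guideSites
    if (is.null(gs)) return(invisible())
    for (i in which(gs$region == region))
      for (k in seq_len(gs$times[i])) add("cassette", cassettes[[i]])
  }
  add("signal", revTranslate(sg$signal))
  addSites("post_signal_peptide")
  add("scaffold", revTranslate(sg$scaffoldUp))
  addSites("epitope_upstream")
  peps <- rep(catalogue$peptide[match(sg$epitopes$name, catalogue$name)],
              sg$epitopes$copies)
  if (anyNA(peps)) stop("subgroup ", sg$label,
                        " references epitopes absent from the catalogue")
  gs <- sg$guideSites
  internal <- if (is.null(gs)) integer(0) else which(gs$region ==
                                                     "epitope_internal")
  remaining <- if (length(internal)) setNames(gs$times[internal],
                                              internal) else integer(0)
  for (j in seq_along(peps)) {
    add("separator", revTranslate("AS"))
    add("epitope", revTranslate(peps[j]))
    for (i in names(remaining)) if (remaining[[i]] > 0L) {
      add("cassette", cassettes[[as.integer(i)]])
      remaining[[i]] <- remaining[[i]] - 1L
    }
  }
  # any internal cassettes still owed (times > number of epitope copies)
  for (i in names(remaining)) if (remaining[[i]] > 0L)
    for (k in seq_len(remaining[[i]])) add("cassette", cassettes[[as.integer(i)]])
  add("separator", revTranslate("AS"))
  addSites("epitope_downstream")
  add("scaffold", revTranslate(sg$scaffoldDown))
  add("stop", "TAA")
  segs
}

# Replace one randomly chosen scaffold codon by TAA (premature stop).
pseudogenise <- function(segs) {
  offs <- 0L
  codons <- list()
  for (s in segs) {
    if (s$role == "scaffold")
      codons[[length(codons) + 1L]] <- offs + seq(1L, nchar(s$dna), by = 3L)
    offs <- offs + nchar(s$dna)
  }
  pos <- unlist(codons)
  at <- pos[sample.int(length(pos), 1L)]
  dna <- paste(vapply(segs, `[[`, "", "dna"), collapse = "")
  paste0(substr(dna, 1L, at - 1L), "TAA", substr(dna, at + 3L, nchar(dna)))
}

#' Generate a synthetic gliadin gene family
#'
#' Draws \code{nCopies} intronless genes from the subgroup templates in
#' \code{spec}:
#' members of a subgroup share the same protein (signal peptide, scaffold,
#' epitope block, embedded guide target cassettes) but differ at synonymous
#' codon positions. Each gene is independently pseudogenised with
#' probability \code{pseudogeneFraction} by substituting one random scaffold
#' codon with a stop codon, so guide target sites and the DNA epitope block
#' survive in pseudogenes (as in real gliadin arrays, where pseudogenes
#' retain near-intact sequence). A fixed seed gives byte-identical output.
#'
#' @param spec a \code{\link{familySpec}}.
#' @param catalogue epitope catalogue resolving the subgroup epitope names.
#' @return a \code{\link{GliadinGeneSet}}; the per-subgroup ground truth
#'   (template protein, genome, members) is stored in
#'   \code{metadata(geneInfo(x))$subgroups}.
#' @examples
#' fam <- generateFamily(defaultAlphaSpec(nCopies = 10,
#'                                        pseudogeneFraction = 0, seed = 7))
#' fam
#' @export
generateFamily <- function(spec, catalogue = cdEpitopes()) {
  stopifnot(inherits(spec, "FamilySpec"))
  k <- length(spec$subgroups)
  sizes <- rep(spec$nCopies %/% k, k)
  extra <- spec$nCopies %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  diploidSpecies <- c(A = "Triticum monococcum", B = "Aegilops speltoides",
                      D = "Aegilops tauschii")
  withSeed(spec$seed, {
    rows <- list(); seqs <- character(); truth <- list()
    for (si in seq_len(k)) {
      sg <- spec$subgroups[[si]]
      cassettes <- if (is.null(sg$guideSites)) list() else
        lapply(seq_len(nrow(sg$guideSites)), function(i)
          makeCassette(sg$guideSites$protospacer[i],
                       sg$guideSites$antisense[i]))
      nDip <- max(1L, round(spec$diploidFraction * sizes[si]))
      dip <- sample.int(sizes[si], min(nDip, sizes[si]))
      templateProt <- NULL
      for (gi in seq_len(sizes[si])) {
        segs <- assembleGene(sg, catalogue, cassettes)
        isPseudo <- runif(1L) < spec$pseudogeneFraction
        dna <- if (isPseudo) pseudogenise(segs) else
          paste(vapply(segs, `[[`, "", "dna"), collapse = "")
        if (is.null(templateProt))
          templateProt <- translateCds(
            paste(vapply(segs, `[[`, "", "dna"), collapse = ""))
        id <- sprintf("%s_%s_%03d", spec$family, sg$label, gi)
        isDip <- gi %in% dip
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = id, family = spec$family,
          genome = if (isDip) sg$genome else "unknown",
          subgroup = sg$label,
          species = if (isDip) diploidSpecies[[sg$genome]]
                    else "Triticum aestivum",
          planted_pseudogene = isPseudo)
        seqs[id] <- dna
      }
      truth[[sg$label]] <- list(label = sg$label, genome = sg$genome,
                                n_members = sizes[si],
                                template_protein = templateProt)
    }
    gd <- DataFrame(do.call(rbind, rows))
    S4Vectors::metadata(gd)$subgroups <- truth
    GliadinGeneSet(DNAStringSet(seqs), gd)
  })
}

#' Assemble genes into a tandem locus
#'
#' Places the genes, in the order given, on the plus strand of one
#' contiguous sequence separated by random intergenic spacers.
#'
#' @param genes a \code{GliadinGeneSet} with at least one gene.
#' @param spacerRange integer length-2 vector: inclusive range of intergenic
#'   spacer lengths (nt).
#' @param seed RNG seed for spacer lengths and composition.
#' @param locusId locus identifier.
#' @param genome subgenome label; defaults to the most common known label
#'   among the genes, else "A".
#' @return a \code{\link{LocusModel}}.
#' @examples
#' fam <- generateFamily(defaultAlphaSpec(nCopies = 5,
#'                                        pseudogeneFraction = 0, seed = 3))
#' generateLocus(fam, c(50, 150), seed = 3)
#' @export
generateLocus <- function(genes, spacerRange = c(200L, 1000L), seed = 1L,
                          locusId = "locus1", genome = NULL) {
  stopifnot(is(genes, "GliadinGeneSet"))
  if (length(genes) < 1L) stop("at least one gene is required")
  if (length(spacerRange) != 2L || spacerRange[1L] > spacerRange[2L] ||
      spacerRange[1L] < 0L)
    stop("spacerRange must be a non-negative increasing length-2 vector")
  if (is.null(genome)) {
    known <- genomeLabel(genes)[genomeLabel(genes) != "unknown"]
    genome <- if (length(known)) names(sort(table(known),
                                            decreasing = TRUE))[1L] else "A"
  }
  withSeed(seed, {
    dna <- as.character(geneSequences(genes))
    n <- length(dna)
    lens <- seq(spacerRange[1L], spacerRange[2L])
    spacers <- vapply(seq_len(n - 1L), function(i) {
      len <- lens[sample.int(length(lens), 1L)]
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, "")
    starts <- integer(n); pos <- 0L
    pieces <- character()
    for (i in seq_len(n)) {
      starts[i] <- pos + 1L
      pieces <- c(pieces, dna[i])
      pos <- pos + nchar(dna[i])
      if (i < n) {
        pieces <- c(pieces, spacers[i])
        pos <- pos + nchar(spacers[i])
      }
    }
    rng <- IRanges(start = starts, width = nchar(dna))
    names(rng) <- geneIds(genes)
    new("LocusModel", locusId = locusId, genome = genome,
        sequence = DNAString(paste(pieces, collapse = "")),
        geneRanges = rng)
  })
}

#' Embed guide target sites into existing genes
#'
#' Inserts an in-frame protospacer+PAM cassette into each gene of a set at a
#' position determined by the gene's own domain annotation. Used to plant
#' known guide target sites (e.g. the published protospacers) in arbitrary
#' synthetic genes; insertion preserves the reading frame of all flanking
#' sequence and refuses motifs that cannot be embedded without an in-frame
#' stop.
#'
#' @param genes a \code{GliadinGeneSet}.
#' @param motif protospacer (ACGT, 17-23 nt).
#' @param region one of post_signal_peptide, epitope_upstream,
#'   epitope_internal, epitope_downstream.
#' @param times number of adjacent cassette copies to insert (default 1).
#' @param antisense if \code{TRUE} (the default, matching the published
#'   guides) the coding strand receives the reverse complement of the
#'   protospacer with a CCN PAM complement 5' of it.
#' @param which optional index/id subset of genes to modify.
#' @param catalogue,signalLength passed to the annotation used to locate the
#'   insertion point.
#' @return the modified \code{GliadinGeneSet}.
#' @export
embedGuideTargets <- function(genes, motif, region = "epitope_upstream",
                              times = 1L, antisense = TRUE, which = NULL,
                              catalogue = cdEpitopes(), signalLength = 20L) {
  stopifnot(is(genes, "GliadinGeneSet"))
  if (nchar(motif) < 17L || nchar(motif) > 23L)
    stop("motif must be 17-23 nt")
  assertACGT(motif, "motif")
  assertCount(times, "times")
  cassette <- strrep(makeCassette(motif, antisense), times)
  idx <- if (is.null(which)) seq_len(length(genes)) else {
    if (is.character(which)) match(which, geneIds(genes)) else which
  }
  ann <- annotateGenes(genes, catalogue, signalLength)
  seqs <- as.character(geneSequences(genes))
  for (i in idx) {
    id <- geneIds(genes)[i]
    dom <- ann$domains[ann$domains$gene_id == id, , drop = FALSE]
    ep <- dom[dom$domain == "epitope_region", , drop = FALSE]
    insAA <- switch(region,
      post_signal_peptide = signalLength,
      epitope_upstream = if (nrow(ep)) ep$start - 1L else signalLength,
      epitope_internal = if (nrow(ep)) ep$start + 8L else
        stop("gene ", id, " has no epitope region for epitope_internal"),
      epitope_downstream = if (nrow(ep)) ep$end else
        nchar(ann$proteins[[id]]) - 1L,
      stop("unknown region: ", region))
    at <- 3L * insAA  # DNA offset (codon boundary) after which to insert
    seqs[i] <- paste0(substr(seqs[i], 1L, at), cassette,
                      substr(seqs[i], at + 1L, nchar(seqs[i])))
  }
  GliadinGeneSet(DNAStringSet(seqs), geneInfo(genes))
}
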