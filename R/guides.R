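#' @include AllClasses.R utils.R annotation.R
#' @importFrom Biostrings matchPattern neditStartingAt reverseComplement
NULL

# Count mismatches between an IUPAC query and a plain-ACGT window, and
# return the mismatching query positions.
iupacMismatchPositions <- function(query, window) {
  q <- strsplit(query, "")[[1L]]
  w <- strsplit(window, "")[[1L]]
  which(!mapply(function(a, b) b %in% IUPAC_SETS[[a]], q, w))
}

matchOneStrand <- function(query, subject, maxMismatch) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(query),
                                   Biostrings::DNAString(subject),
                                   max.mismatch = maxMismatch,
                                   fixed = FALSE)
  if (!length(hits)) return(NULL)
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(query),
                                    Biostrings::DNAString(subject),
                                    starting.at = IRanges::start(hits),
                                    fixed = FALSE)
  data.frame(start = IRanges::start(hits), end = IRanges::end(hits),
             mismatches = as.integer(mm))
}

#' Match a guide protospacer against a coding sequence
#'
#' Scans both strands of \code{subject} for the protospacer, allowing up to
#' \code{maxMismatch} mismatches (mismatches in the PAM are not counted; a
#' valid NGG PAM immediately 3' of the protospacer on the matched strand is
#' required unless \code{requirePam = FALSE}). IUPAC degenerate codes in
#' the query are honoured, so the published degenerate cloning primers can
#' be matched with the same machinery. Coordinates are 1-based inclusive on
#' the stored (plus/coding) strand; \code{cut} is the between-base cut
#' index expressed as the number of bases 5' of the blunt cut on the coding
#' strand, 3 bp 5' of the PAM on the matched strand (SpCas9 convention).
#'
#' @param guide protospacer string, 17-23 nt, IUPAC codes allowed.
#' @param subject a DNA string, \code{DNAString}, named character vector or
#'   \code{GliadinGeneSet}.
#' @param maxMismatch maximum non-PAM mismatches (default 0).
#' @param requirePam require NGG immediately 3' of the match.
#' @return \code{data.frame(gene_id, start, end, strand, mismatches, pam,
#'   cut)}, sorted by gene then start.
#' @examples
#' g <- "ATGGTTGTTGTGATGGAAA"
#' dna <- paste0("AAAA", g, "TGGAAAA")  # sense match with PAM TGG
#' matchGuide(g, dna)
#' @export
matchGuide <- function(guide, subject, maxMismatch = 0L,
                       requirePam = TRUE) {
  if (maxMismatch < 0L) stop("maxMismatch must be >= 0")
  guide <- toupper(as.character(guide))
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")),
            guide))
    stop("guide contains characters outside the IUPAC DNA alphabet")
  seqs <- if (is(subject, "GliadinGeneSet"))
    as.character(geneSequences(subject))
  else if (is(subject, "DNAString")) setNames(as.character(subject), "seq1")
  else {
    subject <- vapply(subject, as.character, "")
    if (is.null(names(subject)))
      names(subject) <- paste0("seq", seq_along(subject))
    subject
  }
  plen <- nchar(guide)
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    fwd <- matchOneStrand(guide, s, maxMismatch)
    if (!is.null(fwd) && nrow(fwd)) {
      fwd$strand <- "+"
      fwd$pam <- substr(rep(s, nrow(fwd)), fwd$end + 1L, fwd$end + 3L)
      fwd$cut <- fwd$end - 3L
      if (requirePam) {
        ok <- nchar(fwd$pam) == 3L & substr(fwd$pam, 2L, 3L) == "GG"
        fwd <- fwd[ok, , drop = FALSE]
      }
    }
    rcs <- revComp(s)
    rev <- matchOneStrand(guide, rcs, maxMismatch)
    if (!is.null(rev) && nrow(rev)) {
      # map [start,end] on the reverse complement back to coding coords
      cs <- L - rev$end + 1L
      ce <- L - rev$start + 1L
      rev <- data.frame(start = cs, end = ce, mismatches = rev$mismatches,
                        strand = "-",
                        pam = vapply(cs, function(p)
                          if (p > 3L) revComp(substr(s, p - 3L, p - 1L))
                          else "", ""),
                        cut = cs + 2L)
      if (requirePam) {
        ok <- rev$start > 3L & substr(rev$pam, 2L, 3L) == "GG"
        rev <- rev[ok, , drop = FALSE]
      }
    }
    hits <- rbind(fwd, rev)
    if (!is.null(hits) && nrow(hits)) {
      hits <- cbind(gene_id = id, hits)
      out[[length(out) + 1L]] <- hits[order(hits$start), , drop = FALSE]
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), mismatches = integer(),
                      strand = character(), pam = character(),
                      cut = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict Cas9 cut sites for a guide in a gene
#'
#' Perfect, PAM-adjacent matches only; one blunt cut per match, 3 bp 5' of
#' the PAM on the matched strand. A gene carrying k copies of the target
#' motif yields exactly k cuts (the design expectation for the guide
#' targeting the repeated DQ2.5-glia-g4c motif: 1 to 6 cuts per gene).
#'
#' @param guide protospacer (ACGT).
#' @param subject a single sequence or \code{GliadinGeneSet}.
#' @return \code{data.frame(gene_id, cut)}; \code{cut} is a between-base
#'   index (bases 5' of the cut) on the coding strand.
#' @export
predictCutSites <- function(guide, subject) {
  m <- matchGuide(guide, subject, maxMismatch = 0L, requirePam = TRUE)
  res <- m[, c("gene_id", "cut")]
  res[order(res$gene_id, res$cut), , drop = FALSE]
}

#' Per-subgroup guide coverage matrix
#'
#' For every guide and every subgroup, the number of member genes carrying
#' at least one perfect PAM-adjacent match. A guide "covers" a subgroup if
#' at least one member matches, and covers all subgroups if every column of
#' its row is positive.
#'
#' @param guides \code{data.frame} with columns \code{name},
#'   \code{protospacer} (e.g. \code{\link{gliadinGuides}()}).
#' @param genes the \code{GliadinGeneSet} that was classified.
#' @param membership \code{data.frame(gene_id, label)} from
#'   \code{\link{classifyFamily}}.
#' @return list with \code{counts} (guides x subgroups integer matrix),
#'   \code{subgroupSizes}, \code{guideTotals} (distinct genes hit among the
#'   classified members) and \code{coversAllSubgroups} (named logical).
#' @export
coverageMatrix <- function(guides, genes, membership) {
  labs <- sort(unique(membership$label))
  counts <- matrix(0L, nrow = nrow(guides), ncol = length(labs),
                   dimnames = list(guides$name, labs))
  totals <- integer(nrow(guides))
  for (i in seq_len(nrow(guides))) {
    m <- matchGuide(guides$protospacer[i], genes, maxMismatch = 0L,
                    requirePam = TRUE)
    hitGenes <- intersect(unique(m$gene_id), membership$gene_id)
    totals[i] <- length(hitGenes)
    if (length(hitGenes)) {
      t <- table(membership$label[membership$gene_id %in% hitGenes])
      counts[i, names(t)] <- as.integer(t)
    }
  }
  sizes <- table(factor(membership$label, levels = labs))
  stopifnot(all(t(counts) <= as.integer(sizes)))
  list(counts = counts,
       subgroupSizes = setNames(as.integer(sizes), labs),
       guideTotals = setNames(totals, guides$name),
       coversAllSubgroups = setNames(rowSums(counts > 0L) == length(labs),
                                     guides$name))
}

#' Scan a background sequence set for guide off-targets
#'
#' Reports every match with at most \code{maxMismatch} non-PAM mismatches
#' (NGG PAM required) and flags whether the PAM-proximal 12 nt -- the seed
#' region that dominates Cas9 specificity -- are mismatch-free.
#'
#' @param guide protospacer.
#' @param background \code{GliadinGeneSet}, named character vector or
#'   \code{DNAStringSet}.
#' @param maxMismatch default 3.
#' @return the \code{\link{matchGuide}} data.frame with an added logical
#'   \code{seed12_clean} column.
#' @export
offTargetScan <- function(guide, background, maxMismatch = 3L) {
  if (is(background, "DNAStringSet"))
    background <- setNames(as.character(background),
                           names(background))
  m <- matchGuide(guide, background, maxMismatch = maxMismatch,
                  requirePam = TRUE)
  if (!nrow(m)) {
    m$seed12_clean <- logical(0)
    return(m)
  }
  seqs <- if (is(background, "GliadinGeneSet"))
    setNames(as.character(geneSequences(background)), geneIds(background))
  else background
  plen <- nchar(guide)
  m$seed12_clean <- vapply(seq_len(nrow(m)), function(i) {
    window <- substr(seqs[[m$gene_id[i]]], m$start[i], m$end[i])
    if (m$strand[i] == "-") window <- revComp(window)
    pos <- iupacMismatchPositions(guide, window)
    # PAM-proximal = 3' end of the protospacer on the matched strand
    !any(pos > plen - 12L)
  }, TRUE)
  m
}

#' Find conserved protospacer-sized windows across a gene family
#'
#' Enumerates every k-mer on both strands of each (non-pseudogene) gene and
#' reports the windows shared by at least \code{minFraction} of the genes,
#' optionally restricted to a protein-domain region -- the strategy used to
#' place guides on relatively conserved stretches near the epitope region.
#'
#' @param genes a \code{GliadinGeneSet}.
#' @param k window size in nt (>= 20; protospacer+PAM scanning uses 23).
#' @param minFraction minimum fraction of distinct genes containing the
#'   window.
#' @param region optional region class (post_signal_peptide,
#'   epitope_upstream, epitope_internal, epitope_downstream): windows must
#'   lie within the corresponding DNA interval of each gene.
#' @param ann optional precomputed annotation (needed for \code{region}).
#' @return \code{data.frame(window, fraction, n_genes)}, sorted by
#'   descending fraction.
#' @export
findConservedWindows <- function(genes, k = 23L, minFraction = 0.5,
                                 region = NULL, ann = NULL) {
  stopifnot(is(genes, "GliadinGeneSet"))
  if (k < 20L) stop("k must be >= 20")
  seqs <- as.character(geneSequences(genes))
  if (k > min(nchar(seqs)))
    stop("k exceeds the shortest gene length")
  if (!is.null(region) && is.null(ann)) ann <- annotateGenes(genes)
  perGene <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    lo <- 1L; hi <- nchar(s)
    if (!is.null(region)) {
      dom <- ann$domains[ann$domains$gene_id == id, , drop = FALSE]
      ep <- dom[dom$domain == "epitope_region", , drop = FALSE]
      sig <- dom[dom$domain == "signal_peptide", , drop = FALSE]
      sigEnd <- if (nrow(sig)) sig$end else 0L
      bounds <- switch(region,
        post_signal_peptide = c(3L * sigEnd + 1L, hi),
        epitope_upstream = c(3L * sigEnd + 1L,
                             if (nrow(ep)) 3L * (ep$start - 1L) else hi),
        epitope_internal = if (nrow(ep))
          c(3L * (ep$start - 1L) + 1L, 3L * ep$end) else c(1L, 0L),
        epitope_downstream = c(if (nrow(ep)) 3L * ep$end + 1L else
          3L * sigEnd + 1L, hi),
        stop("unknown region: ", region))
      lo <- bounds[1L]; hi <- bounds[2L]
    }
    if (hi - lo + 1L < k) return(character(0))
    starts <- lo:(hi - k + 1L)
    win <- substring(s, starts, starts + k - 1L)
    unique(c(win, vapply(win, revComp, "", USE.NAMES = FALSE)))
  })
  tab <- table(unlist(perGene))
  frac <- as.numeric(tab) / length(seqs)
  keep <- frac >= minFraction
  out <- data.frame(window = names(tab)[keep], fraction = frac[keep],
                    n_genes = as.integer(tab)[keep])
  out <- out[order(-out$fraction, out$window), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hairpin (self-complementarity) heuristic for a protospacer
#'
#' Finds the longest exact Watson-Crick stem formed by two non-overlapping
#' substrings of the protospacer separated by a loop of at least
#' \code{minLoop} bases -- a fast screen for guide secondary structure that
#' can impair target binding.
#'
#' @param protospacer ACGT string.
#' @param minStem stem length at or above which the guide is flagged.
#' @param minLoop minimum loop length (>= 3).
#' @return list(stem = max stem length, flagged = logical).
#' @examples
#' hairpinFlag("GGGGCCAAAGGCCCC", minStem = 4)
#' @export
hairpinFlag <- function(protospacer, minStem = 8L, minLoop = 3L) {
  if (minLoop < 3L) stop("minLoop must be >= 3")
  s <- strsplit(toupper(as.character(protospacer)), "")[[1L]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0L
  if (n >= minLoop + 2L) {
    for (i in seq_len(n - 1L)) {
     if (i + minLoop + 1L > n) break
     for (j in seq(i + minLoop + 1L, n)) {
      m <- 0L
      while (i + m <= n && j - m >= 1L &&
             (j - m) - (i + m) - 1L >= minLoop &&
             comp[[s[i + m]]] == s[j - m]) m <- m + 1L
      if (m > best) best <- m
     }
    }
  }
  list(stem = best, flagged = best >= minStem)
}

#' Cross-dimer heuristic for a pair of protospacers
#'
#' Longest contiguous antiparallel Watson-Crick complementary run between
#' two oligos (the longest common substring of \code{a} and the reverse
#' complement of \code{b}); symmetric in its arguments. Used to screen
#' multiplexed guide combinations.
#'
#' @param a,b ACGT strings.
#' @param minRun run length at or above which the pair is flagged.
#' @return list(run = longest complementary run, flagged = logical).
#' @examples
#' crossDimerFlag("ACGTACGT", revComp("ACGTACGT"), minRun = 8)
#' @export
crossDimerFlag <- function(a, b, minRun = 10L) {
  x <- strsplit(toupper(as.character(a)), "")[[1L]]
  y <- strsplit(revComp(toupper(as.character(b))), "")[[1L]]
  n <- length(x); m <- length(y)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    for (j in seq_len(m)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  list(run = best, flagged = best >= minRun)
}
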