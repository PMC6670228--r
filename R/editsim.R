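#' @include AllClasses.R guides.R annotation.R
NULL

sampleSize <- function(sizes, weights) {
  sizes[sample.int(length(sizes), 1L, prob = weights)]
}

#' Classify the consequence of an edit on one gene
#'
#' Compares a gene's coding sequence before and after editing: identical
#' sequences are \code{unchanged}; a net length change not divisible by 3
#' is a \code{frameshift_ko}; an in-frame change introducing a new internal
#' stop codon is a \code{nonsense_ko}; any other in-frame change is an
#' \code{inframe_edit}. A small out-of-frame mutation upstream of the
#' epitope region therefore knocks the gliadin out, while an in-frame
#' excision of the epitope region leaves a shortened, intact protein.
#'
#' @param before,after coding sequences (ACGT strings).
#' @return one of \code{"unchanged"}, \code{"inframe_edit"},
#'   \code{"frameshift_ko"}, \code{"nonsense_ko"}.
#' @examples
#' classifyConsequence("ATGGCTGCATAA", "ATGGCATAA")   # in-frame deletion
#' classifyConsequence("ATGGCTGCATAA", "ATGGCTGCTAA") # frameshift
#' @export
classifyConsequence <- function(before, after) {
  before <- as.character(before); after <- as.character(after)
  if (identical(before, after)) return("unchanged")
  if ((nchar(after) - nchar(before)) %% 3L != 0L) return("frameshift_ko")
  pb <- suppressWarnings(translateCds(before))
  pa <- suppressWarnings(translateCds(after))
  newStop <- as.logical(callPseudogene(pa)) &&
    !as.logical(callPseudogene(pb))
  if (newStop) "nonsense_ko" else "inframe_edit"
}

countHits <- function(protein, catalogue) {
  nrow(scanEpitopes(protein, catalogue))
}

#' Apply Cas9 cuts and stochastic repair to one locus allele
#'
#' Cuts (between-base indices on the locus coding strand, from
#' \code{\link{predictCutSites}} mapped to locus coordinates) are processed
#' left to right. Each adjacent pair excises the intervening segment with
#' probability \code{pSegmentDeletion}: genes fully contained in the
#' excision are \code{deleted}; when the two cuts lie in different genes
#' the flanking genes are \code{fusion}; when both lie in one gene the
#' excision is an ordinary within-gene edit. Unpaired cuts resolve
#' independently: perfect re-ligation with probability
#' \code{pPerfectRepair}, otherwise a small deletion (immediately 5' of the
#' cut) or insertion of random bases. Downstream gene coordinates shift
#' accordingly. Uses the current RNG stream; seed the caller.
#'
#' @param locus a \code{\link{LocusModel}} (one allele).
#' @param cuts integer vector of between-base cut indices; intergenic cuts
#'   are legal.
#' @param policy a \code{\link{repairPolicy}}.
#' @param catalogue epitope catalogue used for the per-gene epitope delta.
#' @return a list of class \code{EditOutcome}: \code{sequence} (edited
#'   allele), \code{genes} (\code{data.frame(gene_id, consequence,
#'   new_start, new_end, epitope_delta)}; deleted genes have NA
#'   coordinates) and \code{segmentDeletions} (excised spans on the
#'   original coordinates).
#' @examples
#' fam <- generateFamily(defaultAlphaSpec(nCopies = 3,
#'                                        pseudogeneFraction = 0, seed = 5))
#' loc <- generateLocus(fam, c(50, 50), seed = 5)
#' cuts <- predictCutSites("ATGGTTGTTGTGATGGAAA", locusSequence(loc))$cut
#' set.seed(1)
#' out <- applyCuts(loc, cuts, repairPolicy(pSegmentDeletion = 1))
#' out$genes
#' @export
applyCuts <- function(locus, cuts, policy, catalogue = cdEpitopes()) {
  stopifnot(is(locus, "LocusModel"), is(policy, "RepairPolicy"))
  s <- as.character(locusSequence(locus))
  L <- nchar(s)
  cuts <- sort(unique(as.integer(cuts)))
  if (length(cuts) && (min(cuts) < 0L || max(cuts) > L))
    stop("cut indices must lie within the locus")
  kept <- rep(TRUE, L)
  insAt <- integer(0); insSeq <- character(0)
  spans <- list()
  i <- 1L
  while (i <= length(cuts)) {
    if (i < length(cuts) && runif(1L) < policy@pSegmentDeletion) {
      a <- cuts[i]; b <- cuts[i + 1L]
      kept[(a + 1L):b] <- FALSE
      spans[[length(spans) + 1L]] <- c(a + 1L, b)
      i <- i + 2L
    } else {
      cc <- cuts[i]
      if (runif(1L) >= policy@pPerfectRepair) {
        if (runif(1L) < policy@pDeletion) {
          d <- sampleSize(policy@delSizes, policy@delWeights)
          if (cc >= 1L) kept[max(1L, cc - d + 1L):cc] <- FALSE
          else kept[seq_len(min(d, L))] <- FALSE
        } else {
          k <- sampleSize(policy@insSizes, policy@insWeights)
          insAt <- c(insAt, cc)
          insSeq <- c(insSeq, paste(sample(c("A", "C", "G", "T"), k,
                                           replace = TRUE), collapse = ""))
        }
      }
      i <- i + 1L
    }
  }
  rng <- geneRanges(locus)
  ids <- names(rng)
  gs <- setNames(IRanges::start(rng), ids)
  ge <- setNames(IRanges::end(rng), ids)
  owner <- rep(NA_character_, L)
  for (id in ids) owner[gs[[id]]:ge[[id]]] <- id

  # emit surviving bases plus insertions, in coordinate order
  chars <- strsplit(s, "")[[1L]]
  keys <- as.numeric(which(kept))
  emitChars <- chars[kept]
  emitOwner <- owner[kept]
  for (j in seq_along(insAt)) {
    t <- insAt[j]
    ichars <- strsplit(insSeq[j], "")[[1L]]
    io <- NA_character_
    for (id in ids) if (t >= gs[[id]] && t < ge[[id]]) io <- id
    keys <- c(keys, t + 0.5 + seq_along(ichars) * 1e-4)
    emitChars <- c(emitChars, ichars)
    emitOwner <- c(emitOwner, rep(io, length(ichars)))
  }
  ord <- order(keys)
  emitChars <- emitChars[ord]; emitOwner <- emitOwner[ord]
  newSeq <- paste(emitChars, collapse = "")

  # fusion / deletion labels from segment-deletion spans
  fused <- character(0); removed <- character(0)
  for (sp in spans) {
    part <- ids[pmax(gs, sp[1L]) <= pmin(ge, sp[2L])]  # overlapping genes
    contained <- part[gs[part] >= sp[1L] & ge[part] <= sp[2L]]
    partial <- setdiff(part, contained)
    removed <- c(removed, contained)
    if (length(partial) >= 2L) fused <- c(fused, partial)
  }

  genes <- lapply(ids, function(id) {
    pos <- which(emitOwner == id)
    oldSeqG <- substr(s, gs[[id]], ge[[id]])
    oldProt <- suppressWarnings(translateCds(oldSeqG))
    oldHits <- countHits(oldProt, catalogue)
    if (!length(pos) || id %in% removed)
      return(data.frame(gene_id = id, consequence = "deleted",
                        new_start = NA_integer_, new_end = NA_integer_,
                        epitope_delta = -oldHits))
    newSeqG <- paste(emitChars[pos], collapse = "")
    newProt <- if (nchar(newSeqG) >= 3L)
      suppressWarnings(translateCds(newSeqG)) else ""
    delta <- (if (nzchar(newProt)) countHits(newProt, catalogue) else 0L) -
      oldHits
    cons <- if (id %in% fused) "fusion" else
      classifyConsequence(oldSeqG, newSeqG)
    data.frame(gene_id = id, consequence = cons,
               new_start = min(pos), new_end = max(pos),
               epitope_delta = delta)
  })
  structure(list(sequence = newSeq, genes = do.call(rbind, genes),
                 segmentDeletions = spans),
            class = "EditOutcome")
}

#' Assemble a wild-type hexaploid genotype template
#'
#' Builds the per-plant genotype used by \code{\link{simulateScreen}}: for
#' each family spec and each subgenome (A, B, D), one tandem locus of
#' \code{genesPerLocus} genes drawn from that genome's subgroups, carried
#' in two identical alleles (diploid behaviour of each subgenome).
#'
#' @param specs list of \code{\link{familySpec}} objects.
#' @param genesPerLocus genes per tandem locus.
#' @param spacerRange intergenic spacer length range (nt).
#' @param seed RNG seed.
#' @return list of class \code{WheatGenotype}: \code{alleles} (list of
#'   \code{LocusModel}, two per locus), \code{families} (named gene_id ->
#'   family map).
#' @export
makeHexaploidGenotype <- function(specs, genesPerLocus = 2L,
                                  spacerRange = c(100L, 100L), seed = 1L) {
  alleles <- list(); families <- character(0)
  for (spec in specs) {
    fam <- generateFamily(familySpec(spec$family,
                                     spec$nCopies, spec$pseudogeneFraction,
                                     spec$subgroups, spec$lociPerGenome,
                                     spec$diploidFraction,
                                     seed = spec$seed + 13L))
    sgGenome <- vapply(spec$subgroups, `[[`, "", "genome")
    names(sgGenome) <- vapply(spec$subgroups, `[[`, "", "label")
    for (g in c("A", "B", "D")) {
      sel <- which(sgGenome[subgroupLabel(fam)] == g)
      if (!length(sel)) next
      sel <- sel[seq_len(min(genesPerLocus, length(sel)))]
      sub <- fam[sel]
      loc <- generateLocus(sub, spacerRange, seed = seed,
                           locusId = sprintf("%s_%s", spec$family, g),
                           genome = g)
      alleles <- c(alleles, list(loc), list(loc))
      families[geneIds(sub)] <- spec$family
    }
  }
  structure(list(alleles = alleles, families = families),
            class = "WheatGenotype")
}

# Profile contribution of one allele: counts of intact proteins per
# (family, mass bin). Intact = translated without internal stop and, for
# edited alleles, consequence unchanged or inframe_edit.
alleleProfile <- function(locus, outcome, families, binWidth = 500,
                          massPerResidue = 110) {
  rng <- geneRanges(locus)
  ids <- names(rng)
  prof <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (is.null(outcome)) {
      seqG <- substr(as.character(locusSequence(locus)),
                     IRanges::start(rng)[i], IRanges::end(rng)[i])
    } else {
      row <- outcome$genes[outcome$genes$gene_id == id, , drop = FALSE]
      if (!row$consequence %in% c("unchanged", "inframe_edit")) next
      seqG <- substr(outcome$sequence, row$new_start, row$new_end)
    }
    prot <- suppressWarnings(translateCds(seqG))
    if (as.logical(callPseudogene(prot))) next
    stopAt <- regexpr("*", prot, fixed = TRUE)
    residues <- if (stopAt > 0L) stopAt - 1L else nchar(prot)
    fam <- families[id]
    if (is.na(fam)) fam <- "unknown"
    bin <- round(massPerResidue * residues / binWidth)
    prof <- c(prof, sprintf("%s:%d", fam, bin))
  }
  if (!length(prof)) return(integer(0))
  tab <- table(prof)
  setNames(as.integer(tab), names(tab))
}

addProfiles <- function(a, b) {
  keys <- union(names(a), names(b))
  if (!length(keys)) return(integer(0))
  va <- setNames(rep(0L, length(keys)), keys); va[names(a)] <- a
  vb <- setNames(rep(0L, length(keys)), keys); vb[names(b)] <- b
  va + vb
}

#' Predict the grain protein profile of a genotype
#'
#' Bins every intact (non-pseudogene, non-knocked-out) protein by
#' approximate mass (110 Da per residue, 0.5 kDa bins by default), the
#' package's proxy for an Acid-PAGE band profile.
#'
#' @param genotype a \code{WheatGenotype}.
#' @param outcomes optional list of \code{EditOutcome} (or NULL entries),
#'   one per allele.
#' @param binWidth mass bin width in Da.
#' @param massPerResidue average residue mass in Da.
#' @return named integer vector of (family:bin) band counts.
#' @export
predictProfile <- function(genotype, outcomes = NULL, binWidth = 500,
                           massPerResidue = 110) {
  prof <- integer(0)
  for (i in seq_along(genotype$alleles)) {
    out <- if (is.null(outcomes)) NULL else outcomes[[i]]
    prof <- addProfiles(prof,
                        alleleProfile(genotype$alleles[[i]], out,
                                      genotype$families, binWidth,
                                      massPerResidue))
  }
  prof
}

#' Compare an edited profile with the wild type
#'
#' \code{clear_change}: at least one band (family:mass bin) gained or lost
#' entirely; \code{potential_change}: the same bands but different counts
#' (an intensity-like difference); \code{none}: identical.
#'
#' @param wt,edited profiles from \code{\link{predictProfile}}.
#' @return one of \code{"none"}, \code{"potential_change"},
#'   \code{"clear_change"}.
#' @export
profileDiff <- function(wt, edited) {
  keys <- union(names(wt), names(edited))
  a <- setNames(rep(0L, length(keys)), keys); a[names(wt)] <- wt
  b <- setNames(rep(0L, length(keys)), keys); b[names(edited)] <- edited
  if (any((a > 0L) != (b > 0L))) return("clear_change")
  if (any(a != b)) return("potential_change")
  "none"
}

deterministicPolicy <- function(policy) {
  degh <- function(p) p %in% c(0, 1)
  degh(policy@pSegmentDeletion) && degh(policy@pPerfectRepair) &&
    (policy@pPerfectRepair == 1 ||
       (policy@pDeletion == 1 && length(policy@delSizes) == 1L))
}

#' Monte-Carlo mutation screen over a plant population
#'
#' Emulates the screening design of the reported experiment: per plant, a
#' fixed number of grains; per grain, every allele of every locus is edited
#' independently -- each predicted cut site fires with probability
#' \code{efficiency}, and fired cuts resolve under the repair policy. A
#' grain's protein profile is compared with the wild type and classed as
#' clear / potential / no change ("any" = clear or potential). One genotype
#' per grain; chimerism and post-meiotic editing are not modelled. Fully
#' reproducible under a fixed seed. When the repair policy is
#' deterministic, per-allele outcomes are memoised by fired-cut subset
#' (supply \code{cache} to share the memo across replicate calls with the
#' same genotype, guides and policy).
#'
#' @param genotype a \code{\link{makeHexaploidGenotype}} result.
#' @param guides character vector of protospacers (or a guides data.frame
#'   with a \code{protospacer} column).
#' @param efficiency per-cut-site firing probability in [0,1].
#' @param nPlants,grainsPerPlant screen size (default 8 grains per plant).
#' @param policy a \code{\link{repairPolicy}}.
#' @param seed RNG seed.
#' @param cache optional environment for outcome memoisation.
#' @param catalogue epitope catalogue.
#' @return list with \code{counts} (one-row data.frame: plants_tested,
#'   grains_tested, plants_clear, grains_clear, plants_any, grains_any),
#'   \code{grain_any_fraction}, \code{grain_clear_fraction} and
#'   \code{n_cut_sites} (total predicted sites over all alleles).
#' @export
simulateScreen <- function(genotype, guides, efficiency, nPlants,
                           grainsPerPlant = 8L, policy = repairPolicy(),
                           seed = 1L, cache = NULL,
                           catalogue = cdEpitopes()) {
  assertProbability(efficiency, "efficiency")
  assertCount(nPlants, "nPlants")
  assertCount(grainsPerPlant, "grainsPerPlant")
  if (is.data.frame(guides)) guides <- guides$protospacer
  nAll <- length(genotype$alleles)
  siteList <- lapply(genotype$alleles, function(loc) {
    cuts <- unlist(lapply(guides, function(g)
      predictCutSites(g, locusSequence(loc))$cut))
    sort(unique(as.integer(cuts)))
  })
  nSites <- sum(lengths(siteList))
  wtAllele <- lapply(genotype$alleles, alleleProfile, outcome = NULL,
                     families = genotype$families)
  wt <- Reduce(addProfiles, wtAllele, integer(0))
  useCache <- deterministicPolicy(policy)
  if (useCache && is.null(cache)) cache <- new.env(parent = emptyenv())
  grainClass <- function(firedPerAllele) {
    if (all(lengths(firedPerAllele) == 0L)) return("none")
    prof <- integer(0)
    for (ai in seq_len(nAll)) {
      fired <- firedPerAllele[[ai]]
      if (!length(fired)) {
        p <- wtAllele[[ai]]
      } else if (useCache) {
        key <- paste0(ai, ":", paste(fired, collapse = ","))
        if (is.null(cache[[key]])) {
          out <- applyCuts(genotype$alleles[[ai]], fired, policy,
                           catalogue)
          cache[[key]] <- alleleProfile(genotype$alleles[[ai]], out,
                                        genotype$families)
        }
        p <- cache[[key]]
      } else {
        out <- applyCuts(genotype$alleles[[ai]], fired, policy, catalogue)
        p <- alleleProfile(genotype$alleles[[ai]], out,
                           genotype$families)
      }
      prof <- addProfiles(prof, p)
    }
    profileDiff(wt, prof)
  }
  withSeed(seed, {
    plantsClear <- 0L; plantsAny <- 0L
    grainsClear <- 0L; grainsAny <- 0L
    for (p in seq_len(nPlants)) {
      pc <- FALSE; pa <- FALSE
      for (g in seq_len(grainsPerPlant)) {
        fired <- lapply(siteList, function(sites)
          sites[runif(length(sites)) < efficiency])
        cls <- grainClass(fired)
        if (cls == "clear_change") { grainsClear <- grainsClear + 1L
                                     pc <- TRUE }
        if (cls != "none") { grainsAny <- grainsAny + 1L; pa <- TRUE }
      }
      if (pc) plantsClear <- plantsClear + 1L
      if (pa) plantsAny <- plantsAny + 1L
    }
    nGrains <- nPlants * grainsPerPlant
    list(counts = data.frame(plants_tested = nPlants,
                             grains_tested = nGrains,
                             plants_clear = plantsClear,
                             grains_clear = grainsClear,
                             plants_any = plantsAny,
                             grains_any = grainsAny),
         grain_any_fraction = grainsAny / nGrains,
         grain_clear_fraction = grainsClear / nGrains,
         n_cut_sites = nSites)
  })
}

#' Estimate editing efficiency from a changed-grain fraction
#'
#' Method-of-moments inversion for a deterministic knockout policy: with S
#' independent cut sites per grain each firing with probability e and every
#' fired cut altering the profile, the per-grain change probability is
#' 1 - (1-e)^S, so e = 1 - (1 - f)^(1/S).
#'
#' @param fraction observed changed-grain fraction.
#' @param nSites number of independent cut sites per grain.
#' @return the efficiency estimate.
#' @export
estimateEfficiency <- function(fraction, nSites) {
  ifelse(fraction >= 1, 1, 1 - (1 - fraction)^(1 / nSites))
}
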