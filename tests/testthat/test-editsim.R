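test_that("consequence classification follows frame and stop logic", {
  wt <- "ATGGCTGCAGCTTAA"
  expect_equal(classifyConsequence(wt, wt), "unchanged")
  expect_equal(classifyConsequence(wt, "ATGGCTGCGCTTAA"), "frameshift_ko")
  expect_equal(classifyConsequence(wt, "ATGGCAGCTTAA"), "inframe_edit")
  # 9-nt in-frame insertion containing TAA: verified by re-translation
  ins <- paste0("ATGGCT", "GCGTAAGCG", "GCAGCTTAA")
  expect_match(translateCds(ins), "\\*.")  # internal stop present
  expect_equal(classifyConsequence(wt, ins), "nonsense_ko")
})

test_that("zero cuts leave the allele untouched", {
  fam <- alphaDemo(n = 3)
  loc <- generateLocus(fam, c(40, 40), seed = 1)
  out <- applyCuts(loc, integer(0), repairPolicy())
  expect_identical(out$sequence, as.character(locusSequence(loc)))
  expect_true(all(out$genes$consequence == "unchanged"))
  expect_true(all(out$genes$epitope_delta == 0L))
})

test_that("paired cuts flanking the epitope region excise it in frame", {
  fam <- alphaDemo(n = 1)
  loc <- generateLocus(fam, c(0, 0), seed = 1)
  ann <- annotateGenes(fam)
  ep <- ann$domains[ann$domains$domain == "epitope_region", ]
  # between-base cuts at codon boundaries flanking the epitope block
  c1 <- 3L * (ep$start - 1L)
  c2 <- 3L * ep$end
  set.seed(2)
  out <- applyCuts(loc, c(c1, c2), repairPolicy(pSegmentDeletion = 1))
  row <- out$genes[1, ]
  expect_equal(row$consequence, "inframe_edit")
  expect_lt(row$epitope_delta, 0L)
  # re-annotation oracle: edited gene translates without premature stop
  edited <- substr(out$sequence, row$new_start, row$new_end)
  expect_false(as.logical(callPseudogene(translateCds(edited))))
  expect_equal(nchar(out$sequence),
               nchar(as.character(locusSequence(loc))) - (c2 - c1))
})

test_that("cuts in genes 1 and 4 of a 5-gene array delete genes 2 and 3", {
  fam <- gammaDemo(n = 6)[1:5]
  loc <- generateLocus(fam, c(50, 50), seed = 2)
  cuts <- predictCutSites("TTGTTGTGGCCATTGTACT",
                          locusSequence(loc))$cut  # one site per gene
  expect_length(cuts, 5L)
  set.seed(3)
  out <- applyCuts(loc, cuts[c(1, 4)], repairPolicy(pSegmentDeletion = 1))
  cons <- setNames(out$genes$consequence, out$genes$gene_id)
  expect_equal(unname(cons[geneIds(fam)[c(2, 3)]]),
               c("deleted", "deleted"))
  expect_equal(unname(cons[geneIds(fam)[c(1, 4)]]),
               c("fusion", "fusion"))
  expect_equal(unname(cons[geneIds(fam)[5]]), "unchanged")
})

test_that("sequence length is conserved up to the applied indels", {
  fam <- alphaDemo(n = 2)
  loc <- generateLocus(fam, c(30, 30), seed = 4)
  L <- nchar(as.character(locusSequence(loc)))
  cut <- predictCutSites("ATGGTTGTTGTGATGGAAA",
                         locusSequence(loc))$cut[1]
  delOnly <- repairPolicy(pSegmentDeletion = 0, pPerfectRepair = 0,
                          pDeletion = 1, delSizes = 5L)
  set.seed(5)
  expect_equal(nchar(applyCuts(loc, cut, delOnly)$sequence), L - 5L)
  insOnly <- repairPolicy(pSegmentDeletion = 0, pPerfectRepair = 0,
                          pDeletion = 0, insSizes = 2L)
  set.seed(5)
  expect_equal(nchar(applyCuts(loc, cut, insOnly)$sequence), L + 2L)
  perfect <- repairPolicy(pSegmentDeletion = 0, pPerfectRepair = 1)
  expect_equal(applyCuts(loc, cut, perfect)$sequence,
               as.character(locusSequence(loc)))
})

test_that("consequence calls agree with re-annotating the edited allele", {
  fam <- gammaDemo(n = 4)
  loc <- generateLocus(fam, c(60, 120), seed = 6)
  guide <- "AATGGTTGTTGTGGTTGCTG"
  cuts <- predictCutSites(guide, locusSequence(loc))$cut
  for (s in 1:5) {
    set.seed(s)
    out <- applyCuts(loc, cuts, repairPolicy())
    for (i in seq_len(nrow(out$genes))) {
      row <- out$genes[i, ]
      if (row$consequence %in% c("deleted", "fusion")) next
      before <- substr(as.character(locusSequence(loc)),
                       IRanges::start(geneRanges(loc))[i],
                       IRanges::end(geneRanges(loc))[i])
      after <- substr(out$sequence, row$new_start, row$new_end)
      lenDiff <- nchar(after) - nchar(before)
      if (row$consequence == "unchanged") {
        expect_identical(after, before)
      } else if (row$consequence == "frameshift_ko") {
        expect_true(lenDiff %% 3L != 0L)
      } else {
        expect_true(lenDiff %% 3L == 0L)
        pa <- suppressWarnings(translateCds(after))
        isPseudo <- as.logical(callPseudogene(pa))
        expect_equal(row$consequence,
                     if (isPseudo) "nonsense_ko" else "inframe_edit")
      }
    }
  }
})

test_that("profiles bin intact proteins by mass and diff against wild type", {
  fam <- alphaDemo(n = 2)  # two subgroups, different template lengths
  gt <- list(alleles = list(generateLocus(fam[1], c(0, 0), seed = 1)),
             families = setNames("alpha", geneIds(fam)[1]))
  class(gt) <- "WheatGenotype"
  wt <- predictProfile(gt)
  prot <- annotateGenes(fam[1])$proteins[[1]]
  residues <- nchar(prot) - 1L  # trailing stop
  expect_equal(names(wt), sprintf("alpha:%d", round(110 * residues / 500)))
  expect_equal(unname(wt), 1L)
  expect_equal(profileDiff(wt, wt), "none")
  # knocking out the only occupant of a bin is a clear change
  expect_equal(profileDiff(wt, integer(0)), "clear_change")
  # count change without bin loss is a potential change
  expect_equal(profileDiff(c(`alpha:9` = 2L), c(`alpha:9` = 1L)),
               "potential_change")
  # in-frame shortening by 30 residues shifts the bin by the arithmetic
  shifted <- setNames(1L, sprintf("alpha:%d",
                                  round(110 * (residues - 30) / 500)))
  expect_equal(profileDiff(wt, shifted), "clear_change")
})

test_that("screen simulation is reproducible and exact at the extremes", {
  spec <- defaultAlphaSpec(nCopies = 10, pseudogeneFraction = 0, seed = 11)
  gt <- makeHexaploidGenotype(list(spec), genesPerLocus = 2, seed = 4)
  ko <- repairPolicy(pSegmentDeletion = 0, pPerfectRepair = 0,
                     pDeletion = 1, delSizes = 1L)
  a213 <- "ATGGTTGTTGTGATGGAAA"

  s0 <- simulateScreen(gt, a213, efficiency = 0, nPlants = 4,
                       grainsPerPlant = 8, policy = ko, seed = 9)
  expect_equal(unlist(s0$counts[, 3:6]), c(plants_clear = 0L,
               grains_clear = 0L, plants_any = 0L, grains_any = 0L))

  seg <- repairPolicy(pSegmentDeletion = 1, pPerfectRepair = 0,
                      pDeletion = 1, delSizes = 1L)
  s1 <- simulateScreen(gt, a213, efficiency = 1, nPlants = 4,
                       grainsPerPlant = 8, policy = seg, seed = 9)
  expect_equal(s1$counts$grains_clear, 32L)
  expect_equal(s1$counts$plants_clear, 4L)

  sa <- simulateScreen(gt, a213, efficiency = 0.2, nPlants = 6,
                       grainsPerPlant = 8, policy = ko, seed = 10)
  sb <- simulateScreen(gt, a213, efficiency = 0.2, nPlants = 6,
                       grainsPerPlant = 8, policy = ko, seed = 10)
  expect_identical(sa$counts, sb$counts)
})
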