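test_that("pseudogene fraction limits are exact at 0 and 1", {
  fam0 <- generateFamily(defaultAlphaSpec(nCopies = 10,
                                          pseudogeneFraction = 0,
                                          seed = 1))
  expect_length(fam0, 10L)
  ann0 <- annotateGenes(fam0)
  expect_false(any(ann0$pseudogene))

  fam1 <- generateFamily(defaultAlphaSpec(nCopies = 10,
                                          pseudogeneFraction = 1,
                                          seed = 1))
  ann1 <- annotateGenes(fam1)
  expect_true(all(ann1$pseudogene))
})

test_that("alpha default pseudogene count falls in the binomial 99% band", {
  fam <- generateFamily(defaultAlphaSpec(nCopies = 100,
                                         pseudogeneFraction = 0.9,
                                         seed = 7))
  n <- sum(geneInfo(fam)$planted_pseudogene)
  band <- qbinom(c(0.005, 0.995), 100, 0.9)
  expect_gte(n, band[1])
  expect_lte(n, band[2])
})

test_that("pseudogene fraction estimator is unbiased over seeds", {
  fracs <- vapply(1:50, function(s) {
    fam <- generateFamily(defaultGammaSpec(nCopies = 40,
                                           pseudogeneFraction = 0.5,
                                           seed = s))
    mean(geneInfo(fam)$planted_pseudogene)
  }, 0)
  se <- sqrt(0.5 * 0.5 / (50 * 40))
  expect_lt(abs(mean(fracs) - 0.5), 2 * se)
})

test_that("a fixed seed reproduces the family byte for byte", {
  a <- generateFamily(defaultAlphaSpec(nCopies = 12, seed = 99))
  b <- generateFamily(defaultAlphaSpec(nCopies = 12, seed = 99))
  expect_identical(as.character(geneSequences(a)),
                   as.character(geneSequences(b)))
  expect_identical(as.data.frame(geneInfo(a)), as.data.frame(geneInfo(b)))
  c <- generateFamily(defaultAlphaSpec(nCopies = 12, seed = 100))
  expect_false(identical(as.character(geneSequences(a)),
                         as.character(geneSequences(c))))
})

test_that("family members are protein-faithful but DNA-diverse paralogs", {
  fam <- alphaDemo(n = 10)
  ann <- annotateGenes(fam)
  sub <- geneInfo(fam)$subgroup
  for (sg in unique(sub)) {
    prots <- unname(ann$proteins[sub == sg])
    dnas <- as.character(geneSequences(fam))[sub == sg]
    expect_length(unique(prots), 1L)
    expect_gt(length(unique(dnas)), 1L)
  }
})

test_that("invalid family specs fail with the offending field named", {
  sg <- defaultAlphaSpec()$subgroups
  expect_error(familySpec("beta", 10, 0.5, sg), "family")
  expect_error(familySpec("alpha", -1, 0.5, sg), "nCopies")
  expect_error(familySpec("alpha", 10, 1.5, sg), "pseudogeneFraction")
  expect_error(familySpec("alpha", 3, 0.5, sg), "nCopies")
})

test_that("locus assembly arithmetic and determinism hold", {
  g300 <- vapply(1:3, function(i) randomDna(300), "")
  genes <- GliadinGeneSet(g300, data.frame(gene_id = paste0("g", 1:3)))
  loc <- generateLocus(genes, c(100, 100), seed = 5)
  expect_equal(length(locusSequence(loc)), 3 * 300 + 2 * 100)
  expect_equal(IRanges::start(geneRanges(loc)), c(1L, 401L, 801L))

  one <- generateLocus(genes[1], c(0, 0), seed = 5)
  expect_equal(length(locusSequence(one)), 300L)

  la <- generateLocus(genes, c(50, 500), seed = 9)
  lb <- generateLocus(genes, c(50, 500), seed = 9)
  expect_identical(as.character(locusSequence(la)),
                   as.character(locusSequence(lb)))
  expect_identical(geneRanges(la), geneRanges(lb))
  expect_error(generateLocus(genes[0]), "at least one gene")
})

test_that("locus manifest is 0-based half-open and round-trips the genes", {
  fam <- alphaDemo(n = 4)
  loc <- generateLocus(fam, c(10, 10), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLocusManifest(loc, path)
  man <- read.delim(path)
  s <- as.character(locusSequence(loc))
  for (i in seq_len(nrow(man))) {
    extracted <- substr(s, man$start[i] + 1L, man$end[i])
    expect_identical(extracted,
                     as.character(geneSequences(fam))[[man$gene_id[i]]])
  }
})

test_that("FASTA round trip preserves sequences and metadata", {
  fam <- generateFamily(defaultGammaSpec(nCopies = 8, seed = 21))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeGeneFasta(fam, path)
  back <- readGeneFasta(path)
  expect_identical(as.character(geneSequences(back)),
                   as.character(geneSequences(fam)))
  expect_identical(geneInfo(back)$subgroup, geneInfo(fam)$subgroup)
  expect_identical(geneInfo(back)$planted_pseudogene,
                   geneInfo(fam)$planted_pseudogene)
})

test_that("embedGuideTargets plants a findable motif the requested number of times", {
  fam <- generateFamily(defaultOmegaSpec(nCopies = 5,
                                         pseudogeneFraction = 0,
                                         seed = 8))
  motif <- "ATGGTTGTTGTGATGGAAA"
  expect_equal(nrow(matchGuide(motif, fam)), 0L)
  emb <- embedGuideTargets(fam, motif, region = "epitope_upstream")
  m <- matchGuide(motif, emb)
  expect_setequal(unique(m$gene_id), geneIds(fam))
  expect_equal(nrow(m), 5L)
  expect_true(all(m$strand == "-"))

  # k embedded copies give exactly k cut sites (exhaustive-scan oracle)
  for (k in c(2L, 4L)) {
    ek <- embedGuideTargets(fam[1], motif, region = "epitope_upstream",
                            times = k)
    cuts <- predictCutSites(motif, ek)
    expect_equal(nrow(cuts), k)
    ora <- oracleMatchGuide(motif,
                            as.character(geneSequences(ek))[[1L]])
    expect_equal(sort(cuts$cut), sort(ora$cut))
  }

  # embedding preserves the reading frame: no new premature stop
  ann <- annotateGenes(emb)
  expect_false(any(ann$pseudogene))
})
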