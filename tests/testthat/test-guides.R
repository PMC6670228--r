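test_that("sense, antisense and degenerate matches are found with PAM logic", {
  g <- "ATGGTTGTTGTGATGGAAA"
  sense <- paste0("AAAA", g, "TGGAAAA")
  m <- matchGuide(g, sense)
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "+")
  expect_equal(m$pam, "TGG")
  # no PAM, no match
  expect_equal(nrow(matchGuide(g, paste0("AAAA", g, "TCAAAAA"))), 0L)

  # the published guides target the antisense strand: their reverse
  # complement appears in database (coding) sequences
  a87 <- "GATTTTGTGGCTGCAATTG"
  expect_identical(revComp(a87), "CAATTGCAGCCACAAAATC")
  coding <- paste0("AAACCA", revComp(a87), "GGAAA")  # CCA = revcomp of TGG
  m2 <- matchGuide(a87, coding)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$strand, "-")
  expect_equal(m2$pam, "TGG")

  # degenerate primer matches its concrete realisation with 0 mismatches
  p <- "ATGAARACMTTTCYCATC"
  mp <- matchGuide(p, paste0("GG", "ATGAAAACATTTCTCATC", "AGGA"),
                   requirePam = FALSE)
  expect_equal(mp$mismatches[mp$strand == "+"], 0L)
})

test_that("cut sites sit 3 bp 5' of the PAM (between-base convention)", {
  g <- paste(rep("ACGTG", 4), collapse = "")  # 20-nt protospacer
  # protospacer at 0-based [100,120), PAM [120,123)
  s <- paste0(randomDnaNoMatch(100, g), g, "AGG", randomDnaNoMatch(30, g))
  m <- matchGuide(g, s)
  plus <- m[m$strand == "+" & m$start == 101L, ]
  expect_equal(plus$cut, 117L)
})

test_that("guide matching equals the brute-force oracle on random cases", {
  set.seed(303)
  for (i in 1:250) {
    guide <- if (i %% 4 == 0) randomIupac(sample(8:20, 1))
             else randomDna(sample(8:20, 1))
    subject <- randomDna(sample(40:80, 1))
    mm <- sample(0:2, 1)
    pam <- sample(c(TRUE, FALSE), 1)
    mine <- matchGuide(guide, subject, maxMismatch = mm, requirePam = pam)
    ora <- oracleMatchGuide(guide, subject, maxMismatch = mm,
                            requirePam = pam)
    mine <- mine[order(mine$start, mine$strand), ]
    expect_equal(nrow(mine), nrow(ora))
    expect_equal(mine$start, ora$start)
    expect_equal(mine$strand, ora$strand)
    expect_equal(mine$mismatches, ora$mismatches)
    expect_equal(mine$cut, ora$cut)
  }
})

test_that("strand symmetry: g vs s equals revcomp(g) vs revcomp(s) swapped", {
  set.seed(404)
  for (i in 1:50) {
    g <- randomDna(12)
    s <- randomDna(60)
    a <- matchGuide(g, s, maxMismatch = 1)
    b <- matchGuide(revComp(g), revComp(s), maxMismatch = 1)
    L <- nchar(s)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      bsw <- data.frame(start = L - b$end + 1L, end = L - b$start + 1L,
                        strand = ifelse(b$strand == "+", "-", "+"),
                        mismatches = b$mismatches)
      ord <- function(d) d[order(d$start, d$strand), ]
      expect_equal(ord(a[, colnames(bsw)]), ord(bsw),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the shipped guide and primer tables validate", {
  g <- gliadinGuides()
  expect_equal(nrow(g), 6L)
  expect_true(all(nchar(g$protospacer) %in% c(19L, 20L)))
  expect_false(any(grepl("[^ACGT]", g$protospacer)))
  expect_true(all(g$targets_antisense))
  p <- degeneratePrimers()
  expect_equal(nrow(p), 2L)
  expect_false(any(grepl("[^ACGTRYMKSWBDHVN]", p$sequence)))
})

test_that("coverage matrix counts member genes and respects subgroup sizes", {
  fam <- alphaDemo(n = 15)
  cl <- classifyFamily(fam)
  guides <- gliadinGuides()
  cov <- coverageMatrix(guides[guides$family == "alpha", ], fam,
                        cl$membership)
  expect_true(all(cov$counts <= rep(cov$subgroupSizes,
                                    each = nrow(cov$counts))))
  expect_true(cov$coversAllSubgroups[["sgRNA_a213"]])
  # a guide matching nothing yields an all-zero row
  none <- coverageMatrix(data.frame(name = "none",
                                    protospacer = strrep("ACGTG", 4)),
                         fam, cl$membership)
  expect_true(all(none$counts == 0L))
  # monotone: a subgroup gaining a matching gene never loses coverage
  part <- cl$membership[-1, ]
  covPart <- coverageMatrix(guides[guides$family == "alpha", ], fam, part)
  full <- cov$counts[, colnames(covPart$counts), drop = FALSE]
  expect_true(all(full >= covPart$counts))
})

test_that("off-target scan annotates mismatches and the 12-nt seed", {
  g <- randomDna(20)
  sub1 <- g
  substr(sub1, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                substr(g, 3, 3))[1]
  bg <- c(hit = paste0("AAAA", sub1, "CGG", "AAAA"))
  res <- offTargetScan(g, bg, maxMismatch = 3)
  expect_equal(nrow(res), 1L)
  expect_equal(res$mismatches, 1L)
  expect_true(res$seed12_clean)  # position 3 of 20 is PAM-distal

  sub2 <- g
  substr(sub2, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                  substr(g, 15, 15))[1]
  res2 <- offTargetScan(g, c(hit = paste0("AAAA", sub2, "CGG")),
                        maxMismatch = 3)
  expect_false(res2$seed12_clean)

  # consistency: scanning the targets equals matchGuide
  fam <- alphaDemo(n = 6)
  a213 <- "ATGGTTGTTGTGATGGAAA"
  expect_equal(offTargetScan(a213, fam, 0)[, 1:7],
               matchGuide(a213, fam))
  expect_equal(nrow(offTargetScan(a213,
                                  c(x = randomDnaNoMatch(200, a213)), 0)),
               0L)
})

test_that("conserved-window discovery counts distinct genes", {
  same <- GliadinGeneSet(rep(randomDna(60), 4),
                         data.frame(gene_id = paste0("g", 1:4)))
  top <- findConservedWindows(same, k = 20, minFraction = 0.5)
  expect_equal(max(top$fraction), 1.0)

  set.seed(77)
  win <- randomDna(23)
  seqs <- vapply(1:10, function(i) {
    s <- randomDna(80)
    if (i <= 6) paste0(substr(s, 1, 30), win, substr(s, 31, 80)) else s
  }, "")
  genes <- GliadinGeneSet(seqs, data.frame(gene_id = paste0("g", 1:10)))
  res <- findConservedWindows(genes, k = 23, minFraction = 0.5)
  expect_equal(res$fraction[res$window == win], 0.6)

  diverse <- GliadinGeneSet(vapply(1:5, function(i) randomDna(50), ""),
                            data.frame(gene_id = paste0("g", 1:5)))
  expect_s3_class(findConservedWindows(diverse, k = 20, minFraction = 1),
                  "data.frame")
  expect_error(findConservedWindows(diverse, k = 60), "shortest gene")
})

test_that("hairpin heuristic equals the exhaustive substring-pair oracle", {
  expect_equal(hairpinFlag(strrep("A", 19))$stem, 0L)
  hp <- hairpinFlag("GGGGCCAAAGGCCCC", minStem = 4, minLoop = 3)
  expect_gte(hp$stem, 4L)
  expect_true(hp$flagged)
  set.seed(505)
  for (i in 1:100) {
    s <- randomDna(sample(10:24, 1))
    loop <- sample(3:5, 1)
    mine <- hairpinFlag(s, minStem = 6, minLoop = loop)
    expect_equal(mine$stem, oracleHairpin(s, loop))
    # monotone: lowering the stem threshold can only keep or add flags
    expect_true(hairpinFlag(s, minStem = 3, minLoop = loop)$flagged >=
                mine$flagged)
  }
})

test_that("cross-dimer run equals the alignment-offset oracle, symmetrically", {
  a <- randomDna(19)
  expect_equal(crossDimerFlag(a, revComp(a))$run, 19L)
  expect_equal(crossDimerFlag("AAAAA", "CCCCC")$run, 0L)
  set.seed(606)
  for (i in 1:100) {
    x <- randomDna(sample(8:22, 1)); y <- randomDna(sample(8:22, 1))
    mine <- crossDimerFlag(x, y)
    expect_equal(mine$run, oracleCrossDimer(x, y))
    expect_equal(mine$run, crossDimerFlag(y, x)$run)
  }
})
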