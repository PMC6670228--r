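test_that("signatures count epitopes in the repetitive region, catalogue order", {
  fam <- gammaDemo(n = 6)  # one gene per subgroup
  ann <- annotateGenes(fam)
  sig <- buildSignatures(ann)
  expect_equal(nrow(sig), 6L)
  # the six-copy-g4c subgroup member: g4c listed before g1/g2 additions
  d1 <- sig$signature[sig$gene_id == "gamma_D1_001"]
  expect_match(d1, "DQ2.5-glia-g1:1")
  expect_match(d1, "DQ2.5-glia-g2:1")
  expect_match(d1, "DQ2.5-glia-g4c:6")
  # catalogue order: g1 < g2 < g4c
  expect_true(regexpr("g1:", d1) < regexpr("g2:", d1))
  expect_true(regexpr("g2:", d1) < regexpr("g4c:", d1))

  # identical templates give identical signatures
  fam2 <- gammaDemo(n = 12)
  sig2 <- buildSignatures(annotateGenes(fam2))
  sub <- setNames(geneInfo(fam2)$subgroup, geneIds(fam2))
  for (sg in unique(sub))
    expect_length(unique(sig2$signature[sub[sig2$gene_id] == sg]), 1L)
})

test_that("grouping is a stable partition and is idempotent", {
  fam <- alphaDemo(n = 17)
  sig <- buildSignatures(annotateGenes(fam))
  gr <- groupBySignature(sig)
  # partition: every gene exactly once, union equals input
  expect_setequal(gr$membership$gene_id, sig$gene_id)
  expect_equal(anyDuplicated(gr$membership$gene_id), 0L)
  expect_equal(sum(gr$subgroups$n_members), nrow(sig))
  # ordering: descending membership, ties by signature
  expect_true(!is.unsorted(rev(gr$subgroups$n_members)))
  # idempotence: regrouping the induced signatures changes nothing
  sig2 <- data.frame(gene_id = gr$membership$gene_id,
                     signature = gr$subgroups$signature[
                       match(gr$membership$label, gr$subgroups$label)])
  gr2 <- groupBySignature(sig2)
  expect_identical(gr2$subgroups$signature, gr$subgroups$signature)
  expect_identical(gr2$membership$label, gr$membership$label)

  one <- groupBySignature(data.frame(gene_id = c("a", "b"),
                                     signature = c("x", "x")))
  expect_equal(nrow(one$subgroups), 1L)
})

test_that("alpha and gamma demo families recover 5 and 6 subgroups", {
  expect_equal(nrow(classifyFamily(alphaDemo(n = 20))$subgroups), 5L)
  expect_equal(nrow(classifyFamily(gammaDemo(n = 18))$subgroups), 6L)
})

test_that("genome assignment follows the majority threshold rule", {
  gr <- list(subgroups = data.frame(label = "S1", signature = "x",
                                    n_members = 3L),
             membership = data.frame(gene_id = c("a", "b", "c"),
                                     label = "S1"))
  res <- assignGenome(gr, c(a = "A", b = "A", c = "A"), threshold = 0.6)
  expect_equal(res$genome, "A")
  expect_equal(res$support, 1.0)

  gr2 <- list(subgroups = data.frame(label = "S1", signature = "x",
                                     n_members = 2L),
              membership = data.frame(gene_id = c("a", "b"), label = "S1"))
  res2 <- assignGenome(gr2, c(a = "A", b = "B"), threshold = 0.6)
  expect_equal(res2$genome, "ambiguous")
  expect_equal(res2$support, 0.5)

  res3 <- assignGenome(gr2, c(a = "unknown", b = "unknown"))
  expect_equal(res3$genome, "ambiguous")
  expect_equal(res3$support, 0)

  expect_error(assignGenome(gr2, c(a = "A", b = "B"), threshold = 0.5),
               "threshold")
})

test_that("planted subgroup structure and genomes are recovered exactly", {
  for (mk in list(function() alphaDemo(n = 20, seed = 5),
                  function() gammaDemo(n = 18, seed = 5))) {
    fam <- mk()
    cl <- classifyFamily(fam)
    truth <- S4Vectors::metadata(geneInfo(fam))$subgroups
    expect_equal(nrow(cl$subgroups), length(truth))
    # membership partition equals the planted partition
    blocks <- function(x) sort(vapply(x, function(v)
      paste(sort(v), collapse = ","), ""))
    planted <- split(geneIds(fam), geneInfo(fam)$subgroup)
    inferred <- split(cl$membership$gene_id, cl$membership$label)
    expect_identical(unname(blocks(planted)), unname(blocks(inferred)))
    # genome assignment is 100% correct with diploid labels present
    plantedGenome <- vapply(truth, `[[`, "", "genome")
    byLabel <- setNames(geneInfo(fam)$subgroup, geneIds(fam))
    for (i in seq_len(nrow(cl$subgroups))) {
      members <- cl$membership$gene_id[cl$membership$label ==
                                       cl$subgroups$label[i]]
      expect_equal(cl$subgroups$genome[i],
                   unname(plantedGenome[byLabel[members[1]]]))
    }
  }
})
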