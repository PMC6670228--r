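#' @include annotation.R
NULL

#' Build per-gene epitope signatures
#'
#' A gene's signature is its combination of coeliac-disease epitopes: the
#' exact occurrence count of every catalogue epitope within the gene's
#' repetitive/epitope region, serialised as \code{"name:count;..."} in
#' catalogue order (empty string when the gene has no epitope hits there).
#' Pseudogenes are excluded by default, mirroring a design focus on
#' full-length genes.
#'
#' @param ann annotation as returned by \code{\link{annotateGenes}}.
#' @param catalogue the epitope catalogue used for the scan (fixes the
#'   ordering of signature terms).
#' @param includePseudogenes keep pseudogenes (signature computed up to
#'   their premature stop via the domain map).
#' @return \code{data.frame(gene_id, signature)}.
#' @export
buildSignatures <- function(ann, catalogue = cdEpitopes(),
                            includePseudogenes = FALSE) {
  ids <- names(ann$proteins)
  if (!includePseudogenes) ids <- ids[!ann$pseudogene[ids]]
  sig <- vapply(ids, function(id) {
    dom <- ann$domains[ann$domains$gene_id == id &
                       ann$domains$domain == "epitope_region", , drop = FALSE]
    if (nrow(dom) == 0L) return("")
    h <- ann$hits[ann$hits$gene_id == id &
                  ann$hits$position >= dom$start &
                  ann$hits$position + 8L <= dom$end + 0L, , drop = FALSE]
    if (nrow(h) == 0L) return("")
    counts <- table(factor(h$epitope_name, levels = catalogue$name))
    counts <- counts[counts > 0L]
    paste(sprintf("%s:%d", names(counts), as.integer(counts)),
          collapse = ";")
  }, "")
  data.frame(gene_id = ids, signature = unname(sig))
}

#' Partition genes into subgroups by identical epitope signature
#'
#' @param signatures \code{data.frame(gene_id, signature)} from
#'   \code{\link{buildSignatures}}.
#' @return list with \code{subgroups}
#'   (\code{data.frame(label, signature, n_members)}, ordered by descending
#'   membership, ties by signature) and \code{membership}
#'   (\code{data.frame(gene_id, label)}).
#' @export
groupBySignature <- function(signatures) {
  if (nrow(signatures) == 0L) stop("at least one signature is required")
  tab <- table(signatures$signature)
  ord <- order(-as.integer(tab), names(tab))
  sigs <- names(tab)[ord]
  labels <- sprintf("SG%02d", seq_along(sigs))
  subgroups <- data.frame(label = labels, signature = sigs,
                          n_members = as.integer(tab)[ord])
  membership <- data.frame(
    gene_id = signatures$gene_id,
    label = labels[match(signatures$signature, sigs)])
  list(subgroups = subgroups, membership = membership)
}

#' Assign a subgenome to each subgroup
#'
#' Genome-of-origin inference by majority vote over the subgroup members
#' whose genome is known (diploid-relative accessions): the majority genome
#' is assigned if its share among labelled members reaches
#' \code{threshold}, otherwise the subgroup is \code{ambiguous}; subgroups
#' with no labelled member are \code{ambiguous} with support 0.
#'
#' @param grouping output of \code{\link{groupBySignature}}.
#' @param genomeLabels named character (gene_id -> A/B/D/"unknown").
#' @param threshold majority share required, in (0.5, 1].
#' @return the \code{subgroups} data.frame with added \code{genome} and
#'   \code{support} columns.
#' @export
assignGenome <- function(grouping, genomeLabels, threshold = 0.6) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  sub <- grouping$subgroups
  res <- t(vapply(sub$label, function(lab) {
    ids <- grouping$membership$gene_id[grouping$membership$label == lab]
    g <- genomeLabels[ids]
    g <- g[!is.na(g) & g %in% c("A", "B", "D")]
    if (!length(g)) return(c(genome = "ambiguous", support = "0"))
    tab <- sort(table(g), decreasing = TRUE)
    share <- tab[1L] / sum(tab)
    c(genome = if (share >= threshold) names(tab)[1L] else "ambiguous",
      support = as.character(share))
  }, c(genome = "", support = "")))
  sub$genome <- unname(res[, "genome"])
  sub$support <- as.numeric(res[, "support"])
  sub
}

#' Classify a gliadin family into epitope-signature subgroups
#'
#' Convenience wrapper: annotation, signatures, grouping and genome
#' assignment in one call.
#'
#' @param genes a \code{GliadinGeneSet}.
#' @param catalogue epitope catalogue.
#' @param includePseudogenes include pseudogenes in the grouping.
#' @param threshold majority threshold for \code{\link{assignGenome}}.
#' @param ann optional precomputed \code{\link{annotateGenes}} result.
#' @return list with \code{subgroups} (label, signature, n_members, genome,
#'   support) and \code{membership} (gene_id, label).
#' @examples
#' fam <- generateFamily(defaultAlphaSpec(nCopies = 15,
#'                                        pseudogeneFraction = 0, seed = 2))
#' cl <- classifyFamily(fam)
#' nrow(cl$subgroups)  # 5 alpha subgroups
#' @export
classifyFamily <- function(genes, catalogue = cdEpitopes(),
                           includePseudogenes = FALSE, threshold = 0.6,
                           ann = NULL) {
  if (is.null(ann)) ann <- annotateGenes(genes, catalogue)
  sig <- buildSignatures(ann, catalogue, includePseudogenes)
  grouping <- groupBySignature(sig)
  labels <- setNames(genomeLabel(genes), geneIds(genes))
  subgroups <- assignGenome(grouping, labels, threshold)
  list(subgroups = subgroups, membership = grouping$membership)
}
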