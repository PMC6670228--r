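#' @include synthetic.R
NULL

# The six published protospacers, used by the default synthetic specs to
# plant target sites per the reported family-wide coverage pattern. The
# shipped guide table (gliadinGuides()) is the authoritative copy.
GUIDE_SEQ <- c(
  sgRNA_a87  = "GATTTTGTGGCTGCAATTG",
  sgRNA_a213 = "ATGGTTGTTGTGATGGAAA",
  sgRNA_a324 = "GTTGTGGTCGAAATGGTTG",
  sgRNA_g86  = "TTGTTGTGGCCATTGTACT",
  sgRNA_g272 = "AATGGTTGTTGTGGTTGCTG",
  sgRNA_g603 = "TGCTGGGGGAATGATTGTTG")

epiDf <- function(...) {
  x <- c(...)
  data.frame(name = names(x), copies = as.integer(x))
}

siteDf <- function(guides, regions, times = 1L) {
  data.frame(protospacer = unname(GUIDE_SEQ[guides]), region = regions,
             times = as.integer(times), antisense = TRUE)
}

#' Default synthetic family specifications
#'
#' Study-condition defaults for the three gliadin families of hexaploid
#' wheat. The alpha family has 100 copies, 90\% pseudogenes and five
#' epitope-signature subgroups (two genome A, two genome B, one genome D);
#' the gamma family has 40 copies and six subgroups (two A, one B, three
#' B/D) whose DQ2.5-glia-g4c copy number rises from 1 to 6, so the guide
#' targeting that epitope motif can cut 1-6 times per gene; the omega
#' family has 16 copies in one subgroup per genome. Pseudogene fractions
#' for gamma and omega (0.5) are package assumptions (see the vignette).
#' Guide target cassettes are embedded per the reported coverage pattern:
#' sgRNA_a213 in all five alpha subgroups, sgRNA_a324 withheld from both
#' B-genome alpha subgroups, sgRNA_a87 only in one B subgroup, sgRNA_g86
#' withheld from one D subgroup, sgRNA_g603 withheld from one A subgroup,
#' sgRNA_g272 in every gamma gene once per g4c epitope copy.
#'
#' @param nCopies total gene copies.
#' @param pseudogeneFraction per-copy pseudogenisation probability.
#' @param seed RNG seed.
#' @return a \code{\link{familySpec}}.
#' @examples
#' spec <- defaultAlphaSpec(nCopies = 20, pseudogeneFraction = 0, seed = 1)
#' length(spec$subgroups)
#' @export
defaultAlphaSpec <- function(nCopies = 100L, pseudogeneFraction = 0.9,
                             seed = 1L) {
  sg <- list(
    subgroupDef("A1", "A", epiDf("DQ2.5-glia-a1a" = 2, "DQ2.5-glia-a2" = 1),
      siteDf(c("sgRNA_a213", "sgRNA_a324"),
             c("epitope_upstream", "epitope_downstream"))),
    subgroupDef("A2", "A", epiDf("DQ2.5-glia-a1a" = 1, "DQ2.5-glia-a1b" = 1),
      siteDf(c("sgRNA_a213", "sgRNA_a324"),
             c("epitope_upstream", "epitope_downstream"))),
    subgroupDef("B1", "B", epiDf("DQ2.5-glia-a3" = 1),
      siteDf(c("sgRNA_a87", "sgRNA_a213"),
             c("post_signal_peptide", "epitope_upstream"))),
    subgroupDef("B2", "B", epiDf("DQ2.5-glia-a1b" = 1),
      siteDf("sgRNA_a213", "epitope_upstream")),
    subgroupDef("D5", "D",
      epiDf("DQ2.5-glia-a1a" = 1, "DQ2.5-glia-a2" = 1, "DQ2.5-glia-a3" = 1),
      siteDf(c("sgRNA_a213", "sgRNA_a324"),
             c("epitope_upstream", "epitope_downstream"))))
  familySpec("alpha", nCopies, pseudogeneFraction, sg, seed = seed)
}

#' @rdname defaultAlphaSpec
#' @export
defaultGammaSpec <- function(nCopies = 40L, pseudogeneFraction = 0.5,
                             seed = 1L) {
  g272 <- function(k, extra, extraRegion) {
    df <- siteDf("sgRNA_g272", "epitope_internal", times = k)
    if (!missing(extra)) df <- rbind(df, siteDf(extra, extraRegion))
    df
  }
  sg <- list(
    subgroupDef("A1", "A", epiDf("DQ2.5-glia-g4c" = 1, "DQ2.5-glia-g1" = 1),
      g272(1L, "sgRNA_g86", "post_signal_peptide")),
    subgroupDef("A2", "A", epiDf("DQ2.5-glia-g4c" = 2, "DQ2.5-glia-g2" = 1),
      g272(2L, c("sgRNA_g86", "sgRNA_g603"),
           c("post_signal_peptide", "epitope_downstream"))),
    subgroupDef("B1", "B", epiDf("DQ2.5-glia-g4c" = 3, "DQ2.5-glia-g3" = 1),
      g272(3L, c("sgRNA_g86", "sgRNA_g603"),
           c("post_signal_peptide", "epitope_downstream"))),
    subgroupDef("BD1", "B",
      epiDf("DQ2.5-glia-g4c" = 4, "DQ2.5-glia-g1" = 1, "DQ2.5-glia-g3" = 1),
      g272(4L, c("sgRNA_g86", "sgRNA_g603"),
           c("post_signal_peptide", "epitope_downstream"))),
    subgroupDef("BD2", "D", epiDf("DQ2.5-glia-g4c" = 5, "DQ2.5-glia-g2" = 1),
      g272(5L, c("sgRNA_g86", "sgRNA_g603"),
           c("post_signal_peptide", "epitope_downstream"))),
    subgroupDef("D1", "D",
      epiDf("DQ2.5-glia-g4c" = 6, "DQ2.5-glia-g1" = 1, "DQ2.5-glia-g2" = 1),
      g272(6L, "sgRNA_g603", "epitope_downstream")))
  familySpec("gamma", nCopies, pseudogeneFraction, sg, seed = seed)
}

#' @rdname defaultAlphaSpec
#' @export
defaultOmegaSpec <- function(nCopies = 16L, pseudogeneFraction = 0.5,
                             seed = 1L) {
  sg <- list(
    subgroupDef("A1", "A", epiDf("DQ2.5-glia-w1" = 2)),
    subgroupDef("B1", "B", epiDf("DQ2.5-glia-w1" = 1, "DQ2.5-glia-w2" = 1)),
    subgroupDef("D1", "D", epiDf("DQ2.5-glia-w2" = 2)))
  familySpec("omega", nCopies, pseudogeneFraction, sg, seed = seed)
}

#' Published guide and primer tables and screening counts
#'
#' \code{gliadinGuides()} returns the six published sgRNA protospacers
#' (name, protospacer, family, region_class, anchor_column,
#' targets_antisense; the guide named sgRNA_g272 carries the anchor column
#' 274 its source states, preserved verbatim). \code{degeneratePrimers()}
#' returns the two degenerate alpha-gliadin cloning primers (IUPAC codes).
#' \code{fielderScreen()} returns the per-construct T0/T1 screening counts
#' (regeneration, Cas9 expression, transgene copy number, Acid-PAGE clear /
#' any changes). \code{paragonScreen()} returns the gamma-irradiated
#' population counts (lines screened and lines with altered profiles).
#'
#' @return a \code{data.frame} (or a named list for
#'   \code{paragonScreen()}).
#' @examples
#' gliadinGuides()
#' fielderScreen()
#' @export
gliadinGuides <- function() {
  g <- read.delim(system.file("extdata", "guides.tsv",
                              package = "gliadinCRISPR", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  stopifnot(all(nchar(g$protospacer) %in% 17:23),
            !any(grepl("[^ACGT]", g$protospacer)))
  g
}

#' @rdname gliadinGuides
#' @export
degeneratePrimers <- function() {
  read.delim(system.file("extdata", "primers.tsv",
                         package = "gliadinCRISPR", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' @rdname gliadinGuides
#' @export
fielderScreen <- function() {
  read.delim(system.file("extdata", "fielder_screen.tsv",
                         package = "gliadinCRISPR", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' @rdname gliadinGuides
#' @export
paragonScreen <- function() {
  x <- read.delim(system.file("extdata", "paragon_screen.tsv",
                              package = "gliadinCRISPR", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  list(lines_screened = x$lines_screened, lines_changed = x$lines_changed)
}
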