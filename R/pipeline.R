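#' @include defaults.R classification.R guides.R editsim.R stats.R io.R
#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
NULL

#' Run the full gliadin guide-design pipeline
#'
#' Executes the stages in order -- generate synthetic families, annotate,
#' classify into subgroups, evaluate guide coverage and oligo flags,
#' simulate a mutation screen, and compute the screening statistics on the
#' shipped count tables -- writing every artifact (FASTA, TSV, JSON) under
#' \code{outDir} together with a manifest of MD5 content hashes. The same
#' configuration and seed give byte-identical artifacts.
#'
#' @param outDir output directory (created if needed).
#' @param alphaSpec,gammaSpec family specs (defaults are the study
#'   conditions at reduced copy number so a demo run takes seconds).
#' @param guides guide table (default \code{\link{gliadinGuides}()}).
#' @param policy repair policy for the simulation stage.
#' @param efficiency per-site editing efficiency for the simulation.
#' @param nPlants,grainsPerPlant simulated screen size.
#' @param seed master seed for all stages.
#' @return invisibly, a list with the stage results and the manifest
#'   \code{data.frame(file, md5)}.
#' @export
runPipeline <- function(outDir,
                        alphaSpec = defaultAlphaSpec(nCopies = 30L,
                                                     seed = 101L),
                        gammaSpec = defaultGammaSpec(nCopies = 12L,
                                                     seed = 102L),
                        guides = gliadinGuides(),
                        policy = repairPolicy(pSegmentDeletion = 1,
                                              pPerfectRepair = 0,
                                              pDeletion = 1, delSizes = 1L),
                        efficiency = 0.1, nPlants = 10L,
                        grainsPerPlant = 8L, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outDir, f)

  # generate
  alphaSpec$seed <- alphaSpec$seed + seed
  gammaSpec$seed <- gammaSpec$seed + seed
  fams <- list(alpha = generateFamily(alphaSpec),
               gamma = generateFamily(gammaSpec))
  for (f in names(fams)) writeGeneFasta(fams[[f]], path(paste0(f, ".fasta")))

  # annotate + classify + design, per family
  coverage <- list()
  for (f in names(fams)) {
    ann <- annotateGenes(fams[[f]])
    write.table(ann$hits, path(paste0(f, "_epitope_hits.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ann$domains, path(paste0(f, "_domains.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    # an all-pseudogene draw (possible at 90% pseudogenes and small n)
    # falls back to grouping the pseudogenes themselves
    cl <- classifyFamily(fams[[f]], ann = ann,
                         includePseudogenes = all(ann$pseudogene))
    write.table(cl$subgroups, path(paste0(f, "_subgroups.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gsel <- guides[guides$family == f, , drop = FALSE]
    cov <- coverageMatrix(gsel, fams[[f]], cl$membership)
    write.table(data.frame(guide = rownames(cov$counts), cov$counts,
                           check.names = FALSE),
                path(paste0(f, "_coverage.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    coverage[[f]] <- cov
  }

  # oligo flags for all guide pairs
  flags <- list(
    hairpin = lapply(setNames(guides$protospacer, guides$name), hairpinFlag),
    cross_dimer = {
      pairs <- utils::combn(nrow(guides), 2L)
      lapply(seq_len(ncol(pairs)), function(i) {
        a <- pairs[1L, i]; b <- pairs[2L, i]
        c(list(pair = paste(guides$name[c(a, b)], collapse = "+")),
          crossDimerFlag(guides$protospacer[a], guides$protospacer[b]))
      })
    })
  jsonlite::write_json(flags, path("oligo_flags.json"), auto_unbox = TRUE)

  # simulate
  genotype <- makeHexaploidGenotype(list(alphaSpec, gammaSpec),
                                    seed = seed)
  sim <- simulateScreen(genotype, guides$protospacer, efficiency, nPlants,
                        grainsPerPlant, policy, seed = seed + 1L)
  write.table(sim$counts, path("simulated_screen.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # stats on the shipped screen tables
  counts <- fielderScreen()
  pt <- percentageTable(counts)
  write.table(pt$table, path("screen_percentages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stats <- list(
    any_changes = heterogeneityChi2(counts$grains_any,
                                    counts$grains_tested),
    clear_changes = heterogeneityChi2(counts$grains_clear,
                                      counts$grains_tested),
    paragon_rate_pct = with(paragonScreen(),
                            mutationRate(lines_changed, lines_screened)))
  jsonlite::write_json(stats, path("screen_stats.json"), auto_unbox = TRUE,
                       digits = NA)

  files <- sort(list.files(outDir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.table(manifest, path("MANIFEST.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(families = fams, coverage = coverage, flags = flags,
                 simulation = sim, percentages = pt, stats = stats,
                 manifest = manifest))
}
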