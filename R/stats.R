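#' @include utils.R
#' @importFrom stats chisq.test
NULL

#' Screening percentage table
#'
#' Derives the summary percentages of a mutation screen from per-construct
#' counts: Cas9 expression among regenerated plants, low transgene copy
#' number (1-2 copies) among expressing plants, and plants/grains with
#' clear or any Acid-PAGE profile changes among those tested. A TOTAL row
#' is appended. Display values are rounded half up to \code{decimals};
#' the unrounded values are returned alongside. Cells with a zero
#' denominator are undefined (NA), not 0.
#'
#' @param counts \code{data.frame} in the layout of
#'   \code{\link{fielderScreen}()}: construct, regenerated, expressing,
#'   low_copy, plants_tested, grains_tested, plants_clear, grains_clear,
#'   plants_any, grains_any.
#' @param decimals decimal places for the display table (default 1).
#' @return list with \code{table} (rounded percentages) and \code{raw}
#'   (unrounded).
#' @examples
#' percentageTable(fielderScreen())$table
#' @export
percentageTable <- function(counts, decimals = 1L) {
  total <- counts[1L, , drop = FALSE]
  total$construct <- "TOTAL"
  num <- vapply(counts, is.numeric, TRUE)
  total[num] <- lapply(counts[num], sum)
  all <- rbind(counts, total)
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  raw <- data.frame(
    construct = all$construct,
    pct_expressing = pct(all$expressing, all$regenerated),
    pct_low_copy = pct(all$low_copy, all$expressing),
    pct_plants_clear = pct(all$plants_clear, all$plants_tested),
    pct_grains_clear = pct(all$grains_clear, all$grains_tested),
    pct_plants_any = pct(all$plants_any, all$plants_tested),
    pct_grains_any = pct(all$grains_any, all$grains_tested))
  rounded <- raw
  rounded[-1L] <- lapply(raw[-1L], roundHalfUp, digits = decimals)
  list(table = rounded, raw = raw)
}

#' Chi-square heterogeneity test across constructs
#'
#' Pearson chi-square on the 2 x k table of successes/failures, without
#' continuity correction, df = k - 1: do the constructs differ in the
#' proportion of changed plants or grains? A \code{small_expected} flag is
#' attached when any expected cell is below 1.
#'
#' @param successes,totals equal-length integer vectors, k >= 2,
#'   0 <= successes <= totals, totals > 0.
#' @return list(statistic, df, p_value, small_expected).
#' @examples
#' heterogeneityChi2(c(20, 5), c(100, 100))  # statistic 10.2857
#' @export
heterogeneityChi2 <- function(successes, totals) {
  if (length(successes) != length(totals))
    stop("successes and totals must have equal length")
  if (length(successes) < 2L) stop("at least two groups are required")
  if (any(totals <= 0L)) stop("all totals must be positive")
  if (any(successes < 0L) || any(successes > totals))
    stop("successes must satisfy 0 <= successes <= totals")
  tab <- cbind(successes, totals - successes)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       small_expected = any(ht$expected < 1))
}

#' Mutation rate of a screened population
#'
#' @param hits number of lines/grains with an altered profile.
#' @param screened number screened (> 0).
#' @return percentage, rounded half up to 2 decimals.
#' @examples
#' mutationRate(14, 360)  # 3.89
#' @export
mutationRate <- function(hits, screened) {
  if (screened <= 0L) stop("screened must be positive")
  if (hits > screened) stop("hits cannot exceed screened")
  roundHalfUp(100 * hits / screened, 2L)
}
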