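# Independent brute-force oracles. Deliberately written with plain string
# ops (no Biostrings) so they share no code path with the implementation.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleRevComp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

oracleMismatches <- function(query, window) {
  q <- strsplit(query, "")[[1L]]
  w <- strsplit(window, "")[[1L]]
  sum(!mapply(function(a, b) b %in% ORACLE_IUPAC[[a]], q, w))
}

# Sliding-window Hamming scan of both strands with NGG PAM filtering;
# returns the same columns as matchGuide, coding-strand coordinates.
oracleMatchGuide <- function(guide, subject, maxMismatch = 0L,
                             requirePam = TRUE) {
  k <- nchar(guide); L <- nchar(subject)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") subject else oracleRevComp(subject)
    if (L < k) next
    for (i in seq_len(L - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      mm <- oracleMismatches(guide, w)
      if (mm > maxMismatch) next
      pam <- substr(s, i + k, i + k + 2L)
      if (requirePam &&
          (nchar(pam) < 3L || substr(pam, 2L, 3L) != "GG")) next
      if (strand == "+") {
        rows[[length(rows) + 1L]] <-
          data.frame(start = i, end = i + k - 1L, strand = "+",
                     mismatches = mm, cut = i + k - 1L - 3L)
      } else {
        cs <- L - (i + k - 1L) + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(start = cs, end = L - i + 1L, strand = "-",
                     mismatches = mm, cut = cs + 2L)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      cut = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exhaustive all-windows epitope scan.
oracleScanEpitopes <- function(protein, catalogue) {
  rows <- list()
  for (i in seq_len(nrow(catalogue))) {
    pep <- catalogue$peptide[i]
    k <- nchar(pep)
    if (nchar(protein) < k) next
    for (p in seq_len(nchar(protein) - k + 1L))
      if (substr(protein, p, p + k - 1L) == pep)
        rows[[length(rows) + 1L]] <-
          data.frame(epitope_name = catalogue$name[i], position = p)
  }
  if (!length(rows))
    return(data.frame(epitope_name = character(), position = integer()))
  out <- do.call(rbind, rows)
  out[order(out$position, match(out$epitope_name, catalogue$name)), ,
      drop = FALSE]
}

# Exhaustive substring-pair hairpin stem search.
oracleHairpin <- function(s, minLoop = 3L) {
  n <- nchar(s); best <- 0L
  maxLen <- (n - minLoop) %/% 2L
  for (len in seq_len(max(maxLen, 0L))) {
    for (i in seq_len(n - len + 1L)) {
      a <- substr(s, i, i + len - 1L)
      jmin <- i + len + minLoop
      if (jmin > n - len + 1L) next
      for (j in seq(jmin, n - len + 1L))
        if (substr(s, j, j + len - 1L) == oracleRevComp(a))
          best <- max(best, len)
    }
  }
  best
}

# Exhaustive alignment-offset cross-dimer run search.
oracleCrossDimer <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(oracleRevComp(b), "")[[1L]]
  best <- 0L
  for (d in seq(-(length(y) - 1L), length(x) - 1L)) {
    run <- 0L
    for (j in seq_along(y)) {
      i <- j + d
      if (i >= 1L && i <= length(x) && x[i] == y[j]) {
        run <- run + 1L
        best <- max(best, run)
      } else run <- 0L
    }
  }
  best
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random DNA guaranteed to contain neither the motif nor its complement
randomDnaNoMatch <- function(n, motif) {
  repeat {
    s <- randomDna(n)
    if (!grepl(motif, s, fixed = TRUE) &&
        !grepl(oracleRevComp(motif), s, fixed = TRUE)) return(s)
  }
}

randomIupac <- function(n, pDegenerate = 0.15) {
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  deg <- sample(c("R", "Y", "M", "K", "S", "W", "N"), n, replace = TRUE)
  pick <- runif(n) < pDegenerate
  paste(ifelse(pick, deg, base), collapse = "")
}

randomProtein <- function(n, alphabet = c("P", "Q", "L", "F", "Y", "S",
                                          "A", "I")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small pseudogene-free study families reused across tests (n below the
# subgroup count returns the first n genes of a minimal family).
alphaDemo <- function(n = 15L, seed = 42L) {
  fam <- generateFamily(defaultAlphaSpec(nCopies = max(n, 5L),
                                         pseudogeneFraction = 0,
                                         seed = seed))
  fam[seq_len(n)]
}
gammaDemo <- function(n = 12L, seed = 42L) {
  fam <- generateFamily(defaultGammaSpec(nCopies = max(n, 6L),
                                         pseudogeneFraction = 0,
                                         seed = seed))
  fam[seq_len(n)]
}
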