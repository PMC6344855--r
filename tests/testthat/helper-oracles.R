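# Brute-force oracles (literal double loops over windows and occurrences)
# and fixture builders shared across test files.

random_seq <- function(n, alphabet = "nucleotide", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  letters <- if (alphabet == "nucleotide") c("A", "C", "G", "T")
             else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# literal window-by-window scorer: for every window position, count the
# occurrences of its left-most k-mer and add the counts position by position
brute_scores <- function(seq, params) {
  k <- params$k
  L <- nchar(seq)
  w <- min(params$w, L)
  km <- substring(seq, 1:(L - k + 1), k:L)
  wild <- if (params$alphabet == "nucleotide") "N" else "X"
  cc <- numeric(L)
  nk <- L - k + 1
  for (i in 1:nk) {
    if (grepl(wild, km[i], fixed = TRUE)) next
    lim <- min(i + w - k, nk)
    occ <- i - 1 + which(km[i:lim] == km[i])
    n <- length(occ)
    if (n >= 2) {
      cc[i:(i + k - 1)] <- cc[i:(i + k - 1)] + n
      for (o in occ[occ != i]) cc[o:(o + k - 1)] <- cc[o:(o + k - 1)] + 1
    }
  }
  cc
}

# literal pair-distance enumerator for the position-period matrix
brute_ppm <- function(seq, hrr, params) {
  L <- nchar(seq)
  rs <- max(0, hrr$start - params$m)
  re <- min(L, hrr$end + params$m)
  rlen <- re - rs
  region <- substr(seq, rs + 1, re)
  h <- min(hrr$end - hrr$start, rlen)
  k <- params$k
  dmax <- rlen %/% 2
  km <- substring(region, 1:(rlen - k + 1), k:rlen)
  wild <- if (params$alphabet == "nucleotide") "N" else "X"
  M <- matrix(0, dmax, rlen)
  nk <- rlen - k + 1
  for (i in 1:nk) {
    if (grepl(wild, km[i], fixed = TRUE)) next
    lim <- min(i + h - k, nk)
    occ <- i - 1 + which(km[i:lim] == km[i])
    n <- length(occ)
    if (n < 2) next
    for (j in 1:(n - 1)) {
      p <- occ[j]; pn <- occ[j + 1]
      d <- pn - p
      if (d > dmax) next
      cols <- unique(c(p:(p + k - 1), pn:(pn + k - 1)))
      M[d, cols] <- M[d, cols] + if (j == 1) n else 1
    }
  }
  M
}

# deterministic mini GenBank entry with two CDS features; expected values
# below were frozen from an independent Biopython (SeqIO) parse of this file
mini_genbank <- function(path) {
  set.seed(77)
  dna <- paste(sample(c("A", "C", "G", "T"), 420, replace = TRUE),
               collapse = "")
  tr2 <- "FQS*MVSSRRGSLDINLTPASLH*DSTSDL"
  fmt <- vapply(seq(1, 420, 60), function(s) {
    chunk <- substr(dna, s, min(s + 59, 420))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, character(1))
  writeLines(c(
    "LOCUS       testgenome                420 bp    DNA     linear   UNK 01-JAN-1980",
    "DEFINITION  synthetic mini genome for parser tests.",
    "FEATURES             Location/Qualifiers",
    "     source          1..420",
    "     CDS             31..120",
    "                     /locus_tag=\"T1\"",
    "     CDS             complement(201..290)",
    "                     /locus_tag=\"T2\"",
    paste0("                     /translation=\"", tr2, "\""),
    "ORIGIN", fmt, "//"), path)
  list(dna = dna, tr2 = tr2)
}
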