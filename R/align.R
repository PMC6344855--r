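# Internal deterministic aligners built on Biostrings pairwise alignment:
# a center-star progressive multiple aligner for repeat-unit fragments, and
# an iterative masked local (Smith-Waterman) search used to map the
# representative motif back to the repeat region.

# substitution matrix for unit alignment: DNA match +1 / mismatch -1
# (wildcard N neutral), protein BLOSUM62; affine gaps open 4, extend 1.
msa_submat <- function(alphabet) {
  if (alphabet == "nucleotide") {
    l <- c("A", "C", "G", "T", "N", "U")
    m <- matrix(-1, length(l), length(l), dimnames = list(l, l))
    diag(m) <- 1
    m["N", ] <- 0; m[, "N"] <- 0
    m
  } else {
    get_blosum62()
  }
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# short-query local search scoring plus standard Karlin-Altschul parameters
# for E-values (gapped values for the respective scoring schemes)
search_scoring <- function(alphabet) {
  if (alphabet == "nucleotide") {
    l <- c("A", "C", "G", "T", "N", "U", "#")
    m <- matrix(-3, length(l), length(l), dimnames = list(l, l))
    diag(m) <- 1
    m["N", ] <- 0; m[, "N"] <- 0
    m["#", ] <- -1e6; m[, "#"] <- -1e6
    list(submat = m, gap_open = 5, gap_ext = 2, lambda = 1.28, K = 0.46)
  } else {
    # short-query protein search: PAM30 with gap 9/1 (blastp-short style)
    e <- new.env()
    utils::data("PAM30", package = "Biostrings", envir = e)
    b <- e$PAM30
    l <- c(rownames(b), "#")
    m <- matrix(-1e6, length(l), length(l), dimnames = list(l, l))
    m[rownames(b), colnames(b)] <- b
    list(submat = m, gap_open = 9, gap_ext = 1, lambda = 0.294, K = 0.11)
  }
}

#' Align repeat-unit fragments (center-star progressive alignment)
#'
#' Deterministic internal multiple aligner: the fragment maximizing the total
#' pairwise alignment score against all others is taken as the center (ties
#' toward the earlier fragment); every fragment is aligned to the center by
#' global affine-gap pairwise alignment (DNA match +1 / mismatch -1, protein
#' BLOSUM62; gap open 4, extend 1) and the pairwise alignments are merged
#' column-wise ("once a gap, always a gap").
#'
#' @param fragments character vector of >= 2 unit fragments.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param backend `"center_star"` (internal, default) or `"mafft"` to call an
#'   external MAFFT executable.
#' @param mafft_path path to the MAFFT executable (backend `"mafft"`).
#' @return A `unit_alignment` object: list with `rows` (equal-length gapped
#'   strings, one per fragment, in input order), `alphabet`, `center` (index
#'   of the center fragment, `NA` for the external backend).
#' @export
align_units <- function(fragments, alphabet = c("nucleotide", "amino_acid"),
                        backend = c("center_star", "mafft"),
                        mafft_path = "mafft") {
  alphabet <- match.arg(alphabet)
  backend <- match.arg(backend)
  if (length(fragments) < 2L) stop("insufficient units: need >= 2 fragments")
  fragments <- toupper(fragments)
  if (backend == "mafft")
    return(align_units_mafft(fragments, alphabet, mafft_path))
  if (length(unique(fragments)) == 1L) {
    return(structure(list(rows = fragments, alphabet = alphabet, center = 1L),
                     class = "unit_alignment"))
  }
  sm <- msa_submat(alphabet)
  frs <- Biostrings::BStringSet(fragments)
  totals <- vapply(seq_along(fragments), function(i) {
    sum(Biostrings::pairwiseAlignment(frs, frs[[i]], type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 4, gapExtension = 1,
                                      scoreOnly = TRUE))
  }, numeric(1))
  ctr <- which.max(totals)
  center <- fragments[ctr]
  Lc <- nchar(center)
  pa <- Biostrings::pairwiseAlignment(frs, center, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 4, gapExtension = 1)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  n <- length(fragments)
  ins <- matrix(0L, n, Lc + 1L)          # insertions after center position j
  chars <- vector("list", n)             # per row: list over slots
  for (r in seq_len(n)) {
    pc <- strsplit(ap[r], "")[[1]]
    sc <- strsplit(as_[r], "")[[1]]
    slots <- vector("list", 2L * Lc + 1L)  # odd: insertion slot, even: column
    cpos <- 0L
    for (j in seq_along(sc)) {
      if (sc[j] == "-") {
        slot <- 2L * cpos + 1L
        slots[[slot]] <- c(slots[[slot]], pc[j])
        ins[r, cpos + 1L] <- ins[r, cpos + 1L] + 1L
      } else {
        cpos <- cpos + 1L
        slots[[2L * cpos]] <- pc[j]
      }
    }
    chars[[r]] <- slots
  }
  maxins <- apply(ins, 2L, max)
  rows <- character(n)
  for (r in seq_len(n)) {
    out <- character(0)
    for (j in 0:Lc) {
      blk <- chars[[r]][[2L * j + 1L]]
      pad <- maxins[j + 1L] - length(blk)
      if (maxins[j + 1L] > 0L)
        out <- c(out, blk, rep("-", pad))
      if (j < Lc) {
        ch <- chars[[r]][[2L * (j + 1L)]]
        out <- c(out, if (is.null(ch)) "-" else ch)
      }
    }
    rows[r] <- paste(out, collapse = "")
  }
  structure(list(rows = rows, alphabet = alphabet, center = ctr),
            class = "unit_alignment")
}

#' @export
print.unit_alignment <- function(x, ...) {
  cat("unit alignment:", length(x$rows), "rows x", nchar(x$rows[1]),
      "columns (", x$alphabet, ")\n")
  if (length(x$rows) <= 20) cat(paste(x$rows, collapse = "\n"), "\n")
  invisible(x)
}

align_units_mafft <- function(fragments, alphabet, mafft_path) {
  inp <- tempfile(fileext = ".fa")
  out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(inp, out)), add = TRUE)
  writeLines(paste0(">f", seq_along(fragments), "\n", fragments), inp)
  status <- suppressWarnings(
    system2(mafft_path, c("--auto", "--quiet", inp), stdout = out,
            stderr = FALSE))
  if (!identical(status, 0L))
    stop("alignment backend failed (mafft); fragments: ",
         paste(fragments, collapse = ","))
  aln <- Biostrings::readBStringSet(out)
  rows <- toupper(as.character(aln))
  rows <- rows[order(as.integer(sub("^f", "", names(rows))))]
  structure(list(rows = unname(rows), alphabet = alphabet, center = NA_integer_),
            class = "unit_alignment")
}

# iterative masked local alignment of a short query against a region; returns
# hits (subject intervals, scores, E-values) and per-hit query-position maps
local_search <- function(query, region_seq, alphabet, max_hits = NULL) {
  sc <- search_scoring(alphabet)
  m <- nchar(query)
  n0 <- nchar(region_seq)
  subj <- strsplit(region_seq, "")[[1]]
  known <- rownames(sc$submat)
  subj[!subj %in% known] <- if (alphabet == "nucleotide") "N" else "X"
  if (is.null(max_hits)) max_hits <- 5L + ceiling(n0 / max(1L, m %/% 2L))
  hits <- list()
  repeat {
    if (length(hits) >= max_hits) break
    pa <- Biostrings::pairwiseAlignment(
      query, paste(subj, collapse = ""), type = "local",
      substitutionMatrix = sc$submat,
      gapOpening = sc$gap_open, gapExtension = sc$gap_ext)
    S <- Biostrings::score(pa)
    if (!is.finite(S) || S <= 0) break
    ap <- as.character(Biostrings::alignedPattern(pa))
    alen <- nchar(ap)
    evalue <- sc$K * m * n0 * exp(-sc$lambda * S)
    if (!(alen >= 0.5 * m || evalue <= 0.01)) break
    ss <- Biostrings::start(Biostrings::subject(pa))
    se <- Biostrings::end(Biostrings::subject(pa))
    qmap <- rep("-", m)
    pc <- strsplit(ap, "")[[1]]
    scs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    qpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
    for (j in seq_along(pc)) {
      if (pc[j] != "-") {
        qpos <- qpos + 1L
        qmap[qpos] <- scs[j]
      }
    }
    hits[[length(hits) + 1L]] <-
      list(sstart = ss, send = se, score = S, evalue = evalue, qmap = qmap)
    subj[ss:se] <- "#"
  }
  hits
}
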