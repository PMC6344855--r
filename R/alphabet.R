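#' Classify a sequence as nucleotide or amino acid
#'
#' A sequence is called nucleotide when at least 95% of its letters belong to
#' the DNA/RNA alphabet `{A, C, G, T, U, N}` (case-insensitive); otherwise it
#' is called amino acid. The rule is deterministic and total: every non-empty
#' string is classified.
#'
#' @param sequence a single character string.
#' @return `"nucleotide"` or `"amino_acid"`.
#' @export
#' @examples
#' detect_alphabet("ACGTACGTAC")  # nucleotide
#' detect_alphabet("MKVLHWRDES")  # amino_acid
detect_alphabet <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("cannot classify an empty sequence")
  ch <- strsplit(toupper(sequence), "")[[1]]
  frac <- mean(ch %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.95) "nucleotide" else "amino_acid"
}

# Vector of k-mer strings starting at every position 1..L-k+1.
kmer_strings <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k")
  substring(seq, 1:(L - k + 1L), k:L)
}

# Integer k-mer identifiers (equal strings share an id) and seed-skip flags
# for k-mers containing the alphabet wildcard (N or X).
kmer_ids <- function(seq, k, alphabet) {
  km <- kmer_strings(seq, k)
  ids <- match(km, km)            # id = position of first occurrence
  skip <- grepl(alphabet_wildcard(alphabet), km, fixed = TRUE)
  list(ids = ids, skip = skip, n = length(ids), kmers = km)
}
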