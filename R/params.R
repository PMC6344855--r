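#' Default screening parameters
#'
#' Returns the parameter set controlling all three screening phases.
#' Defaults follow the published values for each alphabet:
#' nucleotide `w = 1000, k = 10, s = 20, g = 300, m = 1000, P = 0.5`;
#' amino acid `w = 300, k = 3, s = 6, g = 50, m = 300, P = 0.3`;
#' shared motif parameters `q = 0.5, u = 0.8, r = 5`.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param ... named overrides for individual parameters.
#'
#' @return An object of class `periscan_params`: a named list with elements
#'   `w` (sliding-window size, positions), `k` (k-mer size), `s` (peak-height
#'   threshold for cumulative k-mer peak areas), `g` (maximum zero-score gap
#'   merged into one highly repetitive region), `m` (flank added on each side
#'   of an HRR before building the position-period matrix), `P` (minimum
#'   periodicity score for a periodic repeat region), `q` (maximum column gap
#'   fraction kept in a unit alignment), `u` (letter-consistency threshold, in
#'   gap-weighted bits), `r` (minimum length of a removable nonconsensus run)
#'   and `alphabet`.
#' @export
#' @examples
#' default_params("nucleotide")
#' default_params("amino_acid", P = 0.4)
default_params <- function(alphabet = c("nucleotide", "amino_acid"), ...) {
  alphabet <- match.arg(alphabet)
  p <- if (alphabet == "nucleotide") {
    list(w = 1000L, k = 10L, s = 20, g = 300L, m = 1000L, P = 0.5)
  } else {
    list(w = 300L, k = 3L, s = 6, g = 50L, m = 300L, P = 0.3)
  }
  p <- c(p, list(q = 0.5, u = 0.8, r = 5L, alphabet = alphabet))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "periscan_params")
}

validate_params <- function(p) {
  num <- c("w", "k", "s", "g", "m", "P", "q", "u", "r")
  for (nm in num) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]))
      stop("parameter ", nm, " must be a single number")
  }
  if (p$w <= 0 || p$k <= 0 || p$s <= 0 || p$g < 0 || p$m < 0 || p$r <= 0)
    stop("window, k-mer, threshold and run-length parameters must be positive")
  if (p$k >= p$w) stop("k must be smaller than the window size w")
  if (p$P <= 0 || p$P > 1) stop("P must lie in (0, 1]")
  if (p$q <= 0 || p$q > 1) stop("q must lie in (0, 1]")
  if (p$u <= 0) stop("u must be positive")
  if (!p$alphabet %in% c("nucleotide", "amino_acid")) stop("bad alphabet")
  invisible(p)
}

#' @export
print.periscan_params <- function(x, ...) {
  cat("periscan parameters (", x$alphabet, ")\n", sep = "")
  cat(sprintf("  phase 1: w=%d k=%d s=%g g=%d\n", x$w, x$k, x$s, x$g))
  cat(sprintf("  phase 2: m=%d P=%g\n", x$m, x$P))
  cat(sprintf("  phase 3: q=%g u=%g r=%d\n", x$q, x$u, x$r))
  invisible(x)
}

# letters of each alphabet (canonical, no ambiguity codes)
alphabet_letters <- function(alphabet) {
  if (alphabet == "nucleotide") c("A", "C", "G", "T")
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

# wildcard letter skipped as a window seed
alphabet_wildcard <- function(alphabet) {
  if (alphabet == "nucleotide") "N" else "X"
}
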