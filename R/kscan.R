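#' Cumulative k-mer scores along a sequence (phase 1)
#'
#' Scans the sequence with a sliding window of size `w` (`min(w, length)` for
#' short sequences). At each window position the left-most k-mer of the window
#' is taken as the seed; when it occurs `n >= 2` times inside the window, `n`
#' is added to the score of every position of the seed k-mer and 1 is added to
#' every position covered by each other occurrence. Windows whose seed k-mer
#' is unique in the window contribute nothing, so score gaps (c = 0) separate
#' repetitive regions from unique background. Every k-mer position anchors a
#' window; windows running past the sequence end are clipped. Seed k-mers
#' containing the alphabet wildcard (`N`/`X`) are skipped; their positions can
#' still be counted as occurrences of other seeds when letter-identical.
#'
#' @param seq single character string (uppercase letters).
#' @param params a [default_params()] object.
#' @return A `score_track` object: list with `scores` (numeric vector, one
#'   value per sequence position), `params`, and `length`.
#' @seealso [extract_ckpas()], [merge_to_hrrs()]
#' @export
cumulative_kmer_scores <- function(seq, params) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- as.integer(params$k)
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k: empty score track")
  w_eff <- min(as.integer(params$w), L)
  nk <- L - k + 1L
  ki <- kmer_ids(seq, k, params$alphabet)
  did <- match(ki$ids, unique(ki$ids))
  ng <- max(did)
  cnt <- tabulate(did, nbins = ng)
  starts <- cumsum(c(0L, cnt[-ng]))
  ord <- order(did)                      # stable: ascending position in group
  rank_in_group <- integer(nk)
  rank_in_group[ord] <- sequence(cnt)
  gpos <- ord
  up <- starts                           # per-group pointer: last index <= lim
  D <- numeric(L + k + 1L)               # difference array for range adds
  span <- w_eff - k                      # occurrences start within i..i+span
  skip <- ki$skip
  for (i in seq_len(nk)) {
    if (skip[i]) next
    g <- did[i]
    lim <- min(i + span, nk)             # trailing windows clip at the end
    hi <- up[g]
    gend <- starts[g] + cnt[g]
    while (hi < gend && gpos[hi + 1L] <= lim) hi <- hi + 1L
    up[g] <- hi
    lo <- starts[g] + rank_in_group[i]
    n <- hi - lo + 1L
    if (n >= 2L) {
      D[i] <- D[i] + n
      D[i + k] <- D[i + k] - n
      oth <- gpos[(lo + 1L):hi]
      D[oth] <- D[oth] + 1
      D[oth + k] <- D[oth + k] - 1
    }
  }
  structure(list(scores = cumsum(D[seq_len(L)]), params = params, length = L),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("cumulative k-mer score track: length", x$length,
      "| max", max(x$scores), "| positive positions", sum(x$scores > 0), "\n")
  invisible(x)
}

#' Extract cumulative k-mer peak areas (CKPAs)
#'
#' A CKPA is a maximal run of strictly positive scores whose maximum reaches
#' the peak-height threshold `s`. Intervals are 0-based half-open, sorted and
#' non-overlapping.
#'
#' @param track a [cumulative_kmer_scores()] result.
#' @param s peak-height threshold (default from `track$params`).
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `peak_height`.
#' @export
extract_ckpas <- function(track, s = track$params$s) {
  runs <- positive_runs(track$scores)
  if (nrow(runs) == 0L) return(runs[, c("start", "end", "peak_height")])
  runs <- runs[runs$peak_height >= s, , drop = FALSE]
  rownames(runs) <- NULL
  runs[, c("start", "end", "peak_height")]
}

# maximal runs of scores > 0, as 0-based half-open intervals with run maxima
positive_runs <- function(scores) {
  r <- rle(scores > 0)
  ends1 <- cumsum(r$lengths)             # 1-based inclusive run ends
  starts1 <- ends1 - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      peak_height = numeric(0)))
  }
  pk <- vapply(keep, function(j) max(scores[starts1[j]:ends1[j]]), numeric(1))
  data.frame(start = starts1[keep] - 1L, end = ends1[keep],
             peak_height = pk)
}

#' Merge peak areas into highly repetitive regions (HRRs)
#'
#' Chains of CKPAs separated by gaps of `g` or less positions are merged into
#' one region spanning the outermost peak-area bounds; the reported peak
#' height is the chain maximum. Positive runs whose own peak stays below the
#' threshold (isolated low-complexity blips) do not extend a chain — with a
#' permissive merge gap they would bridge unrelated regions through random
#' k-mer coincidences and bloat every region, diluting the downstream
#' periodicity score and inflating mapped unit counts.
#'
#' @param ckpas data.frame from [extract_ckpas()].
#' @param track the corresponding score track (supplies the default `g`).
#' @param g maximum merge gap (default from `track$params`).
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `peak_height`; regions are sorted and disjoint.
#' @export
merge_to_hrrs <- function(ckpas, track, g = track$params$g) {
  if (nrow(ckpas) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      peak_height = numeric(0)))
  }
  gap_before <- c(Inf, ckpas$start[-1L] - ckpas$end[-nrow(ckpas)])
  chain <- cumsum(gap_before > g)
  out <- lapply(split(seq_len(nrow(ckpas)), chain), function(ix) {
    data.frame(start = ckpas$start[ix[1L]], end = ckpas$end[ix[length(ix)]],
               peak_height = max(ckpas$peak_height[ix]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect highly repetitive regions in one call
#'
#' Convenience wrapper: [cumulative_kmer_scores()] then [extract_ckpas()] and
#' [merge_to_hrrs()].
#'
#' @inheritParams cumulative_kmer_scores
#' @return data.frame of HRRs (`start`, `end` 0-based half-open,
#'   `peak_height`).
#' @export
detect_hrrs <- function(seq, params) {
  track <- cumulative_kmer_scores(seq, params)
  merge_to_hrrs(extract_ckpas(track), track)
}
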