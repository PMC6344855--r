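# Phase 2: position-period matrix (PPM), dominant period, periodicity score.
#
# The PPM is built over the HRR's surrounding region [start - m, end + m)
# (clipped to the sequence) with a sliding window equal to the HRR size h.
# For every window, the occurrences p1 < p2 < ... < pn of the left-most
# k-mer are chained; the first consecutive pair adds n and every later
# consecutive pair adds 1, at the row equal to the pair distance, to all
# columns covered by the two k-mer spans. Row depth is capped at
# floor(region length / 2), matching the periodicity-score denominator.

# Shared occurrence-chain scan over a region. `emit(first_pos, occ, n)` is
# called for every window anchor whose seed k-mer recurs in the window.
# Every k-mer position of the region anchors a window; windows extending past
# the region end are clipped, so chains are collected across the whole region
# even when the window size approaches the region size.
ppm_scan <- function(region_seq, h, k, alphabet, emit) {
  L <- nchar(region_seq)
  nk <- L - k + 1L
  ki <- kmer_ids(region_seq, k, alphabet)
  did <- match(ki$ids, unique(ki$ids))
  ng <- max(did)
  cnt <- tabulate(did, nbins = ng)
  starts <- cumsum(c(0L, cnt[-ng]))
  ord <- order(did)
  rank_in_group <- integer(nk)
  rank_in_group[ord] <- sequence(cnt)
  up <- starts
  span <- h - k
  for (i in seq_len(nk)) {
    if (ki$skip[i]) next
    g <- did[i]
    lim <- min(i + span, nk)
    hi <- up[g]
    gend <- starts[g] + cnt[g]
    while (hi < gend && ord[hi + 1L] <= lim) hi <- hi + 1L
    up[g] <- hi
    lo <- starts[g] + rank_in_group[i]
    n <- hi - lo + 1L
    if (n >= 2L) emit(i, ord[lo:hi], n)
  }
  invisible(NULL)
}

ppm_region <- function(seq_len_total, hrr, m) {
  rs <- max(0L, hrr$start - as.integer(m))
  re <- min(seq_len_total, hrr$end + as.integer(m))
  list(rs = rs, re = re, h = hrr$end - hrr$start)
}

#' Build the position-period matrix for an HRR neighborhood
#'
#' @param seq the full sequence (character scalar).
#' @param hrr one HRR: a list or one-row data.frame with `start`, `end`
#'   (0-based half-open).
#' @param params a [default_params()] object.
#' @return A `ppm` object: list with `matrix` (rows = pair distance 1..D_max,
#'   columns = position within the scanned region), `region_start`,
#'   `region_end` (0-based half-open bounds of the scanned region), `window`
#'   (the window size h) and `k`.
#' @export
build_ppm <- function(seq, hrr, params) {
  L <- nchar(seq)
  reg <- ppm_region(L, hrr, params$m)
  rlen <- reg$re - reg$rs
  k <- as.integer(params$k)
  if (rlen < k) stop("scanned region shorter than k: empty matrix")
  h <- min(reg$h, rlen)
  dmax <- rlen %/% 2L
  M <- matrix(0, nrow = dmax, ncol = rlen)
  region_seq <- substr(seq, reg$rs + 1L, reg$re)
  emit <- function(i, occ, n) {
    for (j in seq_len(length(occ) - 1L)) {
      p <- occ[j]; pn <- occ[j + 1L]
      d <- pn - p
      if (d > dmax) next
      cols <- if (d < k) p:(pn + k - 1L) else c(p:(p + k - 1L), pn:(pn + k - 1L))
      val <- if (j == 1L) n else 1L
      M[d, cols] <<- M[d, cols] + val
    }
  }
  ppm_scan(region_seq, h, k, params$alphabet, emit)
  structure(list(matrix = M, region_start = reg$rs, region_end = reg$re,
                 window = h, k = k),
            class = "ppm")
}

# Fast path: accumulate only the row marginal (sum over columns) of the PPM.
# Exact: each pair at distance d covers k + min(d, k) columns.
ppm_marginal_fast <- function(seq, hrr, params) {
  L <- nchar(seq)
  reg <- ppm_region(L, hrr, params$m)
  rlen <- reg$re - reg$rs
  k <- as.integer(params$k)
  if (rlen < k) stop("scanned region shorter than k: empty matrix")
  h <- min(reg$h, rlen)
  dmax <- rlen %/% 2L
  region_seq <- substr(seq, reg$rs + 1L, reg$re)
  acc_d <- vector("list", rlen)
  acc_w <- vector("list", rlen)
  ii <- 0L
  emit <- function(i, occ, n) {
    dv <- diff(occ)
    vals <- rep(1, length(dv)); vals[1L] <- n
    ii <<- ii + 1L
    acc_d[[ii]] <<- dv
    acc_w[[ii]] <<- vals * (k + pmin(dv, k))
  }
  ppm_scan(region_seq, h, k, params$alphabet, emit)
  marg <- numeric(dmax)
  if (ii > 0L) {
    dd <- unlist(acc_d[seq_len(ii)], use.names = FALSE)
    ww <- unlist(acc_w[seq_len(ii)], use.names = FALSE)
    keep <- dd <= dmax
    if (any(keep)) {
      agg <- rowsum(ww[keep], dd[keep])
      marg[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  structure(list(marginal = marg, ncol = rlen, region_start = reg$rs,
                 region_end = reg$re, window = h, k = k),
            class = "ppm_marginal")
}

#' @export
print.ppm <- function(x, ...) {
  cat("position-period matrix:", nrow(x$matrix), "periods x", ncol(x$matrix),
      "positions | region [", x$region_start, ",", x$region_end,
      ") | window", x$window, "\n")
  invisible(x)
}

#' Row marginal of a position-period matrix
#'
#' Sums each row (pair distance) across columns; the distribution over which
#' the dominant period is identified.
#'
#' @param ppm a `ppm` or `ppm_marginal` object.
#' @return numeric vector indexed by pair distance `1..D_max`.
#' @export
ppm_row_marginal <- function(ppm) {
  if (inherits(ppm, "ppm_marginal")) return(ppm$marginal)
  if (inherits(ppm, "ppm")) return(rowSums(ppm$matrix))
  if (is.numeric(ppm)) return(ppm)
  stop("not a position-period matrix")
}

#' Dominant repeat period of a PPM
#'
#' The pair distance with the largest row marginal; ties break toward the
#' smaller period.
#'
#' @inheritParams ppm_row_marginal
#' @return integer period.
#' @export
dominant_period <- function(ppm) {
  marg <- ppm_row_marginal(ppm)
  if (!any(marg > 0)) stop("all-zero position-period matrix: no period")
  which.max(marg)  # first maximum = smallest period
}

#' Periodicity score of a PPM at period d
#'
#' Mass in rows `floor(0.8 d) .. ceiling(1.2 d)` divided by the mass in rows
#' `1 .. floor(ncol / 2)` (the full row depth of the matrix). Lies in
#' `[0, 1]` and is invariant under uniform scaling of the matrix.
#'
#' @inheritParams ppm_row_marginal
#' @param d period (row index).
#' @return numeric score in `[0, 1]`.
#' @export
periodicity_score <- function(ppm, d) {
  marg <- ppm_row_marginal(ppm)
  denom <- sum(marg)
  if (denom <= 0) stop("zero total PPM mass: periodicity score undefined")
  lo <- max(1L, floor(0.8 * d))
  hi <- min(length(marg), ceiling(1.2 * d))
  sum(marg[lo:hi]) / denom
}

#' Promote an HRR to a periodic repeat region (PRR)
#'
#' @param hrr one HRR (list or one-row data.frame with `start`, `end`,
#'   optionally `peak_height`).
#' @param ppm the PPM (or row marginal) for the HRR neighborhood.
#' @param params a [default_params()] object.
#' @return A one-row data.frame with `start`, `end`, `peak_height`, `period`
#'   and `score` when the periodicity score reaches `params$P`; otherwise
#'   `NULL`.
#' @export
promote_to_prr <- function(hrr, ppm, params) {
  d <- dominant_period(ppm)
  sc <- periodicity_score(ppm, d)
  if (sc < params$P) return(NULL)
  data.frame(start = hrr$start, end = hrr$end,
             peak_height = if (!is.null(hrr$peak_height)) hrr$peak_height else NA_real_,
             period = as.integer(d), score = sc)
}

#' Detect periodic repeat regions (phases 1 and 2)
#'
#' Runs [detect_hrrs()] and promotes each HRR whose periodicity score reaches
#' `params$P`.
#'
#' @inheritParams cumulative_kmer_scores
#' @return data.frame of PRRs: `start`, `end` (0-based half-open),
#'   `peak_height`, `period`, `score`. Zero rows when nothing is found.
#' @export
detect_prrs <- function(seq, params) {
  detect_prrs_from_hrrs(seq, detect_hrrs(seq, params), params)
}
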