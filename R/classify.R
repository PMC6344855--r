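# Downstream descriptors and benchmark statistics: CRISPR candidate
# filtering, region overlap agreement (ROA), recall/precision/FPR, the
# positive likelihood ratio, and per-protein maximum repeat unit size
# filtering.

#' Summarize a periodic repeat region and its mapped units
#'
#' @param prr one PRR (with `start`, `end`, `period`, `score`).
#' @param motif the matching `repeat_motif` (see [representative_and_map()]),
#'   or `NULL` when phase 3 produced none.
#' @param alphabet alphabet of the scanned record.
#' @param record_id id of the scanned record.
#' @return A one-row data.frame: `record`, `start`, `end`, `alphabet`,
#'   `period`, `score`, `n_units`, `unit_size` (median mapped unit length),
#'   `interspace` (median gap between consecutive mapped units) and `motif`
#'   (masked motif string).
#' @export
repeat_descriptor <- function(prr, motif, alphabet, record_id = "seq") {
  n_units <- if (is.null(motif)) NA_integer_ else motif$n_units
  unit_size <- interspace <- NA_real_
  motif_str <- NA_character_
  if (!is.null(motif)) {
    un <- motif$units
    unit_size <- stats::median(un$end - un$start)
    interspace <- if (nrow(un) >= 2L)
      stats::median(un$start[-1L] - un$end[-nrow(un)]) else 0
    motif_str <- motif$masked_motif
  }
  data.frame(record = record_id, start = prr$start, end = prr$end,
             alphabet = alphabet, period = as.integer(prr$period),
             score = prr$score, n_units = n_units, unit_size = unit_size,
             interspace = interspace, motif = motif_str,
             stringsAsFactors = FALSE)
}

#' CRISPR candidate filter
#'
#' A nucleotide repeat descriptor is a CRISPR candidate when its interspace
#' size lies in 25-60 bp and its repeating period in 58-81 bp (all bounds
#' inclusive).
#'
#' @param desc a [repeat_descriptor()] row (needs `alphabet`, `period`,
#'   `interspace`).
#' @return logical.
#' @export
is_crispr_candidate <- function(desc) {
  if (any(desc$alphabet != "nucleotide"))
    stop("CRISPR candidate filtering applies to nucleotide repeats only")
  !is.na(desc$interspace) &
    desc$interspace >= 25 & desc$interspace <= 60 &
    desc$period >= 58 & desc$period <= 81
}

#' Region overlap agreement (ROA)
#'
#' Overlap size divided by union size of two intervals on the same record;
#' symmetric, in `[0, 1]`, and 1 iff the intervals are identical.
#'
#' @param a,b intervals as `c(start, end)` (0-based half-open) or one-row
#'   data.frames with `start`, `end`.
#' @return numeric ROA.
#' @export
region_overlap_agreement <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  if (a[2L] <= a[1L] || b[2L] <= b[1L])
    stop("ROA undefined for empty intervals")
  ov <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  un <- max(a[2L], b[2L]) - min(a[1L], b[1L])
  # union of two possibly disjoint intervals: total covered length
  if (ov == 0) un <- (a[2L] - a[1L]) + (b[2L] - b[1L])
  ov / un
}

as_interval <- function(x) {
  if (is.data.frame(x)) c(x$start[1L], x$end[1L]) else as.numeric(x[1:2])
}

#' Benchmark predicted intervals against a truth set
#'
#' A truth region is recalled when some prediction reaches ROA at or above
#' the threshold with it; a prediction is a true positive when it reaches the
#' threshold with some truth region. Matching is greedy 1-to-1 by descending
#' ROA within each record.
#'
#' @param pred,truth data.frames with `record`, `start`, `end` (0-based
#'   half-open). See [read_intervals()] for file input.
#' @param roa_threshold ROA threshold in `[0, 1]`.
#' @param fpr optional externally measured false positive rate, stored in the
#'   result and used for the positive likelihood ratio.
#' @return list with `recall`, `precision`, `n_truth`, `n_pred`,
#'   `true_positives`, `roa_threshold`, `fpr` and `plr` (recall / fpr; `Inf`
#'   when `fpr` is zero, `NA` when `fpr` is missing).
#' @export
evaluate_predictions <- function(pred, truth, roa_threshold, fpr = NA_real_) {
  stopifnot(roa_threshold >= 0, roa_threshold <= 1)
  if (is.null(truth) || nrow(truth) == 0L)
    stop("recall undefined: empty truth set")
  if (is.null(pred$record)) pred$record <- "seq"
  if (is.null(truth$record)) truth$record <- "seq"
  tp <- 0L
  matched_truth <- 0L
  for (rec in unique(truth$record)) {
    tt <- truth[truth$record == rec, , drop = FALSE]
    pp <- pred[pred$record == rec, , drop = FALSE]
    if (nrow(pp) == 0L) next
    roa <- outer(seq_len(nrow(pp)), seq_len(nrow(tt)),
                 Vectorize(function(i, j)
                   region_overlap_agreement(pp[i, ], tt[j, ])))
    used_p <- logical(nrow(pp)); used_t <- logical(nrow(tt))
    repeat {
      roa_w <- roa
      roa_w[used_p, ] <- -1; roa_w[, used_t] <- -1
      best <- which.max(roa_w)
      if (length(best) == 0L || roa_w[best] < roa_threshold) break
      ij <- arrayInd(best, dim(roa_w))
      used_p[ij[1L]] <- TRUE; used_t[ij[2L]] <- TRUE
      tp <- tp + 1L
      matched_truth <- matched_truth + 1L
    }
  }
  recall <- matched_truth / nrow(truth)
  precision <- if (nrow(pred)) tp / nrow(pred) else NA_real_
  list(recall = recall, precision = precision,
       n_truth = nrow(truth), n_pred = nrow(pred), true_positives = tp,
       roa_threshold = roa_threshold, fpr = fpr,
       plr = if (is.na(fpr)) NA_real_ else positive_likelihood_ratio(recall, fpr))
}

#' Positive likelihood ratio
#'
#' Recall divided by false positive rate; `Inf` when the FPR is zero.
#'
#' @param recall,fpr rates in `[0, 1]`.
#' @return numeric PLR.
#' @export
positive_likelihood_ratio <- function(recall, fpr) {
  stopifnot(recall >= 0, recall <= 1, fpr >= 0, fpr <= 1)
  if (fpr == 0) return(Inf)
  recall / fpr
}

#' Filter proteins by maximum repeat unit size per protein (maxRUSPP)
#'
#' Keeps proteins whose largest detected repeat unit size lies within
#' `tolerance` of the expected family unit size (bounds inclusive).
#'
#' @param proteins data.frame with columns `id` and `maxruspp` (largest
#'   median unit size among the protein's PRRs).
#' @param expected_unit expected family unit size (aa).
#' @param tolerance allowed deviation (aa), default 5.
#' @return the kept subset of `proteins`.
#' @export
filter_by_maxruspp <- function(proteins, expected_unit, tolerance = 5) {
  keep <- !is.na(proteins$maxruspp) &
    abs(proteins$maxruspp - expected_unit) <= tolerance
  proteins[keep, , drop = FALSE]
}

#' Read truth or prediction intervals from BED or 3-column TSV
#'
#' BED and plain 3-column TSV are both read as (record, start, end) with
#' 0-based half-open coordinates; header lines and extra columns are
#' tolerated.
#'
#' @param path input file.
#' @return data.frame `record`, `start`, `end`.
#' @export
read_intervals <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!is.numeric(df[[2L]])) {  # header row present
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
  }
  out <- data.frame(record = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("empty interval in ", path)
  out
}
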