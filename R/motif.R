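# Phase 3: seed k-mer, unit fragments, consensus punctuation and motif
# mapping.

#' Seed k-mer of a periodic repeat region
#'
#' Among all k-mers occurring in the PRR, returns the one whose
#' consecutive-occurrence pairs at distances within
#' `floor(0.8 d) .. ceiling(1.2 d)` contribute the largest total
#' position-period-matrix mass (value added times columns covered); ties
#' break toward the k-mer whose first occurrence is left-most.
#'
#' @param seq full sequence (character scalar).
#' @param prr one PRR (list or one-row data.frame with `start`, `end`,
#'   `period`).
#' @param params a [default_params()] object.
#' @return the seed k-mer string.
#' @export
find_kseed <- function(seq, prr, params) {
  k <- as.integer(params$k)
  d <- as.integer(prr$period)
  region_seq <- substr(seq, prr$start + 1L, prr$end)
  rlen <- nchar(region_seq)
  if (rlen < k) stop("region shorter than k")
  lo <- max(1L, floor(0.8 * d))
  hi <- ceiling(1.2 * d)
  ki <- kmer_ids(region_seq, k, params$alphabet)
  # each consecutive-occurrence pair counts once, weighted by the PPM columns
  # it covers; for a perfect tandem every unit rotation then ties exactly and
  # the left-most one is selected
  by_id <- split(seq_len(ki$n), ki$ids)
  stats <- vapply(by_id, function(occ) {
    if (length(occ) < 2L) return(c(0, 0))
    dv <- diff(occ)
    w <- k + pmin(dv, k)
    c(sum(w[dv >= lo & dv <= hi]), sum(w))
  }, numeric(2))
  mass <- stats[1L, ]
  purity <- ifelse(stats[2L, ] > 0, stats[1L, ] / stats[2L, ], 0)
  first <- vapply(by_id, `[[`, integer(1), 1L)
  skip <- ki$skip[first]
  ok <- mass > 0 & !skip
  if (!any(ok)) stop("seed not found: no k-mer recurs within the period band")
  # ties on in-band mass break toward the more purely periodic k-mer (all of
  # whose occurrence pairs lie in the band), then toward the left-most one
  ord <- order(-mass[ok], -purity[ok], first[ok])[1L]
  i0 <- first[ok][ord]
  substr(region_seq, i0, i0 + k - 1L)
}

#' Extract period-sized unit fragments at seed occurrences
#'
#' One fragment of length `d` starts at every (possibly overlapping)
#' occurrence of the seed k-mer inside the PRR; the last fragment is
#' truncated at the PRR end.
#'
#' @inheritParams find_kseed
#' @param k_seed seed k-mer from [find_kseed()].
#' @return list with `fragments` (character vector) and `intervals`
#'   (data.frame `start`, `end`, 0-based half-open, absolute coordinates).
#' @export
extract_units <- function(seq, prr, k_seed, params) {
  region_seq <- substr(seq, prr$start + 1L, prr$end)
  d <- as.integer(prr$period)
  occ <- overlapping_matches(k_seed, region_seq)
  if (length(occ) < 2L) stop("insufficient units: seed k-mer occurs < 2 times")
  rlen <- nchar(region_seq)
  ends <- pmin(occ + d - 1L, rlen)
  frags <- substring(region_seq, occ, ends)
  list(fragments = frags,
       intervals = data.frame(start = prr$start + occ - 1L,
                              end = prr$start + ends))
}

# all (overlapping) occurrence starts of a fixed pattern, 1-based
overlapping_matches <- function(pattern, subject) {
  m <- nchar(pattern)
  L <- nchar(subject)
  if (L < m) return(integer(0))
  which(substring(subject, 1:(L - m + 1L), m:L) == pattern)
}

#' Per-column profile of a unit alignment
#'
#' For each alignment column: the letter/gap frequency table, the information
#' content `b = log2(|A|) - H` of the non-gap letter distribution (bits;
#' `|A|` = 4 or 20), the gap fraction, and the letter consistency
#' `l = b * (1 - gap fraction)` (gap-weighted bits). All-gap columns have
#' `b = 0`.
#'
#' @param alignment a [align_units()] result.
#' @return A `column_profile` object: list with `freq` (letters + `-` by
#'   columns frequency matrix, columns sum to 1) and `stats` (data.frame
#'   `b`, `gap_fraction`, `consistency`).
#' @export
column_profile <- function(alignment) {
  rows <- alignment$rows
  mat <- do.call(rbind, strsplit(rows, ""))
  nr <- nrow(mat); nc <- ncol(mat)
  absize <- if (alignment$alphabet == "nucleotide") 4L else 20L
  letters_seen <- sort(setdiff(unique(as.vector(mat)), "-"))
  lv <- c(letters_seen, "-")
  freq <- matrix(0, length(lv), nc, dimnames = list(lv, NULL))
  b <- gapf <- numeric(nc)
  for (j in seq_len(nc)) {
    tj <- table(factor(mat[, j], levels = lv))
    freq[, j] <- as.numeric(tj) / nr
    gaps <- tj[["-"]]
    gapf[j] <- gaps / nr
    lets <- tj[names(tj) != "-"]
    tot <- sum(lets)
    if (tot == 0) {
      b[j] <- 0
    } else {
      p <- lets[lets > 0] / tot
      b[j] <- max(0, log2(absize) + sum(p * log2(p)))
    }
  }
  structure(list(freq = freq,
                 stats = data.frame(b = b, gap_fraction = gapf,
                                    consistency = b * (1 - gapf))),
            class = "column_profile")
}

#' Circular punctuation of a unit alignment
#'
#' Columns with gap fraction above `q` are removed. The remaining columns are
#' treated as a ring (repeat units are circular permutations of the motif);
#' the longest circular run of nonconsensus columns (consistency `l < u`) is
#' located, and when its length exceeds `r` those columns are removed and the
#' alignment is rotated to begin immediately after the removed run. Otherwise
#' the original column order is kept. Equally long runs break toward the
#' earliest start in linear order.
#'
#' @param alignment a [align_units()] result.
#' @param profile the matching [column_profile()].
#' @param params a [default_params()] object (`q`, `u`, `r`).
#' @return A `unit_alignment` with attributes `rotated` (logical) and
#'   `removed_columns` (count).
#' @export
punctuate_circular <- function(alignment, profile, params) {
  st <- profile$stats
  keep <- which(st$gap_fraction <= params$q)
  if (!length(keep)) stop("degenerate motif: all columns gap-filtered")
  l <- st$consistency[keep]
  nc <- length(keep)
  low <- l < params$u
  run <- longest_circular_run(low)
  rot <- FALSE
  sel <- keep
  if (!is.null(run) && run$length > params$r) {
    if (run$length >= nc) stop("degenerate motif: no consensus columns remain")
    ring <- seq_len(nc)
    rm_idx <- ((run$start - 1L + seq_len(run$length) - 1L) %% nc) + 1L
    after <- ((run$start - 1L + run$length) %% nc) + 1L
    ord <- setdiff(((after - 1L + seq_len(nc) - 1L) %% nc) + 1L, rm_idx)
    sel <- keep[ord]
    rot <- TRUE
  }
  mat <- do.call(rbind, strsplit(alignment$rows, ""))
  rows <- apply(mat[, sel, drop = FALSE], 1L, paste, collapse = "")
  structure(list(rows = rows, alphabet = alignment$alphabet,
                 center = alignment$center),
            class = "unit_alignment",
            rotated = rot, removed_columns = if (rot) run$length else 0L,
            kept_columns = sel)
}

# longest run of TRUE on a ring; NULL when no TRUE. Returns start (1-based,
# in ring coordinates) and length (capped at the ring size).
longest_circular_run <- function(x) {
  n <- length(x)
  if (!any(x)) return(NULL)
  if (all(x)) return(list(start = 1L, length = n))
  xx <- c(x, x)
  r <- rle(xx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & starts <= n)
  lens <- pmin(r$lengths[cand], n)
  best <- cand[which.max(lens)]
  list(start = starts[best], length = min(r$lengths[best], n))
}

#' Representative motif, mapping and masked motif string
#'
#' The representative sequence takes the most frequent non-gap letter of each
#' (punctuated) alignment column, ties broken alphabetically. Representatives
#' no longer than the k-mer size are mapped by exact scanning of the PRR;
#' longer ones by an iterative masked local (Smith-Waterman) search with
#' short-query scoring (DNA match +1 / mismatch -3, gap 5/2; protein PAM30,
#' gap 9/1), keeping hits whose alignment length reaches 50% of the query
#' length or whose Karlin-Altschul E-value is 0.01 or less. The
#' mapped units rebuild a per-position letter frequency profile from which
#' the masked motif takes the most frequent letter per position, masking with
#' `*` every position whose top letter frequency is below 60%.
#'
#' @param alignment punctuated [align_units()] result.
#' @param seq full sequence (character scalar).
#' @param prr one PRR (with `start`, `end`).
#' @param params a [default_params()] object.
#' @return A `repeat_motif` object: list with `representative`,
#'   `masked_motif`, `logo` (letters-by-position frequency matrix over mapped
#'   units), `units` (data.frame `start`, `end`, 0-based half-open absolute
#'   intervals), `n_units`, `method` (`"exact_scan"` or `"local_search"`).
#' @export
representative_and_map <- function(alignment, seq, prr, params) {
  prof <- column_profile(alignment)
  rep_seq <- representative_sequence(prof)
  if (!nzchar(rep_seq)) stop("mapping failed: empty representative")
  region_seq <- substr(seq, prr$start + 1L, prr$end)
  ab_letters <- alphabet_letters(alignment$alphabet)
  m <- nchar(rep_seq)
  if (m <= params$k) {
    occ <- nonoverlapping_matches(rep_seq, region_seq)
    if (!length(occ)) stop("mapping failed: zero mapped units")
    units <- data.frame(start = prr$start + occ - 1L,
                        end = prr$start + occ - 1L + m)
    maps <- lapply(occ, function(o) {
      strsplit(substr(region_seq, o, o + m - 1L), "")[[1]]
    })
    method <- "exact_scan"
  } else {
    hits <- local_search(rep_seq, region_seq, alignment$alphabet)
    if (!length(hits)) stop("mapping failed: zero mapped units")
    ord <- order(vapply(hits, `[[`, numeric(1), "sstart"))
    hits <- hits[ord]
    units <- data.frame(start = prr$start + vapply(hits, `[[`, numeric(1), "sstart") - 1L,
                        end = prr$start + vapply(hits, `[[`, numeric(1), "send"))
    maps <- lapply(hits, `[[`, "qmap")
    method <- "local_search"
  }
  lv <- sort(unique(c(ab_letters, unlist(maps))))
  lv <- setdiff(lv, "-")
  logo <- matrix(0, length(lv), m, dimnames = list(lv, NULL))
  for (mp in maps) {
    ok <- which(mp != "-")
    if (length(ok)) {
      ix <- cbind(match(mp[ok], lv), ok)
      logo[ix] <- logo[ix] + 1
    }
  }
  nu <- length(maps)
  logo <- logo / nu
  top <- apply(logo, 2L, max)
  top_letter <- rownames(logo)[apply(logo, 2L, which.max)]  # ties: alphabetical
  masked <- ifelse(top >= 0.60, top_letter, "*")
  structure(list(representative = rep_seq,
                 masked_motif = paste(masked, collapse = ""),
                 logo = logo,
                 units = units, n_units = nu, method = method),
            class = "repeat_motif")
}

representative_sequence <- function(profile) {
  fr <- profile$freq
  lets <- setdiff(rownames(fr), "-")
  out <- character(0)
  for (j in seq_len(ncol(fr))) {
    v <- fr[lets, j]
    if (all(v == 0)) next                 # all-gap column carries no letter
    out <- c(out, lets[which.max(v)])     # rownames sorted: ties alphabetical
  }
  paste(out, collapse = "")
}

# greedy left-to-right non-overlapping exact matches, 1-based starts
nonoverlapping_matches <- function(pattern, subject) {
  occ <- overlapping_matches(pattern, subject)
  if (!length(occ)) return(integer(0))
  m <- nchar(pattern)
  out <- integer(0)
  last_end <- 0L
  for (o in occ) {
    if (o > last_end) {
      out <- c(out, o)
      last_end <- o + m - 1L
    }
  }
  out
}

#' @export
print.repeat_motif <- function(x, ...) {
  cat("repeat motif (", x$method, "): ", x$n_units, " units\n",
      "  representative: ", x$representative, "\n",
      "  masked motif:   ", x$masked_motif, "\n", sep = "")
  invisible(x)
}

#' Motif annotation for one PRR (phase 3 in one call)
#'
#' [find_kseed()], [extract_units()], [align_units()], [column_profile()],
#' [punctuate_circular()] and [representative_and_map()] chained.
#'
#' @inheritParams find_kseed
#' @inheritParams align_units
#' @return A `repeat_motif` object (see [representative_and_map()]).
#' @export
annotate_motif <- function(seq, prr, params,
                           backend = c("center_star", "mafft"),
                           mafft_path = "mafft") {
  ks <- find_kseed(seq, prr, params)
  un <- extract_units(seq, prr, ks, params)
  aln <- align_units(un$fragments, params$alphabet, backend = backend,
                     mafft_path = mafft_path)
  prof <- column_profile(aln)
  pun <- punctuate_circular(aln, prof, params)
  mot <- representative_and_map(pun, seq, prr, params)
  mot$k_seed <- ks
  mot
}
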