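# Synthetic repeat arrays with known ground truth: the test substrate for the
# whole screen. Substitution-only noise; spacers and flanks are random letters
# of the alphabet. Flank letters adjacent to the array are resampled so that
# the flank never extends the periodic pattern, keeping the ground-truth unit
# intervals exact by construction.

#' Spacer laws for synthetic repeat arrays
#'
#' @param size fixed spacer length (positions).
#' @param lo,hi inclusive bounds for uniformly drawn spacer lengths.
#' @return A spacer-law object used in [repeat_spec()].
#' @export
spacer_none <- function() structure(list(type = "none"), class = "spacer_law")

#' @rdname spacer_none
#' @export
spacer_fixed <- function(size) {
  stopifnot(size >= 0)
  structure(list(type = "fixed", size = as.integer(size)), class = "spacer_law")
}

#' @rdname spacer_none
#' @export
spacer_uniform <- function(lo, hi) {
  stopifnot(lo >= 0, hi >= lo)
  structure(list(type = "uniform", lo = as.integer(lo), hi = as.integer(hi)),
            class = "spacer_law")
}

spacer_label <- function(law) {
  switch(law$type,
         none = "none",
         fixed = sprintf("fixed(%d)", law$size),
         uniform = sprintf("uniform(%d,%d)", law$lo, law$hi))
}

#' Specification of a synthetic repeat array
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param copies number of repeat units (>= 2).
#' @param unit repeat unit as a letter string, or `NULL` to draw a random
#'   primitive unit of `unit_size` letters (primitive: not a whole-number
#'   power of a shorter string, so the intended period is unambiguous).
#' @param unit_size unit length when `unit` is `NULL`.
#' @param spacer a spacer law ([spacer_none()], [spacer_fixed()],
#'   [spacer_uniform()]); spacers separate consecutive units and carry random
#'   letters.
#' @param noise_rate per-position substitution probability in `[0, 1]`,
#'   applied independently to every position of every unit copy (spacers and
#'   flanks are left untouched).
#' @param flank_size random flank length added on each side; defaults to
#'   2000 (nucleotide) or 300 (amino acid).
#' @param keep_positions optional 1-based unit positions never mutated
#'   (conserved anchor residues).
#' @param seed integer seed; generation is fully reproducible.
#' @return A `repeat_spec` object.
#' @export
repeat_spec <- function(alphabet = c("nucleotide", "amino_acid"),
                        copies,
                        unit = NULL, unit_size = NULL,
                        spacer = spacer_none(),
                        noise_rate = 0,
                        flank_size = NULL,
                        keep_positions = NULL,
                        seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(copies >= 2, noise_rate >= 0, noise_rate <= 1,
            inherits(spacer, "spacer_law"))
  if (is.null(unit) && is.null(unit_size))
    stop("give either a unit string or a unit_size")
  if (!is.null(unit)) {
    unit <- toupper(unit)
    unit_size <- nchar(unit)
  }
  stopifnot(unit_size >= 1)
  if (is.null(flank_size))
    flank_size <- if (alphabet == "nucleotide") 2000L else 300L
  structure(list(alphabet = alphabet, copies = as.integer(copies),
                 unit = unit, unit_size = as.integer(unit_size),
                 spacer = spacer, noise_rate = noise_rate,
                 flank_size = as.integer(flank_size),
                 keep_positions = keep_positions,
                 seed = as.integer(seed)),
            class = "repeat_spec")
}

# TRUE when x (a character vector of letters) is not a power of a shorter unit
is_primitive_unit <- function(x) {
  u <- length(x)
  if (u == 1L) return(TRUE)
  for (p in seq_len(u %/% 2L)) {
    if (u %% p == 0L && all(x == rep_len(x[seq_len(p)], u))) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic repeat array with ground truth
#'
#' Assembles `flank + unit (+ spacer) + ... + unit + flank`, mutating each
#' unit copy independently at `noise_rate` per position (substitutions to a
#' uniformly chosen different letter). Fully reproducible from `spec$seed`.
#'
#' @param spec a [repeat_spec()].
#' @return list with `record` (list: `id`, `sequence`, `alphabet`) and `truth`
#'   (list: `region_start`, `region_end` 0-based half-open, `period` = modal
#'   distance between consecutive unit starts (ties toward the smaller
#'   value), `units` data.frame of unit intervals, `unit` = template string,
#'   `spacer_sizes`).
#' @export
generate_repeat <- function(spec) {
  stopifnot(inherits(spec, "repeat_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  ab <- alphabet_letters(spec$alphabet)
  u <- spec$unit_size
  if (is.null(spec$unit)) {
    repeat {
      tmpl <- sample(ab, u, replace = TRUE)
      if (is_primitive_unit(tmpl)) break
    }
  } else {
    tmpl <- strsplit(spec$unit, "")[[1]]
  }
  nsp <- spec$copies - 1L
  sp_sizes <- switch(spec$spacer$type,
                     none = rep(0L, nsp),
                     fixed = rep(spec$spacer$size, nsp),
                     uniform = sample(spec$spacer$lo:spec$spacer$hi, nsp,
                                      replace = TRUE))
  mutable <- setdiff(seq_len(u), spec$keep_positions)
  units <- vector("list", spec$copies)
  for (j in seq_len(spec$copies)) {
    cp <- tmpl
    if (spec$noise_rate > 0 && length(mutable)) {
      hit <- mutable[stats::runif(length(mutable)) < spec$noise_rate]
      for (p in hit) cp[p] <- sample(setdiff(ab, cp[p]), 1L)
    }
    units[[j]] <- cp
  }
  parts <- character(0)
  unit_starts <- integer(spec$copies)
  pos <- 0L
  for (j in seq_len(spec$copies)) {
    unit_starts[j] <- pos
    parts <- c(parts, paste(units[[j]], collapse = ""))
    pos <- pos + u
    if (j <= nsp && sp_sizes[j] > 0L) {
      parts <- c(parts, paste(sample(ab, sp_sizes[j], replace = TRUE),
                              collapse = ""))
      pos <- pos + sp_sizes[j]
    }
  }
  core <- paste(parts, collapse = "")
  fl <- spec$flank_size
  left <- right <- character(0)
  if (fl > 0L) {
    left <- sample(ab, fl, replace = TRUE)
    right <- sample(ab, fl, replace = TRUE)
    # do not let a flank letter extend the periodic pattern into the flank
    if (left[fl] == tmpl[u]) left[fl] <- sample(setdiff(ab, tmpl[u]), 1L)
    if (right[1L] == tmpl[1L]) right[1L] <- sample(setdiff(ab, tmpl[1L]), 1L)
  }
  sequence <- paste0(paste(left, collapse = ""), core,
                     paste(right, collapse = ""))
  start_diffs <- diff(unit_starts)
  period <- if (length(start_diffs)) {
    tab <- table(start_diffs)
    as.integer(names(tab)[which.max(tab)])  # ties: table is sorted ascending
  } else u
  list(record = list(id = sprintf("synthetic_%s_u%d_n%g_seed%d",
                                  spec$alphabet, u, spec$noise_rate, spec$seed),
                     sequence = sequence, alphabet = spec$alphabet),
       truth = list(region_start = fl, region_end = fl + nchar(core),
                    period = period,
                    units = data.frame(start = fl + unit_starts,
                                       end = fl + unit_starts + u),
                    unit = paste(tmpl, collapse = ""),
                    spacer_sizes = sp_sizes))
}

#' Noise-tolerance sweep over synthetic repeat arrays
#'
#' For every combination of unit size, spacer law and noise level, generates
#' `replicates` seeded arrays, runs phases 1 and 2 ([detect_prrs()]) with the
#' given parameters, and reports the fraction of replicates in which some
#' detected periodic repeat region overlaps the true array and has a period
#' within `period_tol` of the true period.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param unit_sizes integer vector of unit sizes.
#' @param spacer_laws list of spacer-law objects (see [spacer_none()]).
#' @param noise_grid numeric vector of substitution rates, ascending.
#' @param replicates replicates per cell.
#' @param copies unit copies per array (default 10).
#' @param seed master seed; per-replicate seeds are streamed from it and
#'   recorded per cell.
#' @param params screening parameters (default [default_params()] for the
#'   alphabet).
#' @param period_tol tolerated absolute period error (default 1).
#' @param stop_after_failures stop scanning higher noise levels after this
#'   many consecutive levels whose worst cell falls below `target`; `Inf`
#'   (default) evaluates the whole grid. Recovery is monotone non-increasing
#'   in noise, so truncation does not change [max_tolerated_noise()].
#' @param target recovery fraction used by the truncation rule (default 0.9).
#' @return data.frame with one row per (unit size, spacer, noise) cell:
#'   `alphabet`, `unit_size`, `spacer`, `noise`, `replicates`, `recovered`,
#'   `fraction`, `seed_base`.
#' @export
noise_tolerance_sweep <- function(alphabet, unit_sizes, spacer_laws,
                                  noise_grid, replicates,
                                  copies = 10L, seed = 1L,
                                  params = default_params(alphabet),
                                  period_tol = 1L,
                                  stop_after_failures = Inf,
                                  target = 0.9) {
  if (inherits(spacer_laws, "spacer_law")) spacer_laws <- list(spacer_laws)
  noise_grid <- sort(noise_grid)
  rows <- list()
  counter <- 0L
  consec_fail <- 0L
  for (noise in noise_grid) {
    level_min <- 1
    for (us in unit_sizes) {
      for (law in spacer_laws) {
        rec <- 0L
        seed_base <- derive_seed(seed, counter)
        for (rep_i in seq_len(replicates)) {
          counter <- counter + 1L
          spec <- repeat_spec(alphabet, copies = copies, unit_size = us,
                              spacer = law, noise_rate = noise,
                              seed = derive_seed(seed, counter))
          g <- generate_repeat(spec)
          if (period_recovered(g, params, period_tol)) rec <- rec + 1L
        }
        frac <- rec / replicates
        level_min <- min(level_min, frac)
        rows[[length(rows) + 1L]] <-
          data.frame(alphabet = alphabet, unit_size = us,
                     spacer = spacer_label(law), noise = noise,
                     replicates = replicates, recovered = rec,
                     fraction = frac, seed_base = seed_base)
      }
    }
    consec_fail <- if (level_min < target) consec_fail + 1L else 0L
    if (consec_fail > stop_after_failures) break
  }
  do.call(rbind, rows)
}

period_recovered <- function(g, params, period_tol) {
  prrs <- detect_prrs(g$record$sequence, params)
  if (nrow(prrs) == 0L) return(FALSE)
  ov <- pmin(prrs$end, g$truth$region_end) - pmax(prrs$start, g$truth$region_start)
  tp <- g$truth$period
  hit <- abs(prrs$period - tp) <= period_tol
  sp <- g$truth$spacer_sizes
  if (length(sp) && min(sp) != max(sp)) {
    # variable spacers: the realized unit-start distances span several values,
    # so any period within the 0.8-1.2 band of the modal distance counts
    hit <- hit | (prrs$period >= floor(0.8 * tp) &
                    prrs$period <= ceiling(1.2 * tp))
  }
  any(ov > 0 & hit)
}

derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 7919 + counter * 104729) %% 2147483647)
}

#' Largest tolerated noise level from a sweep table
#'
#' @param sweep a [noise_tolerance_sweep()] result.
#' @param target minimum recovery fraction (default 0.9).
#' @return The largest noise level at which every cell of the sweep reaches
#'   `target`, or `NA` if none does.
#' @export
max_tolerated_noise <- function(sweep, target = 0.9) {
  ok <- vapply(split(sweep$fraction, sweep$noise), function(f) all(f >= target),
               logical(1))
  lev <- as.numeric(names(ok))
  if (!any(ok)) return(NA_real_)
  max(lev[ok])
}
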