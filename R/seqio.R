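# FASTA / GenBank input, CDS protein extraction, annotated GenBank and TSV
# output. GenBank flat files are parsed with a purpose-built minimal reader
# (LOCUS, FEATURES with qualifiers, ORIGIN); original header and feature
# lines are kept verbatim so that annotation output round-trips the input.
# All in-memory coordinates are 0-based half-open; conversion to GenBank's
# 1-based inclusive intervals happens only at output.

#' Load sequence records from FASTA or GenBank
#'
#' One record per entry; letters are uppercased and the alphabet is detected
#' with [detect_alphabet()]. For GenBank nucleotide entries, every CDS
#' feature additionally yields an amino-acid record (the `/translation`
#' qualifier verbatim, or an in-frame translation with the standard code when
#' the qualifier is absent) carrying provenance: parent record id, locus tag,
#' genomic interval and strand.
#'
#' @param path input file.
#' @param format `"auto"` (default; sniffed from the first non-blank line),
#'   `"fasta"` or `"genbank"`.
#' @return list of `periscan_record` objects: `id`, `sequence`, `alphabet`,
#'   `provenance` (`NULL`, or list `parent_id`, `locus_tag`, `start`, `end`,
#'   `strand` for CDS-derived records), and for GenBank entries the parsed
#'   `features` plus raw lines enabling round-trip output.
#' @export
load_records <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read input file: ", path)
  if (format == "auto") {
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    head_lines <- head_lines[nzchar(trimws(head_lines))]
    if (!length(head_lines)) stop("empty input: no sequence entries in ", path)
    format <- if (startsWith(head_lines[1L], ">")) "fasta"
              else if (grepl("^LOCUS", head_lines[1L])) "genbank"
              else stop("cannot detect input format of ", path)
  }
  recs <- if (format == "fasta") read_fasta_records(path)
          else read_genbank_records(path)
  if (!length(recs)) stop("empty input: no sequence entries in ", path)
  recs
}

new_record <- function(id, sequence, alphabet = detect_alphabet(sequence),
                       provenance = NULL, features = NULL, raw = NULL) {
  stopifnot(nzchar(sequence))
  structure(list(id = id, sequence = toupper(sequence), alphabet = alphabet,
                 provenance = provenance, features = features, raw = raw),
            class = "periscan_record")
}

#' @export
print.periscan_record <- function(x, ...) {
  cat("record ", x$id, ": ", nchar(x$sequence), " ", x$alphabet, " letters",
      if (!is.null(x$provenance)) sprintf(" (CDS of %s)", x$provenance$parent_id),
      "\n", sep = "")
  invisible(x)
}

read_fasta_records <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  lapply(seq_along(ss), function(i) {
    id <- strsplit(names(ss)[i], "\\s+")[[1]][1L]
    new_record(id, as.character(ss[[i]]))
  })
}

# ---- GenBank flat-file reading ------------------------------------------

read_genbank_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(grepl("^//\\s*$", lines))
  if (!length(ends)) stop("no GenBank entries (missing // terminator) in ", path)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (e in seq_along(ends)) {
    entry <- lines[starts[e]:(ends[e] - 1L)]
    entry <- entry[cumsum(grepl("^LOCUS", entry)) > 0L]
    if (!length(entry)) next
    parsed <- parse_genbank_entry(entry)
    out <- c(out, list(parsed$record), parsed$proteins)
  }
  out
}

parse_genbank_entry <- function(entry) {
  locus_line <- entry[1L]
  id <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]][1L]
  fstart <- grep("^FEATURES", entry)[1L]
  ostart <- grep("^ORIGIN", entry)[1L]
  if (is.na(ostart)) stop("GenBank entry ", id, " has no ORIGIN block")
  seq_lines <- entry[(ostart + 1L):length(entry)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank entry ", id, " has an empty sequence")
  header_lines <- entry[seq_len((if (is.na(fstart)) ostart else fstart) - 1L)]
  feature_lines <- if (!is.na(fstart) && ostart > fstart + 1L)
    entry[(fstart + 1L):(ostart - 1L)] else character(0)
  feats <- parse_genbank_features(feature_lines)
  rec <- new_record(id, sequence, features = feats,
                    raw = list(header = header_lines,
                               features = feature_lines))
  proteins <- list()
  cds <- Filter(function(f) f$key == "CDS", feats)
  for (i in seq_along(cds)) {
    f <- cds[[i]]
    tag <- if (!is.null(f$qualifiers$locus_tag)) f$qualifiers$locus_tag
           else sprintf("CDS_%d", i)
    aa <- f$qualifiers$translation
    if (is.null(aa)) aa <- translate_cds(sequence, f$start, f$end, f$strand)
    if (is.null(aa) || !nzchar(aa)) next
    proteins[[length(proteins) + 1L]] <-
      new_record(paste(id, tag, sep = "|"), aa, alphabet = "amino_acid",
                 provenance = list(parent_id = id, locus_tag = tag,
                                   start = f$start, end = f$end,
                                   strand = f$strand))
  }
  list(record = rec, proteins = proteins)
}

parse_genbank_features <- function(lines) {
  if (!length(lines)) return(list())
  is_key <- grepl("^ {5}\\S", lines)
  idx <- which(is_key)
  feats <- list()
  for (j in seq_along(idx)) {
    from <- idx[j]
    to <- if (j < length(idx)) idx[j + 1L] - 1L else length(lines)
    block <- lines[from:to]
    key <- strsplit(trimws(block[1L]), "\\s+")[[1]][1L]
    rest <- sub("^ {5}\\S+\\s*", "", block[1L])
    body <- c(rest, trimws(block[-1L]))
    # location may continue over lines until the first qualifier
    qstart <- grep("^/", body)
    loc_txt <- paste(body[seq_len(if (length(qstart)) qstart[1L] - 1L
                                  else length(body))], collapse = "")
    quals <- parse_genbank_qualifiers(body[if (length(qstart))
      qstart[1L]:length(body) else integer(0)])
    loc <- parse_genbank_location(loc_txt)
    feats[[length(feats) + 1L]] <-
      list(key = key, start = loc$start, end = loc$end, strand = loc$strand,
           location = loc_txt, qualifiers = quals)
  }
  feats
}

parse_genbank_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  starts <- grep("^/", lines)
  quals <- list()
  for (j in seq_along(starts)) {
    from <- starts[j]
    to <- if (j < length(starts)) starts[j + 1L] - 1L else length(lines)
    txt <- paste(lines[from:to], collapse = "")
    nm <- sub("^/([^=]+)=?.*$", "\\1", txt)
    val <- if (grepl("=", txt, fixed = TRUE)) sub("^/[^=]+=", "", txt) else TRUE
    if (is.character(val)) {
      val <- gsub("^\"|\"$", "", val)
      if (nm == "translation") val <- gsub("\\s", "", val)
    }
    quals[[nm]] <- val
  }
  quals
}

# returns 0-based half-open interval and strand; join/order spans are
# collapsed to their overall extent
parse_genbank_location <- function(txt) {
  strand <- if (grepl("complement", txt)) "-" else "+"
  nums <- as.numeric(regmatches(txt, gregexpr("[0-9]+", txt))[[1]])
  if (!length(nums)) stop("cannot parse GenBank location: ", txt)
  list(start = as.integer(min(nums) - 1L), end = as.integer(max(nums)),
       strand = strand)
}

translate_cds <- function(sequence, start, end, strand) {
  nt <- substr(sequence, start + 1L, end)
  if (strand == "-")
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)  # drop partial codon
  if (nchar(nt) < 3L) return(NULL)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

# ---- GenBank / TSV output -----------------------------------------------

#' Write a GenBank file annotated with periodic repeat regions
#'
#' Each region becomes a `repeat_region` feature (1-based inclusive
#' coordinates) with qualifiers for the repeat period, periodicity score and
#' masked motif; mapped repeat units become `repeat_unit` sub-features. When
#' the record originated from a GenBank file its header and existing feature
#' lines are re-emitted verbatim, so writing with an empty region list
#' round-trips the input annotations.
#'
#' @param record a `periscan_record` (nucleotide).
#' @param regions data.frame of regions (`start`, `end` 0-based half-open,
#'   optionally `period`, `score`, `motif`) or an empty data.frame.
#' @param path output file.
#' @param motifs optional list of `repeat_motif` objects parallel to
#'   `regions`, providing unit sub-features.
#' @return `path`, invisibly.
#' @export
write_annotated_genbank <- function(record, regions, path, motifs = NULL) {
  L <- nchar(record$sequence)
  if (nrow(regions)) {
    if (any(regions$start < 0 | regions$end > L | regions$start >= regions$end))
      stop("repeat region out of record bounds")
  }
  header <- if (!is.null(record$raw)) record$raw$header else {
    c(sprintf("LOCUS       %-17s%d bp    %s     linear   UNK 01-JAN-1980",
              record$id, L,
              if (record$alphabet == "nucleotide") "DNA" else "PRT"),
      sprintf("DEFINITION  %s.", record$id))
  }
  feat <- if (!is.null(record$raw)) record$raw$features else {
    sprintf("     source          1..%d", L)
  }
  new_feats <- character(0)
  for (j in seq_len(nrow(regions))) {
    r <- regions[j, ]
    new_feats <- c(new_feats,
                   sprintf("     repeat_region   %d..%d", r$start + 1L, r$end))
    quals <- c(sprintf("/rpt_type=\"%s\"", "periodic"))
    if (!is.null(r$period) && !is.na(r$period))
      quals <- c(quals, sprintf("/note=\"repeat period %d; periodicity score %.3f\"",
                                as.integer(r$period), r$score))
    if (!is.null(r$motif) && !is.na(r$motif) && nzchar(r$motif))
      quals <- c(quals, sprintf("/rpt_unit_seq=\"%s\"", r$motif))
    new_feats <- c(new_feats, wrap_qualifiers(quals))
    if (!is.null(motifs) && length(motifs) >= j && !is.null(motifs[[j]])) {
      un <- motifs[[j]]$units
      for (i in seq_len(nrow(un))) {
        new_feats <- c(new_feats,
                       sprintf("     repeat_unit     %d..%d",
                               un$start[i] + 1L, un$end[i]),
                       wrap_qualifiers(sprintf("/note=\"unit %d of %d\"",
                                               i, nrow(un))))
      }
    }
  }
  origin <- format_origin(record$sequence)
  writeLines(c(header, "FEATURES             Location/Qualifiers",
               feat, new_feats, "ORIGIN", origin, "//"), path)
  invisible(path)
}

wrap_qualifiers <- function(quals, width = 58L) {
  out <- character(0)
  for (q in quals) {
    while (nchar(q) > width) {
      out <- c(out, paste0(strrep(" ", 21L), substr(q, 1L, width)))
      q <- substr(q, width + 1L, nchar(q))
    }
    out <- c(out, paste0(strrep(" ", 21L), q))
  }
  out
}

format_origin <- function(sequence) {
  L <- nchar(sequence)
  starts <- seq(1L, L, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, character(1))
}

#' Repeat-region intervals recorded in a GenBank-derived record
#'
#' @param record a `periscan_record` loaded from GenBank.
#' @return data.frame `start`, `end` (0-based half-open) of `repeat_region`
#'   features.
#' @export
genbank_repeat_regions <- function(record) {
  feats <- Filter(function(f) f$key == "repeat_region",
                  record$features %||% list())
  data.frame(start = vapply(feats, `[[`, numeric(1), "start"),
             end = vapply(feats, `[[`, numeric(1), "end"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a protein-coordinate interval onto its parent nucleotide record
#'
#' @param provenance the `provenance` element of a CDS-derived record.
#' @param start,end 0-based half-open interval in protein coordinates.
#' @return list `start`, `end` (0-based half-open genomic interval),
#'   `strand`.
#' @export
map_protein_interval <- function(provenance, start, end) {
  stopifnot(!is.null(provenance))
  if (provenance$strand == "+") {
    list(start = provenance$start + 3L * start,
         end = provenance$start + 3L * end,
         strand = "+")
  } else {
    list(start = provenance$end - 3L * end,
         end = provenance$end - 3L * start,
         strand = "-")
  }
}
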