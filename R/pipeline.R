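# End-to-end orchestration: phases 1-3 over every record of an input file,
# descriptor tables, CRISPR candidate filtering and annotated output.

#' Scan one sequence for periodic repeats (all three phases)
#'
#' @param seq character scalar sequence.
#' @param params a [default_params()] object; defaults to the alphabet's
#'   published parameter set.
#' @param record_id id used in the descriptor table.
#' @return list with `hrrs`, `prrs` (phase 1-2 data.frames), `motifs` (list
#'   of `repeat_motif` or `NULL`, parallel to `prrs` rows) and `table`
#'   (descriptor data.frame, one row per PRR; PRRs whose motif step fails are
#'   kept with `NA` motif columns).
#' @export
scan_sequence <- function(seq, params = NULL, record_id = "seq") {
  seq <- toupper(seq)
  if (is.null(params)) params <- default_params(detect_alphabet(seq))
  track <- cumulative_kmer_scores(seq, params)
  hrrs <- merge_to_hrrs(extract_ckpas(track), track)
  prrs <- detect_prrs_from_hrrs(seq, hrrs, params)
  motifs <- vector("list", nrow(prrs))
  rows <- list()
  for (j in seq_len(nrow(prrs))) {
    mot <- tryCatch(annotate_motif(seq, prrs[j, ], params),
                    error = function(e) NULL)
    motifs[[j]] <- mot
    rows[[j]] <- repeat_descriptor(prrs[j, ], mot, params$alphabet, record_id)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else empty_descriptor_table()
  list(hrrs = hrrs, prrs = prrs, motifs = motifs, table = tab)
}

detect_prrs_from_hrrs <- function(seq, hrrs, params) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_height = numeric(0), period = integer(0),
                      score = numeric(0))
  if (nrow(hrrs) == 0L) return(empty)
  out <- lapply(seq_len(nrow(hrrs)), function(j) {
    pm <- ppm_marginal_fast(seq, hrrs[j, ], params)
    if (!any(pm$marginal > 0)) return(NULL)
    promote_to_prr(hrrs[j, ], pm, params)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

empty_descriptor_table <- function() {
  data.frame(record = character(0), start = integer(0), end = integer(0),
             alphabet = character(0), period = integer(0), score = numeric(0),
             n_units = integer(0), unit_size = numeric(0),
             interspace = numeric(0), motif = character(0),
             stringsAsFactors = FALSE)
}

#' Run the full screen over an input file
#'
#' Loads all entries (nucleotide records and, for GenBank input, their
#' CDS-derived proteins), runs the three screening phases on each, and
#' writes: an annotated GenBank file per nucleotide record
#' (`<prefix>_<id>.gb`; protein repeats are mapped back to genomic
#' coordinates through their CDS), a descriptor TSV (`<prefix>_prrs.tsv`)
#' and a CRISPR-candidate TSV (`<prefix>_crispr.tsv`). Failures confined to
#' one entry are logged and skipped.
#'
#' @param input path to a FASTA or GenBank file.
#' @param out_prefix output path prefix; `NULL` suppresses file output.
#' @param dna_params,protein_params parameter overrides (default:
#'   [default_params()] per alphabet).
#' @param crispr_filter apply [is_crispr_candidate()] to nucleotide repeats
#'   (default TRUE).
#' @param verbose print per-entry progress.
#' @return list with `table` (all descriptors), `crispr` (candidate subset),
#'   `n_records`, `counts` (PRRs per alphabet) and `files` (paths written).
#' @export
run_pipeline <- function(input, out_prefix = NULL,
                         dna_params = default_params("nucleotide"),
                         protein_params = default_params("amino_acid"),
                         crispr_filter = TRUE, verbose = FALSE) {
  records <- load_records(input)
  tabs <- list()
  scans <- list()
  for (rec in records) {
    params <- if (rec$alphabet == "nucleotide") dna_params else protein_params
    res <- tryCatch(scan_sequence(rec$sequence, params, rec$id),
                    error = function(e) {
                      warning("entry ", rec$id, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    scans[[rec$id]] <- res
    tabs[[rec$id]] <- res$table
    if (verbose)
      message(sprintf("%s: %d HRR, %d PRR (%s)", rec$id, nrow(res$hrrs),
                      nrow(res$prrs), rec$alphabet))
  }
  table <- if (length(tabs)) do.call(rbind, tabs) else empty_descriptor_table()
  rownames(table) <- NULL
  dna_tab <- table[table$alphabet == "nucleotide", , drop = FALSE]
  crispr <- if (nrow(dna_tab) && crispr_filter)
    dna_tab[is_crispr_candidate(dna_tab), , drop = FALSE] else
    empty_descriptor_table()
  files <- character(0)
  if (!is.null(out_prefix)) {
    files <- write_pipeline_outputs(records, scans, table, crispr, out_prefix)
  }
  list(table = table, crispr = crispr, n_records = length(records),
       counts = c(nucleotide = sum(table$alphabet == "nucleotide"),
                  amino_acid = sum(table$alphabet == "amino_acid")),
       files = files)
}

write_pipeline_outputs <- function(records, scans, table, crispr, prefix) {
  files <- character(0)
  prr_path <- paste0(prefix, "_prrs.tsv")
  utils::write.table(table, prr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, prr_path)
  cr_path <- paste0(prefix, "_crispr.tsv")
  utils::write.table(crispr, cr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, cr_path)
  by_id <- stats::setNames(records, vapply(records, `[[`, character(1), "id"))
  for (rec in records) {
    if (rec$alphabet != "nucleotide" || !is.null(rec$provenance)) next
    res <- scans[[rec$id]]
    if (is.null(res)) next
    regions <- res$prrs
    motifs <- res$motifs
    regions$motif <- vapply(motifs, function(m)
      if (is.null(m)) NA_character_ else m$masked_motif, character(1))
    # protein repeats of this record's CDS translations, mapped to genome
    for (other in names(scans)) {
      orec <- by_id[[other]]
      if (is.null(orec$provenance) || orec$provenance$parent_id != rec$id) next
      pres <- scans[[other]]
      for (j in seq_len(nrow(pres$prrs))) {
        gi <- map_protein_interval(orec$provenance,
                                   pres$prrs$start[j], pres$prrs$end[j])
        regions <- rbind(regions,
                         data.frame(start = gi$start, end = gi$end,
                                    peak_height = pres$prrs$peak_height[j],
                                    period = pres$prrs$period[j],
                                    score = pres$prrs$score[j],
                                    motif = if (!is.null(pres$motifs[[j]]))
                                      pres$motifs[[j]]$masked_motif
                                    else NA_character_))
        motifs <- c(motifs, list(NULL))
      }
    }
    gb_path <- paste0(prefix, "_", gsub("[^A-Za-z0-9._-]", "_", rec$id), ".gb")
    write_annotated_genbank(rec, regions, gb_path, motifs)
    files <- c(files, gb_path)
  }
  files
}
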