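# Structured output: GFF3 for intervals (via rtracklayer, 1-based inclusive
# per the standard), a TSV array summary and a JSON overview. Field order is
# deterministic and re-reading the GFF3 reproduces the intervals exactly.

.partition_granges <- function(partition, arrays, seqname) {
  rows <- list()
  add <- function(type, start0, end0, score = NA_real_, attrs = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, start = start0 + 1L, end = end0, score = score,
      name = if (is.null(attrs)) type else attrs, stringsAsFactors = FALSE)
  }
  if (!is.null(partition)) {
    add("ETAS_domain", partition$etas[["start"]], partition$etas[["end"]])
    add("CCR_domain", partition$ccr[["start"]], partition$ccr[["end"]])
    add("CSB_domain", partition$csb[["start"]], partition$csb[["end"]])
    h <- partition$hits
    for (i in seq_len(nrow(h)))
      add("motif_hit", h$start[i], h$end[i], h$mismatches[i], h$motif[i])
  }
  for (a in arrays)
    add("tandem_array", a$start, a$end, a$mean_identity,
        sprintf("unit%dx%d", a$unit_length, a$copy_number))
  if (length(rows) == 0L) return(GenomicRanges::GRanges())
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    type = df$type, score = df$score, Name = df$name)
  gr
}

#' Write a structural-annotation report
#'
#' Emits three sibling files: `<path>.gff3` with the domain, motif-hit and
#' tandem-array intervals (1-based inclusive, per the GFF3 standard),
#' `<path>.tsv` with one row per tandem array (header only when no arrays
#' were found), and `<path>.json` with the rearrangement call and domain
#' summary. Re-reading the GFF3 with [read_report_gff3()] reproduces the
#' intervals exactly.
#'
#' @param partition a `cr_partition` from [partition_cr()], or `NULL`.
#' @param arrays list of tandem arrays from [find_tandem_repeats()].
#' @param call a `rearrangement_call` from [classify_rearrangement()], or
#'   `NULL`.
#' @param path output path prefix (no extension).
#' @param seqname sequence name used in the GFF3.
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(partition, arrays, call, path, seqname = "CR") {
  gff <- paste0(path, ".gff3")
  tsv <- paste0(path, ".tsv")
  jsn <- paste0(path, ".json")

  gr <- .partition_granges(partition, arrays, seqname)
  rtracklayer::export(gr, gff, format = "gff3")

  tab <- data.frame(start = integer(), end = integer(),
                    unit_length = integer(), copy_number = integer(),
                    tail_length = integer(), mean_identity = numeric(),
                    consensus = character(), stringsAsFactors = FALSE)
  for (a in arrays)
    tab <- rbind(tab, data.frame(start = a$start, end = a$end,
                                 unit_length = a$unit_length,
                                 copy_number = a$copy_number,
                                 tail_length = a$tail_length,
                                 mean_identity = round(a$mean_identity, 4),
                                 consensus = a$consensus,
                                 stringsAsFactors = FALSE))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    rearrangement = if (is.null(call)) NULL else list(
      type = call$type,
      events = lapply(call$events, function(e)
        list(kind = e$kind, labels = e$labels)),
      flags = call$flags),
    cr_partition = if (is.null(partition)) NULL else list(
      etas = unname(partition$etas), ccr = unname(partition$ccr),
      csb = unname(partition$csb),
      domain_at_content = as.list(partition$domain_at_content),
      boundary_evidence = as.list(partition$boundary_evidence)),
    n_tandem_arrays = length(arrays))
  jsonlite::write_json(summary, jsn, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(gff3 = gff, tsv = tsv, json = jsn))
}

#' Re-read a report GFF3
#'
#' @param path a `.gff3` file written by [write_report()].
#' @return data.frame with `type`, `start`, `end` (0-based half-open,
#'   converted back from GFF3 1-based inclusive), `name`, `score`.
#' @export
read_report_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    type = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
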