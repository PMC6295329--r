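# Minimal GenBank flat-file I/O for annotated mitogenomes.
#
# Coordinates are converted at this boundary: GenBank is 1-based inclusive,
# everything internal is 0-based half-open. Features written by
# write_genbank() round-trip bit-identically through read_genbank().

.GB_FEATURE_KEYS <- c("gene", "tRNA", "rRNA", "CDS", "D-loop", "rep_origin",
                      "misc_feature")

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses the LOCUS line (length, circular topology), the feature table and
#' the ORIGIN sequence block. Gene, tRNA, rRNA, CDS, D-loop, rep_origin and
#' misc_feature entries are mapped into the controlled vocabulary with
#' [normalize_label()]; for tRNAs the `/product`, `/note` and `/anticodon`
#' qualifiers are combined so that serine/leucine codon families can be
#' resolved. Unmapped labels are retained with their raw text and flagged
#' unknown. `join()` locations (features spanning the circular origin) are
#' split into one feature row per span. When a gene is annotated both as a
#' `gene` and as a `CDS`/`tRNA`/`rRNA` with the same normalized label and
#' overlapping span, a single feature is kept.
#'
#' @param path path to a GenBank flat file.
#' @return a [mito_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("parse error: empty file: ", path)

  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) > 0L && grepl("circular", locus[1], ignore.case = TRUE)
  id <- if (length(locus) > 0L) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                         "\\s+")[[1]][1] else basename(path)
  acc <- grep("^ACCESSION", lines, value = TRUE)
  source_id <- if (length(acc) > 0L) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (is.na(a) || !nzchar(a)) id else a
  } else id

  # ORIGIN block -> residues
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) stop("parse error: no ORIGIN sequence block in ", path)
  seq_lines <- lines[(oi[1] + 1L):length(lines)]
  endi <- grep("^//", seq_lines)
  if (length(endi) > 0L) seq_lines <- seq_lines[seq_len(endi[1] - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(residues)) stop("parse error: ORIGIN block contains no sequence")

  feats <- .parse_gb_features(lines)
  if (nrow(feats) == 0L)
    stop("empty-annotation error: no recognizable features in ", path)
  feats <- .dedupe_gb_features(feats)
  if (all(feats$label == "unknown"))
    stop("empty-annotation error: no features mapped into the vocabulary in ",
         path)

  mito_genome(nuc_sequence(id, residues, circular = circular), feats,
              source_id = source_id)
}

.parse_gb_features <- function(lines) {
  fi <- grep("^FEATURES", lines)
  if (length(fi) == 0L) return(data.frame())
  oi <- grep("^ORIGIN", lines)
  stopi <- if (length(oi) > 0L) oi[1] - 1L else length(lines)
  block <- lines[(fi[1] + 1L):stopi]

  entries <- list()
  cur <- NULL
  for (ln in block) {
    key_m <- regmatches(ln, regexec("^ {1,10}([A-Za-z_'-]+) +(\\S.*)$", ln))[[1]]
    is_key <- length(key_m) == 3L && !startsWith(trimws(ln), "/")
    if (is_key) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      cur <- list(key = key_m[2], loc = key_m[3], quals = character())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (length(cur$quals) == 0L) cur$loc <- paste0(cur$loc, txt)
      else cur$quals[length(cur$quals)] <-
             paste(cur$quals[length(cur$quals)], txt)
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  rows <- list()
  for (e in entries) {
    if (!(e$key %in% .GB_FEATURE_KEYS) || e$key == "source") next
    spans <- .parse_gb_location(e$loc)
    if (is.null(spans)) next
    label <- .gb_feature_label(e)
    for (r in seq_len(nrow(spans))) {
      rows[[length(rows) + 1L]] <- data.frame(
        key = e$key, label = label$token,
        start = spans$start[r], end = spans$end[r],
        strand = if (spans$complement[r]) "L" else "H",
        raw = label$raw, unknown = !(label$token %in% MITO_VOCAB),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

.parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  complement <- grepl("^complement\\(", loc)
  loc <- gsub("^complement\\(|\\)$", "", loc)
  join <- grepl("^(join|order)\\(", loc)
  loc <- gsub("^(join|order)\\(|\\)$", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3L) {
      c(as.integer(m[2]) - 1L, as.integer(m[3]))   # 1-based incl -> 0-based half-open
    } else if (grepl("^\\d+$", p)) {
      v <- as.integer(p); c(v - 1L, v)
    } else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(NULL)
  data.frame(start = vapply(out, `[`, integer(1), 1L),
             end = vapply(out, `[`, integer(1), 2L),
             complement = complement)
}

.gb_qual <- function(e, name) {
  pat <- paste0("^/", name, "=")
  hit <- grep(pat, e$quals, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  gsub("^\"|\"$", "", sub(pat, "", hit[1]))
}

.gb_feature_label <- function(e) {
  if (e$key == "D-loop") {
    raw <- "D-loop"
  } else if (e$key == "rep_origin") {
    raw <- .gb_qual(e, "note")
    if (is.na(raw)) raw <- "rep_origin"
  } else {
    parts <- c(.gb_qual(e, "gene"), .gb_qual(e, "product"),
               .gb_qual(e, "note"), .gb_qual(e, "anticodon"),
               .gb_qual(e, "standard_name"))
    parts <- parts[!is.na(parts)]
    raw <- if (length(parts) > 0L) parts[1] else e$key
  }
  # try the primary label first, then with disambiguating qualifiers appended
  token <- normalize_label(raw)
  if (token %in% c("trnS", "trnL", "unknown")) {
    quals <- c(.gb_qual(e, "product"), .gb_qual(e, "note"),
               .gb_qual(e, "anticodon"))
    quals <- quals[!is.na(quals)]
    cand <- c(quals, paste(raw, quals))
    for (x in cand) {
      t2 <- normalize_label(x)
      if (!(t2 %in% c("trnS", "trnL", "unknown"))) { token <- t2; break }
    }
  }
  if (e$key == "rep_origin" && token == "unknown") token <- "OL"
  list(token = token, raw = raw)
}

.dedupe_gb_features <- function(feats) {
  # prefer the typed feature (tRNA/rRNA/CDS/D-loop/rep_origin) over the bare
  # gene entry when both describe the same normalized label and overlap
  keep <- rep(TRUE, nrow(feats))
  typed <- feats$key != "gene"
  for (i in which(feats$key == "gene")) {
    ov <- typed & feats$label == feats$label[i] &
      feats$start < feats$end[i] & feats$end > feats$start[i]
    if (any(ov)) keep[i] <- FALSE
  }
  feats <- feats[keep, , drop = FALSE]
  # collapse exact duplicates
  dup <- duplicated(feats[, c("label", "start", "end", "strand")])
  feats <- feats[!dup, , drop = FALSE]
  feats$key <- NULL
  rownames(feats) <- NULL
  feats
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a deterministic record (fixed field order, 60-residue ORIGIN lines)
#' that [read_genbank()] parses back into an identical feature table.
#' Protein-coding genes and rRNAs are written as `gene` features, tRNAs as
#' `tRNA`, the control region as `D-loop` and the light-strand origin as
#' `rep_origin`.
#'
#' @param g a [mito_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  stopifnot(inherits(g, "mito_genome"))
  n <- seq_length(g$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (g$sequence$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s     UNA",
                     g$sequence$id, n, topo), con)
  writeLines(sprintf("DEFINITION  %s mitochondrial DNA.", g$source_id), con)
  writeLines(sprintf("ACCESSION   %s", g$source_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  writeLines(sprintf("                     /organism=\"%s\"", g$source_id), con)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    lab <- f$label[i]
    if (lab == "CR") {
      writeLines(sprintf("     D-loop          %s", loc), con)
      writeLines("                     /note=\"control region\"", con)
    } else if (lab == "OL") {
      writeLines(sprintf("     rep_origin      %s", loc), con)
      writeLines("                     /note=\"origin of L-strand replication\"", con)
    } else if (grepl("^trn", lab)) {
      writeLines(sprintf("     tRNA            %s", loc), con)
      writeLines(sprintf("                     /product=\"%s\"", lab), con)
    } else if (lab %in% c("rrnS", "rrnL")) {
      writeLines(sprintf("     rRNA            %s", loc), con)
      writeLines(sprintf("                     /product=\"%s\"", lab), con)
    } else {
      key <- if (f$unknown[i]) "misc_feature" else "gene"
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf("                     /gene=\"%s\"",
                         if (f$unknown[i]) f$raw[i] else lab), con)
    }
  }
  writeLines("ORIGIN", con)
  res <- tolower(g$sequence$residues)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(res, p, min(p + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
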