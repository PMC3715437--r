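#' Read a FASTA file of protein sequences
#'
#' Wraps [Biostrings::readBStringSet()] with the validation contract the
#' pipeline needs: identifiers are the first whitespace-delimited token of
#' each header, sequences are uppercased with gap and whitespace
#' characters stripped, record order is preserved, and duplicate
#' identifiers or residues outside the accepted alphabet (20 amino acids
#' plus X/B/Z/U) are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = identifiers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate FASTA identifier '%s'", dup[1]), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[-.* \t]", "", seqs)
  names(seqs) <- ids
  for (i in seq_along(seqs)) check_sequence_alphabet(seqs[[i]], ids[i])
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an IUPred/ANCHOR-style per-residue score track
#'
#' The plain-text dialect: lines starting with `#` are comments; data
#' lines are whitespace-separated, either three columns
#' (`index amino_acid score`, IUPred style) or two columns
#' (`index score`). Indices must be 1-based and consecutive; scores must
#' lie in \[0, 1\].
#'
#' @param path Path to the track file.
#' @param kind `"disorder"` or `"binding"`.
#' @return A [score_track()]; residue letters are retained when present.
#' @export
read_score_track <- function(path, kind = c("disorder", "binding")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("no data lines in %s", path), call. = FALSE)
  fields <- strsplit(lines, "\\s+")
  ncol <- vapply(fields, length, 1L)
  if (any(!(ncol %in% c(2L, 3L)))) {
    stop(sprintf("line %d of %s: expected 2 or 3 whitespace-separated fields",
                 which(!(ncol %in% c(2L, 3L)))[1], path), call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
  if (any(is.na(idx))) {
    stop(sprintf("non-integer residue index on line %d of %s",
                 which(is.na(idx))[1], path), call. = FALSE)
  }
  gap <- which(idx != seq_along(idx))
  if (length(gap)) {
    stop(sprintf("non-consecutive residue index at line %d of %s (found %d, expected %d)",
                 gap[1], path, idx[gap[1]], gap[1]), call. = FALSE)
  }
  has_res <- all(ncol == 3L)
  scores <- suppressWarnings(as.numeric(
    vapply(seq_along(fields), function(i) fields[[i]][ncol[i]], "")))
  if (any(is.na(scores))) {
    stop(sprintf("non-numeric score on line %d of %s",
                 which(is.na(scores))[1], path), call. = FALSE)
  }
  residues <- if (has_res) vapply(fields, `[`, "", 2L) else NULL
  score_track(scores, kind = kind, residues = residues)
}

#' Write a score track in the 3-column plain-text dialect
#'
#' @param track A [score_track()].
#' @param path Output path.
#' @param sequence Optional sequence supplying the residue column when the
#'   track itself carries none.
#' @param digits Printed score precision.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path, sequence = NULL, digits = 4L) {
  stopifnot(inherits(track, "score_track"))
  res <- track$residues
  if (is.null(res) && !is.null(sequence)) {
    res <- strsplit(toupper(sequence), "")[[1]]
  }
  n <- length(track$scores)
  lines <- if (is.null(res)) {
    sprintf("%d %.*f", seq_len(n), digits, track$scores)
  } else {
    sprintf("%d %s %.*f", seq_len(n), res, digits, track$scores)
  }
  writeLines(c(sprintf("# kind: %s", track$kind), lines), path)
  invisible(path)
}

#' Read a protein annotation table
#'
#' TSV with header and columns `accession`, `name`, `species`,
#' `functional_group`, `routes` (semicolon-separated route labels) and
#' `tm_segments` (semicolon-separated `start-end` tokens). Sequences are
#' attached by accession from a FASTA-derived vector; every record is
#' validated against the protein-record invariants, and unknown group or
#' route tokens are rejected.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Named character vector from [read_fasta()].
#' @return List of [protein_record()] objects, in file order.
#' @export
read_annotation_table <- function(path, sequences) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  tab <- read.delim(path, colClasses = "character", na.strings = NULL,
                    check.names = FALSE)
  needed <- c("accession", "name", "species", "functional_group",
              "routes", "tm_segments")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("annotation table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    acc <- tab$accession[i]
    if (!acc %in% names(sequences)) {
      stop(sprintf("row %d: accession '%s' absent from FASTA", i, acc),
           call. = FALSE)
    }
    routes <- strsplit(tab$routes[i], ";", fixed = TRUE)[[1]]
    routes <- trimws(routes[nzchar(trimws(routes))])
    tm <- parse_segment_field(tab$tm_segments[i], sprintf("(row %d)", i))
    records[[i]] <- tryCatch(
      protein_record(acc, sequences[[acc]], name = tab$name[i],
                     species = tab$species[i],
                     functional_group = tab$functional_group[i],
                     routes = routes, tm_segments = tm),
      error = function(e) {
        stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
  }
  records
}

#' Write an annotation table for a list of protein records
#'
#' Inverse of [read_annotation_table()] (sequences go to FASTA
#' separately).
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(records, path) {
  tab <- data.frame(
    accession = vapply(records, `[[`, "", "accession"),
    name = vapply(records, `[[`, "", "name"),
    species = vapply(records, `[[`, "", "species"),
    functional_group = vapply(records, `[[`, "", "functional_group"),
    routes = vapply(records, function(r) paste(r$routes, collapse = ";"), ""),
    tm_segments = vapply(records, function(r) format_segment_field(r$tm_segments), ""))
  write_table(tab, path)
}

#' Write a report table as TSV
#'
#' Writes a header plus one line per row, in the given (or native) column
#' order. Floating-point cells are rendered with two decimals, matching
#' the convention of the published summary tables; columns named in
#' `percent_cols` are first multiplied by 100 (so a stored fraction
#' 0.6008 prints as `60.08`). Output is deterministic: re-writing
#' identical rows yields a byte-identical file.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param columns Column order (default: as given).
#' @param percent_cols Names of fraction-valued columns to print as
#'   percentages.
#' @param digits Decimal places for numeric cells.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, columns = names(rows),
                        percent_cols = character(), digits = 2L) {
  stopifnot(is.data.frame(rows))
  missing <- setdiff(columns, names(rows))
  if (length(missing)) {
    stop(sprintf("rows lack column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- rows[, columns, drop = FALSE]
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      if (nm %in% percent_cols) col <- col * 100
      out[[nm]] <- formatC(col, format = "f", digits = digits)
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot open '%s' for writing", path), call. = FALSE)
  })
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction edge table
#'
#' TSV with columns `source_accession`, `partner_id`, `partner_sequence`,
#' `confidence`. Each row is one pre-filter interaction edge between a
#' trafficking protein and a candidate partner.
#'
#' @param path Path to the edge TSV.
#' @return Data frame of validated edges.
#' @export
read_interaction_edges <- function(path) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  needed <- c("source_accession", "partner_id", "partner_sequence", "confidence")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("edge table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab$confidence <- as.numeric(tab$confidence)
  if (any(is.na(tab$confidence) | tab$confidence < 0 | tab$confidence > 1)) {
    stop("confidence must be a number in [0,1]", call. = FALSE)
  }
  if (any(!nzchar(tab$partner_sequence))) {
    stop("partner_sequence must be non-empty", call. = FALSE)
  }
  tab
}

#' Read a per-protein off-pathway interaction report
#'
#' TSV with columns `gene_name`, `accession`, `route`, `n_offpathway`,
#' `length`, `disorder_content`, `n_ldr30`, `n_dbr`, `dbr_residue_ratio`,
#' `functional_group` — the shape of the published per-protein moonlighting
#' report, consumable directly by [offpathway_totals()]. Percentage
#' columns are stored on the 0-100 scale they are printed on.
#'
#' @param path Path to the report TSV.
#' @return Data frame with typed columns.
#' @export
read_interaction_report <- function(path) {
  tab <- read.delim(path, check.names = FALSE,
                    colClasses = c(route = "character"))
  needed <- c("gene_name", "accession", "route", "n_offpathway",
              "functional_group")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("interaction report lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab$n_offpathway <- as.integer(tab$n_offpathway)
  if (any(is.na(tab$n_offpathway) | tab$n_offpathway < 0)) {
    stop("n_offpathway must be a non-negative integer", call. = FALSE)
  }
  tab
}

#' Read a tissue-specific-exon table
#'
#' TSV with columns `gene`, `transcript_id`, `switch_score`, `route`
#' (semicolon-separated for exons shared between routes),
#' `functional_group`, `coding` (TRUE/FALSE) and either `protein_span`
#' (`start-end`, direct input mode) or `cds_exon_lengths`
#' (semicolon-separated nucleotide counts) plus `tse_exon_index`.
#'
#' @param path Path to the TSE TSV.
#' @return Data frame with parsed columns; `protein_start`/`protein_end`
#'   are `NA` for rows that need [map_exon_to_protein()].
#' @export
read_tse_table <- function(path) {
  tab <- read.delim(path, colClasses = "character", na.strings = c("NA", ""),
                    check.names = FALSE)
  needed <- c("gene", "transcript_id", "switch_score", "route",
              "functional_group", "coding")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("TSE table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab$switch_score <- as.numeric(tab$switch_score)
  if (any(is.na(tab$switch_score) | tab$switch_score < 0 |
          tab$switch_score > 1)) {
    stop("switch_score must be a number in [0,1]", call. = FALSE)
  }
  tab$coding <- toupper(tab$coding) %in% c("TRUE", "T", "1", "YES")
  tab$protein_start <- NA_integer_
  tab$protein_end <- NA_integer_
  if ("protein_span" %in% names(tab)) {
    for (i in which(!is.na(tab$protein_span))) {
      seg <- parse_segment_field(tab$protein_span[i], sprintf("(row %d)", i))
      if (nrow(seg) != 1L) {
        stop(sprintf("row %d: protein_span must be a single interval", i),
             call. = FALSE)
      }
      tab$protein_start[i] <- seg$start
      tab$protein_end[i] <- seg$end
    }
  }
  has_span <- !is.na(tab$protein_start)
  has_exon <- if (all(c("cds_exon_lengths", "tse_exon_index") %in% names(tab)))
    !is.na(tab$cds_exon_lengths) & !is.na(tab$tse_exon_index) else
    rep(FALSE, nrow(tab))
  bad <- which(has_span == has_exon)
  if (length(bad)) {
    stop(sprintf("row %d: exactly one of protein_span or cds_exon_lengths + tse_exon_index must be present",
                 bad[1]), call. = FALSE)
  }
  tab
}

#' Read an ortholog pair table
#'
#' TSV with columns `human_accession` and `yeast_accession`.
#'
#' @param path Path to the pair TSV.
#' @return Data frame of pairs.
#' @export
read_ortholog_pairs <- function(path) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  needed <- c("human_accession", "yeast_accession")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("ortholog table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab
}
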