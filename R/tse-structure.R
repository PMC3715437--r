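# Tissue-specific exon (TSE) structural analysis: exon selection,
# CDS-exon to protein-coordinate mapping, TSE disorder content and DBR
# association including the 5-residue boundary neighbourhood.

#' Select tissue-specific exons by switch score
#'
#' Keeps coding exon records whose exon switch score (the 0-1 measure of
#' the spread between the two most extreme tissue inclusion levels)
#' reaches `min_switch` (default 0.25). Non-coding records are dropped
#' with a message.
#'
#' @param records TSE table from [read_tse_table()].
#' @param min_switch Minimum switch score.
#' @return The selected subset of `records`.
#' @export
select_tses <- function(records, min_switch = 0.25) {
  noncoding <- !records$coding
  if (any(noncoding)) {
    message(sprintf("excluding %d non-coding exon record(s): %s",
                    sum(noncoding),
                    paste(records$gene[noncoding], collapse = ", ")))
  }
  records[records$coding & records$switch_score >= min_switch, ,
          drop = FALSE]
}

#' Map a CDS exon onto protein residue coordinates
#'
#' Given the ordered nucleotide lengths of a transcript's CDS exons and
#' the index of the tissue-specific exon, returns the residue span the
#' exon encodes. Residue `r` occupies CDS bases `3r-2 .. 3r`; under the
#' codon-majority rule a residue belongs to the exon when at least two of
#' its three bases fall inside it (`rule = "first_base"` instead assigns
#' each residue to the exon holding its first codon base). A CDS length
#' that is not a multiple of 3 raises a warning and the trailing partial
#' codon is ignored.
#'
#' @param cds_exon_lengths Integer vector of exon lengths (nucleotides).
#' @param tse_exon_index 1-based position of the TSE in that vector.
#' @param rule Boundary-residue assignment rule.
#' @return A one-row segment table (`start`, `end`), or a zero-row one
#'   with attribute `empty_span = TRUE` when the exon contributes no
#'   residue under the rule.
#' @export
#' @examples
#' map_exon_to_protein(c(10, 20, 15), 2)  # residues 4-10
map_exon_to_protein <- function(cds_exon_lengths, tse_exon_index,
                                rule = c("majority", "first_base")) {
  rule <- match.arg(rule)
  cds_exon_lengths <- as.integer(cds_exon_lengths)
  if (any(is.na(cds_exon_lengths) | cds_exon_lengths < 1L)) {
    stop("exon lengths must be positive integers", call. = FALSE)
  }
  if (tse_exon_index < 1L || tse_exon_index > length(cds_exon_lengths)) {
    stop("tse_exon_index out of range", call. = FALSE)
  }
  total <- sum(cds_exon_lengths)
  if (total %% 3L != 0L) {
    warning(sprintf("CDS length %d is not a multiple of 3; trailing partial codon ignored",
                    total))
  }
  n_res <- total %/% 3L
  ends <- cumsum(cds_exon_lengths)
  exon_start <- ends[tse_exon_index] - cds_exon_lengths[tse_exon_index] + 1L
  exon_end <- ends[tse_exon_index]
  r <- seq_len(n_res)
  base_lo <- 3L * r - 2L
  base_hi <- 3L * r
  inside <- if (rule == "majority") {
    pmax(0L, pmin(exon_end, base_hi) - pmax(exon_start, base_lo) + 1L) >= 2L
  } else {
    base_lo >= exon_start & base_lo <= exon_end
  }
  hit <- which(inside)
  if (!length(hit)) {
    out <- segments()
    attr(out, "empty_span") <- TRUE
    return(out)
  }
  segments(hit[1], hit[length(hit)])
}

#' Disorder content of a TSE-encoded protein span
#'
#' Fraction of disordered residues inside the span, with
#' transmembrane-excluded residues removed from both numerator and
#' denominator — consistent with the whole-protein metrics (disorder is
#' predicted on the whole protein; only the span is tallied).
#'
#' @param span One-row segment table (the TSE's residue span).
#' @param mask Protein [apply_tm_mask()] mask (e.g. `summary$mask`).
#' @return List with `fraction` (`NA` with `defined = FALSE` when the
#'   span is entirely excluded), `n_disordered` and `n_countable`.
#' @export
tse_disorder <- function(span, mask) {
  stopifnot(inherits(mask, "binary_mask"), nrow(span) == 1L)
  check_segments_within(span, length(mask$flags), "TSE span")
  idx <- span$start:span$end
  countable <- !mask$excluded[idx]
  n <- sum(countable)
  if (n == 0L) {
    return(list(fraction = NA_real_, n_disordered = 0L, n_countable = 0L,
                defined = FALSE))
  }
  d <- sum(mask$flags[idx] & countable)
  list(fraction = d / n, n_disordered = d, n_countable = n, defined = TRUE)
}

#' Associate DBRs with a TSE span and its boundary neighbourhood
#'
#' Splits a protein's disordered binding regions into those intersecting
#' the TSE span and those disjoint from it but touching the `flank`
#' -residue neighbourhood of either boundary
#' (`[start-flank, start-1]` or `[end+1, end+flank]`) — binding regions
#' likely affected by the presence or absence of the exon.
#'
#' @param span One-row segment table.
#' @param dbrs Segment table of DBRs.
#' @param flank Neighbourhood width in residues.
#' @return List of two segment tables: `overlapping` and `flank_only`.
#' @export
tse_dbr_association <- function(span, dbrs, flank = 5L) {
  stopifnot(nrow(span) == 1L)
  if (!nrow(dbrs)) {
    return(list(overlapping = segments(), flank_only = segments()))
  }
  overlaps_span <- dbrs$start <= span$end & dbrs$end >= span$start
  left_lo <- max(1L, span$start - flank)
  in_left <- dbrs$start <= span$start - 1L & dbrs$end >= left_lo
  in_right <- dbrs$start <= span$end + flank & dbrs$end >= span$end + 1L
  flank_only <- !overlaps_span & (in_left | in_right)
  list(overlapping = dbrs[overlaps_span, , drop = FALSE],
       flank_only = dbrs[flank_only, , drop = FALSE])
}

#' Analyse the structure of a set of tissue-specific exons
#'
#' For each selected TSE, computes its protein span (direct
#' `protein_span` mode or via [map_exon_to_protein()]), its disorder
#' fraction and its DBR associations, then pools the per-exon counts.
#'
#' @param tses Selected TSE table ([select_tses()] output); rows must
#'   carry an `accession` column resolving into `summaries`.
#' @param summaries Named list of [summarize_protein()] results (with
#'   binding tracks) keyed by accession.
#' @param flank DBR boundary neighbourhood width.
#' @return Data frame with one row per TSE: the span, `tse_disorder`
#'   fraction, residue counts, `n_dbr_overlap`, `n_dbr_flank`, and the
#'   formatted DBR location strings.
#' @export
tse_structure <- function(tses, summaries, flank = 5L) {
  if (!"accession" %in% names(tses)) {
    stop("TSE table must carry an 'accession' column", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(tses)), function(i) {
    acc <- tses$accession[i]
    s <- summaries[[acc]]
    if (is.null(s)) stop(sprintf("no summary for accession '%s'", acc),
                         call. = FALSE)
    span <- if (!is.na(tses$protein_start[i])) {
      segments(tses$protein_start[i], tses$protein_end[i])
    } else {
      lens <- as.integer(strsplit(tses$cds_exon_lengths[i], ";")[[1]])
      map_exon_to_protein(lens, as.integer(tses$tse_exon_index[i]))
    }
    if (!nrow(span)) {
      return(cbind(tses[i, c("gene", "transcript_id", "switch_score",
                             "route", "functional_group"), drop = FALSE],
                   data.frame(accession = acc, protein_start = NA_integer_,
                              protein_end = NA_integer_,
                              tse_disorder = NA_real_, n_disordered = 0L,
                              n_countable = 0L, n_dbr_overlap = 0L,
                              n_dbr_flank = 0L, dbr_overlapping = "",
                              dbr_flank = "", empty_span = TRUE)))
    }
    dis <- tse_disorder(span, s$mask)
    dbrs <- if (is.null(s$dbr_segments)) segments() else
      s$dbr_segments[, c("start", "end"), drop = FALSE]
    assoc <- tse_dbr_association(span, dbrs, flank)
    cbind(tses[i, c("gene", "transcript_id", "switch_score", "route",
                    "functional_group"), drop = FALSE],
          data.frame(accession = acc, protein_start = span$start,
                     protein_end = span$end,
                     tse_disorder = dis$fraction,
                     n_disordered = dis$n_disordered,
                     n_countable = dis$n_countable,
                     n_dbr_overlap = nrow(assoc$overlapping),
                     n_dbr_flank = nrow(assoc$flank_only),
                     dbr_overlapping = format_segment_field(assoc$overlapping),
                     dbr_flank = format_segment_field(assoc$flank_only),
                     empty_span = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a TSE structure table
#'
#' Pools the per-exon residue counts into the headline quantities: total
#' TSE-encoded residues, the pooled disordered fraction (total disordered
#' TSE residues / total TSE residues), DBR tallies, per-route exon counts
#' (an exon shared between routes counts once per route) and a
#' per-row flag marking exons more disordered than the reference proteome
#' disorder content.
#'
#' @param rows Output of [tse_structure()].
#' @param proteome_disorder_reference Reference proteome disorder content
#'   (fraction).
#' @return List with `n_tses`, `total_residues`, `pooled_disorder`,
#'   `n_dbr_overlap`, `n_dbr_flank`, `per_route` (data frame) and `rows`
#'   (the input with the added `more_disordered_than_reference`
#'   column).
#' @export
tse_report <- function(rows, proteome_disorder_reference) {
  if (!nrow(rows)) stop("empty TSE structure table", call. = FALSE)
  rows$more_disordered_than_reference <-
    !is.na(rows$tse_disorder) &
    rows$tse_disorder > proteome_disorder_reference
  route_lists <- strsplit(rows$route, ";", fixed = TRUE)
  routes <- sort(unique(unlist(route_lists)))
  per_route <- do.call(rbind, lapply(routes, function(r) {
    hit <- vapply(route_lists, function(x) r %in% x, TRUE)
    data.frame(route = r, n_tses = sum(hit),
               total_residues = sum(rows$n_countable[hit]),
               pooled_disorder = if (sum(rows$n_countable[hit]) > 0)
                 sum(rows$n_disordered[hit]) / sum(rows$n_countable[hit])
               else NA_real_)
  }))
  list(n_tses = nrow(rows),
       total_residues = sum(rows$n_countable),
       pooled_disorder = sum(rows$n_disordered) / sum(rows$n_countable),
       n_dbr_overlap = sum(rows$n_dbr_overlap),
       n_dbr_flank = sum(rows$n_dbr_flank),
       per_route = per_route,
       reference = proteome_disorder_reference,
       rows = rows)
}
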