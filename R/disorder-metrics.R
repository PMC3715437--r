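#' Binarize a score track at a disorder threshold
#'
#' Maps per-residue scores to an ordered/disordered (or
#' non-binding/binding) classification. A residue is flagged when its
#' score is greater than or equal to the threshold; ties at the threshold
#' count as disordered, the convention used throughout the package (the
#' standard cut-off is 0.5).
#'
#' @param track A [score_track()].
#' @param threshold Classification threshold, strictly inside (0, 1).
#' @return Logical vector, one flag per residue.
#' @export
binarize_track <- function(track, threshold = 0.5) {
  stopifnot(inherits(track, "score_track"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  track$scores >= threshold
}

#' Apply a transmembrane mask to residue flags
#'
#' Residues inside annotated transmembrane segments are excluded from
#' every disorder metric: they enter neither the numerator nor the
#' denominator of any ratio, and they interrupt disordered runs (see
#' [find_runs()]).
#'
#' @param flags Logical per-residue vector from [binarize_track()].
#' @param tm_segments Segment table of TM stretches; pairwise
#'   non-overlapping and within bounds.
#' @return An object of class `"binary_mask"` with elements `flags` and
#'   `excluded` (both logical, protein length) and the integer
#'   `effective_length` after exclusion.
#' @export
apply_tm_mask <- function(flags, tm_segments = segments()) {
  stopifnot(is.logical(flags), length(flags) >= 1L)
  check_segments_within(tm_segments, length(flags), "TM segment")
  if (segments_overlap(tm_segments)) {
    stop("overlapping TM segments", call. = FALSE)
  }
  excluded <- segment_mask(tm_segments, length(flags))
  structure(list(flags = flags, excluded = excluded,
                 effective_length = sum(!excluded)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d residues (%d excluded), %d flagged countable\n",
              length(x$flags), sum(x$excluded),
              sum(x$flags & !x$excluded)))
  invisible(x)
}

#' Find disordered runs of a minimum length
#'
#' Segments the mask into maximal runs of countable flagged residues with
#' length at least `k` — the long-disordered-region (LDR) definition when
#' applied to a disorder mask, and the disordered-binding-region (DBR)
#' definition when applied to a binding mask. Under the default no-join
#' policy an excluded (transmembrane) residue interrupts a run even when
#' flagged residues continue on its far side, since a membrane-embedded
#' stretch physically interrupts a disordered region. With
#' `join_over_excluded = TRUE` runs instead continue across excluded
#' residues (which still contribute nothing to run length).
#'
#' @param mask A [apply_tm_mask()] result (or logical vector, taken as a
#'   mask with nothing excluded).
#' @param k Minimum run length in countable residues (`k >= 1`).
#' @param join_over_excluded Join policy across excluded residues.
#' @return Data frame with columns `start`, `end` (original protein
#'   coordinates of the first/last countable residue) and `length`
#'   (countable residues), ordered by `start`.
#' @export
find_runs <- function(mask, k = 1L, join_over_excluded = FALSE) {
  if (is.logical(mask)) mask <- apply_tm_mask(mask)
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  countable <- mask$flags & !mask$excluded
  if (join_over_excluded) {
    # Work in excluded-free coordinates, then map back.
    keep <- which(!mask$excluded)
    runs <- runs_from_logical(countable[keep])
    if (nrow(runs)) {
      runs$length <- runs$end - runs$start + 1L
      runs$start <- keep[runs$start]
      runs$end <- keep[runs$end]
    }
  } else {
    runs <- runs_from_logical(countable)
    if (nrow(runs)) runs$length <- runs$end - runs$start + 1L
  }
  if (!nrow(runs)) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  runs <- runs[runs$length >= k, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

# Maximal TRUE runs of a logical vector as a start/end table.
runs_from_logical <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Summarise the disorder metrics of one protein
#'
#' Computes the three standard per-protein measures from binarized score
#' tracks, after transmembrane exclusion:
#'
#' * disorder content: countable disordered residues / effective length;
#' * LDR residue ratio per `k`: residues in maximal disordered runs of at
#'   least `k` residues / effective length (`k` = 30, 50, 100 by
#'   default);
#' * DBR residue ratio: same construction on the binding track with
#'   minimum run length `dbr_min_len`.
#'
#' An absent binding track leaves the DBR fields flagged unavailable
#' (`NA`), not zero.
#'
#' @param protein A [protein_record()].
#' @param disorder_track Disorder [score_track()] of matching length.
#' @param binding_track Optional binding [score_track()].
#' @param k_values LDR minimum lengths to evaluate.
#' @param dbr_min_len Minimum DBR run length (see Details in the methods
#'   vignette; region counts depend on this convention).
#' @param threshold Binarization threshold.
#' @param join_over_excluded Run join policy across TM residues, see
#'   [find_runs()].
#' @return An object of class `"disorder_summary"`: a list with fields
#'   `accession`, `length`, `effective_length`, `disorder_content`,
#'   `ldr_residue_ratio` / `n_ldr` / `has_ldr` (named by `k`),
#'   `dbr_residue_ratio`, `n_dbr`, `dbr_available`.
#' @export
summarize_protein <- function(protein, disorder_track, binding_track = NULL,
                              k_values = c(30L, 50L, 100L), dbr_min_len = 6L,
                              threshold = 0.5, join_over_excluded = FALSE) {
  stopifnot(inherits(protein, "protein_record"))
  validate_track(disorder_track, protein$sequence, protein$accession)
  if (disorder_track$kind != "disorder") {
    stop("disorder_track must have kind 'disorder'", call. = FALSE)
  }
  mask <- apply_tm_mask(binarize_track(disorder_track, threshold),
                        protein$tm_segments)
  eff <- mask$effective_length
  if (eff == 0L) {
    warning(sprintf("protein '%s' is entirely transmembrane; metrics undefined",
                    protein$accession))
  }
  n_dis <- sum(mask$flags & !mask$excluded)
  dc <- if (eff > 0L) n_dis / eff else NA_real_

  k_values <- sort(as.integer(k_values))
  ldr_ratio <- n_ldr <- setNames(numeric(length(k_values)),
                                 as.character(k_values))
  has_ldr <- setNames(logical(length(k_values)), as.character(k_values))
  for (i in seq_along(k_values)) {
    runs <- find_runs(mask, k_values[i], join_over_excluded)
    n_ldr[i] <- nrow(runs)
    ldr_ratio[i] <- if (eff > 0L) sum(runs$length) / eff else NA_real_
    has_ldr[i] <- nrow(runs) > 0L
  }

  dbr_available <- !is.null(binding_track)
  dbr_ratio <- NA_real_
  n_dbr <- NA_integer_
  dbr_runs <- NULL
  if (dbr_available) {
    validate_track(binding_track, protein$sequence, protein$accession)
    if (binding_track$kind != "binding") {
      stop("binding_track must have kind 'binding'", call. = FALSE)
    }
    bmask <- apply_tm_mask(binarize_track(binding_track, threshold),
                           protein$tm_segments)
    dbr_runs <- find_runs(bmask, dbr_min_len, join_over_excluded)
    n_dbr <- nrow(dbr_runs)
    dbr_ratio <- if (eff > 0L) sum(dbr_runs$length) / eff else NA_real_
  }

  structure(list(accession = protein$accession,
                 length = length(mask$flags),
                 effective_length = eff,
                 disorder_content = dc,
                 ldr_residue_ratio = ldr_ratio,
                 n_ldr = setNames(as.integer(n_ldr), names(ldr_ratio)),
                 has_ldr = has_ldr,
                 dbr_residue_ratio = dbr_ratio,
                 n_dbr = n_dbr,
                 dbr_available = dbr_available,
                 dbr_segments = dbr_runs,
                 mask = mask),
            class = "disorder_summary")
}

#' @export
print.disorder_summary <- function(x, ...) {
  cat(sprintf("<disorder_summary> %s: %d aa (eff. %d), d.c. %.2f%%, DBR %s\n",
              x$accession, x$length, x$effective_length,
              100 * x$disorder_content,
              if (x$dbr_available) sprintf("%.2f%%", 100 * x$dbr_residue_ratio)
              else "unavailable"))
  invisible(x)
}

#' Tabulate a list of disorder summaries
#'
#' Flattens [summarize_protein()] results to one row per protein, the
#' shape consumed by the cohort-statistics functions and written by the
#' pipeline's summary reports.
#'
#' @param summaries List of `disorder_summary` objects.
#' @return Data frame with columns `accession`, `length`,
#'   `effective_length`, `disorder_content`, `ldr_ratio_<k>`,
#'   `n_ldr_<k>`, `has_ldr_<k>`, `dbr_residue_ratio`, `n_dbr`.
#' @export
summary_table <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  ks <- names(summaries[[1]]$ldr_residue_ratio)
  base <- data.frame(
    accession = vapply(summaries, `[[`, "", "accession"),
    length = vapply(summaries, `[[`, 1L, "length"),
    effective_length = vapply(summaries, `[[`, 1L, "effective_length"),
    disorder_content = vapply(summaries, `[[`, 1, "disorder_content"))
  for (k in ks) {
    base[[paste0("ldr_ratio_", k)]] <-
      vapply(summaries, function(s) s$ldr_residue_ratio[[k]], 1)
    base[[paste0("n_ldr_", k)]] <-
      vapply(summaries, function(s) s$n_ldr[[k]], 1L)
    base[[paste0("has_ldr_", k)]] <-
      vapply(summaries, function(s) s$has_ldr[[k]], TRUE)
  }
  base$dbr_residue_ratio <- vapply(summaries, `[[`, 1, "dbr_residue_ratio")
  base$n_dbr <- vapply(summaries, `[[`, 1L, "n_dbr")
  rownames(base) <- NULL
  base
}

#' Run the per-protein metrics stage over a cohort on disk
#'
#' Convenience driver tying [read_fasta()], [read_annotation_table()],
#' [read_score_track()] and [summarize_protein()] together: for each
#' annotated protein it expects `<accession>.iupred` (and optionally
#' `<accession>.anchor`) under `track_dir`.
#'
#' @param fasta Path to the cohort FASTA.
#' @param annotations Path to the annotation TSV.
#' @param track_dir Directory of per-protein track files.
#' @param ... Passed on to [summarize_protein()].
#' @return List with `records` (protein records) and `summaries`
#'   (disorder summaries), parallel by accession.
#' @export
run_metrics <- function(fasta, annotations, track_dir, ...) {
  seqs <- read_fasta(fasta)
  records <- read_annotation_table(annotations, seqs)
  summaries <- lapply(records, function(rec) {
    dis <- read_score_track(file.path(track_dir,
                                      paste0(rec$accession, ".iupred")),
                            kind = "disorder")
    anchor_path <- file.path(track_dir, paste0(rec$accession, ".anchor"))
    bind <- if (file.exists(anchor_path)) {
      read_score_track(anchor_path, kind = "binding")
    }
    summarize_protein(rec, dis, bind, ...)
  })
  list(records = records, summaries = summaries)
}
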