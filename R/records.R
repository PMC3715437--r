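#' Construct a protein record
#'
#' One vesicle-trafficking protein: identifiers, species, sequence,
#' functional group, route memberships and annotated transmembrane
#' segments. Functional groups follow the eight-group classification used
#' for trafficking proteins (COAT, ASP, EARP, UCP, MSTC, OFRP, SNARE,
#' NTSR) plus NONE for background proteins; routes are CLTR (clathrin),
#' COPI and COPII. A protein may belong to several routes (e.g. cargo
#' receptors shared between COPI and COPII).
#'
#' @param accession UniProt-style accession (non-empty string).
#' @param sequence Amino-acid sequence (uppercase; 20 standard residues
#'   plus X/B/Z/U).
#' @param name Gene/protein name; defaults to the accession.
#' @param species One of `"human"`, `"yeast"`, `"other"`.
#' @param functional_group One of the group labels above.
#' @param routes Character vector, subset of `c("CLTR","COPI","COPII")`.
#' @param tm_segments Transmembrane segments as returned by [segments()];
#'   pairwise non-overlapping and within the sequence.
#' @return An object of class `"protein_record"`.
#' @export
#' @examples
#' protein_record("P09496", "MAELD", name = "CLTA",
#'                functional_group = "COAT", routes = "CLTR")
protein_record <- function(accession, sequence, name = accession,
                           species = "human", functional_group = "NONE",
                           routes = character(), tm_segments = segments()) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop(sprintf("protein '%s': sequence must be non-empty", accession),
         call. = FALSE)
  }
  check_sequence_alphabet(sequence, accession)
  species <- match.arg(species, VT_SPECIES)
  functional_group <- match.arg(functional_group, VT_GROUPS)
  if (functional_group == "NTSR" && species != "human") {
    stop(sprintf("protein '%s': NTSR group is defined for human only",
                 accession), call. = FALSE)
  }
  routes <- unique(as.character(routes))
  unknown <- setdiff(routes, VT_ROUTES)
  if (length(unknown)) {
    stop(sprintf("protein '%s': unknown route '%s'", accession, unknown[1]),
         call. = FALSE)
  }
  len <- nchar(sequence)
  check_segments_within(tm_segments, len,
                        sprintf("protein '%s': TM segment", accession))
  if (segments_overlap(tm_segments)) {
    stop(sprintf("protein '%s': overlapping TM segments", accession),
         call. = FALSE)
  }
  structure(list(accession = accession, name = name, species = species,
                 sequence = sequence, functional_group = functional_group,
                 routes = routes, tm_segments = tm_segments),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s, %s) %d aa, group %s, routes [%s], %d TM\n",
              x$accession, x$name, x$species, nchar(x$sequence),
              x$functional_group, paste(x$routes, collapse = ","),
              nrow(x$tm_segments)))
  invisible(x)
}

check_sequence_alphabet <- function(sequence, id) {
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!(letters %in% VT_AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("'%s': invalid residue '%s' at position %d",
                 id, letters[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(sequence)
}

#' Construct a per-residue score track
#'
#' A track holds one score in \[0, 1\] per residue, of kind `"disorder"`
#' (IUPred-style disorder probability) or `"binding"` (ANCHOR-style
#' disordered-binding propensity). Residue letters, when available from
#' the track file, are retained for cross-validation against the owning
#' sequence.
#'
#' @param scores Numeric vector of per-residue scores in \[0, 1\].
#' @param kind `"disorder"` or `"binding"`.
#' @param residues Optional character vector of one-letter residue codes,
#'   same length as `scores`.
#' @return An object of class `"score_track"`.
#' @export
score_track <- function(scores, kind = c("disorder", "binding"),
                        residues = NULL) {
  kind <- match.arg(kind)
  scores <- as.numeric(scores)
  if (!length(scores)) stop("score track must be non-empty", call. = FALSE)
  bad <- which(is.na(scores) | scores < 0 | scores > 1)
  if (length(bad)) {
    stop(sprintf("score outside [0,1] at residue %d", bad[1]), call. = FALSE)
  }
  if (!is.null(residues)) {
    residues <- toupper(as.character(residues))
    if (length(residues) != length(scores)) {
      stop("residues and scores differ in length", call. = FALSE)
    }
  }
  structure(list(kind = kind, scores = scores, residues = residues),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> kind=%s, %d residues, mean score %.3f\n",
              x$kind, length(x$scores), mean(x$scores)))
  invisible(x)
}

#' @export
length.score_track <- function(x) length(x$scores)

#' Validate a score track against a protein sequence
#'
#' Checks length equality and, when the track carries residue letters,
#' per-position agreement with the sequence.
#'
#' @param track A [score_track()].
#' @param sequence Amino-acid string of the owning protein.
#' @param id Identifier used in error messages.
#' @return The track, invisibly; errors cite the first offending position.
#' @export
validate_track <- function(track, sequence, id = "protein") {
  stopifnot(inherits(track, "score_track"))
  len <- nchar(sequence)
  if (length(track$scores) != len) {
    stop(sprintf("'%s': track has %d scores but sequence has %d residues",
                 id, length(track$scores), len), call. = FALSE)
  }
  if (!is.null(track$residues)) {
    seq_letters <- strsplit(toupper(sequence), "")[[1]]
    bad <- which(track$residues != seq_letters)
    if (length(bad)) {
      stop(sprintf("'%s': track residue '%s' disagrees with sequence '%s' at position %d",
                   id, track$residues[bad[1]], seq_letters[bad[1]], bad[1]),
           call. = FALSE)
    }
  }
  invisible(track)
}
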