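#' Build a segment table
#'
#' Segments are 1-based, inclusive residue intervals, the coordinate
#' convention used for transmembrane stretches, Pfam-style domains,
#' disordered runs, DBRs and exon-encoded protein spans throughout the
#' package.
#'
#' @param start,end Integer vectors of equal length; `1 <= start <= end`.
#' @return A data frame with integer columns `start` and `end`.
#' @export
#' @examples
#' segments(c(1, 10), c(5, 20))
segments <- function(start = integer(), end = integer()) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("'start' and 'end' must have equal length", call. = FALSE)
  }
  if (any(is.na(start)) || any(is.na(end))) {
    stop("segment bounds must not be NA", call. = FALSE)
  }
  if (any(start < 1L)) stop("segment start must be >= 1", call. = FALSE)
  bad <- which(start > end)
  if (length(bad)) {
    stop(sprintf("segment %d has start > end (%d > %d)",
                 bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  data.frame(start = start, end = end)
}

# Parse "start-end;start-end" tokens (as used in annotation TSVs) into a
# segment table. `context` labels error messages, e.g. a row number.
parse_segment_field <- function(x, context = "") {
  if (is.na(x) || !nzchar(trimws(x))) return(segments())
  tokens <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(trimws(tokens))]
  m <- regmatches(tokens, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", tokens))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed segment token '%s'%s", tokens[bad[1]],
                 if (nzchar(context)) paste0(" ", context) else ""),
         call. = FALSE)
  }
  starts <- vapply(m, function(g) as.integer(g[2]), 1L)
  ends <- vapply(m, function(g) as.integer(g[3]), 1L)
  tryCatch(segments(starts, ends), error = function(e) {
    stop(sprintf("%s%s", conditionMessage(e),
                 if (nzchar(context)) paste0(" ", context) else ""),
         call. = FALSE)
  })
}

format_segment_field <- function(seg) {
  if (!nrow(seg)) return("")
  paste(sprintf("%d-%d", seg$start, seg$end), collapse = ";")
}

# TRUE when any pair of segments overlaps.
segments_overlap <- function(seg) {
  if (nrow(seg) < 2) return(FALSE)
  o <- order(seg$start, seg$end)
  any(seg$start[o][-1] <= seg$end[o][-nrow(seg)])
}

# Logical residue membership vector of length `len` for a segment table.
segment_mask <- function(seg, len) {
  m <- logical(len)
  for (i in seq_len(nrow(seg))) m[seg$start[i]:seg$end[i]] <- TRUE
  m
}

check_segments_within <- function(seg, len, what = "segment") {
  if (nrow(seg) && any(seg$end > len)) {
    stop(sprintf("%s extends beyond sequence length %d", what, len),
         call. = FALSE)
  }
  invisible(seg)
}
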