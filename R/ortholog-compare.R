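# Human-yeast ortholog disorder comparison.

#' Compare disorder content across ortholog pairs
#'
#' For each human-yeast ortholog pair, computes the signed difference in
#' disorder content (human minus yeast, in percentage points) and
#' assigns a category:
#'
#' * `below_threshold` — neither member exceeds `dc_threshold` disorder
#'   content (strictly greater than 30% is required to enter the
#'   comparison); retained in the output but excluded from category
#'   tallies;
#' * `similar` — absolute difference under `similar_margin` percentage
#'   points (default 5);
#' * `human_higher` / `yeast_higher` otherwise.
#'
#' Pairs sitting exactly on the disorder-content threshold are flagged in
#' `boundary_case`.
#'
#' @param pairs Data frame with columns `human_accession`,
#'   `yeast_accession` (see [read_ortholog_pairs()]).
#' @param summaries_human,summaries_yeast Summaries ([summary_table()]
#'   shape or list of [summarize_protein()] results) for each species.
#' @param dc_threshold Disorder-content entry threshold (fraction).
#' @param similar_margin Margin defining `similar`, in percentage
#'   points.
#' @return Data frame with one row per pair: `dc_human`, `dc_yeast`
#'   (fractions), `delta` (percentage points), `category`,
#'   `boundary_case`; attribute `tallies` holds the category counts over
#'   above-threshold pairs.
#' @export
compare_orthologs <- function(pairs, summaries_human, summaries_yeast,
                              dc_threshold = 0.30, similar_margin = 5) {
  dh <- as_summary_df(summaries_human)
  dy <- as_summary_df(summaries_yeast)
  lookup <- function(df, acc, species) {
    hit <- df$disorder_content[df$accession == acc]
    if (!length(hit)) {
      stop(sprintf("no %s summary for accession '%s'", species, acc),
           call. = FALSE)
    }
    hit[1]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    hacc <- pairs$human_accession[i]
    yacc <- pairs$yeast_accession[i]
    dc_h <- lookup(dh, hacc, "human")
    dc_y <- lookup(dy, yacc, "yeast")
    delta <- (dc_h - dc_y) * 100
    top <- max(dc_h, dc_y)
    category <- if (top <= dc_threshold) "below_threshold"
      else if (abs(delta) < similar_margin) "similar"
      else if (delta > 0) "human_higher"
      else "yeast_higher"
    data.frame(human_accession = hacc, yeast_accession = yacc,
               dc_human = dc_h, dc_yeast = dc_y, delta = delta,
               category = category,
               boundary_case = isTRUE(all.equal(top, dc_threshold)))
  })
  out <- do.call(rbind, rows)
  above <- out$category != "below_threshold"
  attr(out, "tallies") <- c(
    n_pairs = nrow(out),
    n_above_threshold = sum(above),
    similar = sum(out$category == "similar"),
    human_higher = sum(out$category == "human_higher"),
    yeast_higher = sum(out$category == "yeast_higher"))
  out
}
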