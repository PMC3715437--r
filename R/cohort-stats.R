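# Cohort-level statistics: group summaries, LDR prevalence, rank-sum and
# enrichment tests, route comparisons, the highly-disordered selection
# rule and the structured-island domain-context classification.

# Accept either a list of disorder_summary objects or an already-flat
# summary_table() data frame.
as_summary_df <- function(summaries) {
  if (is.data.frame(summaries)) return(summaries)
  summary_table(summaries)
}

# Expand an accession -> label(s) grouping (named character vector or
# named list) into a two-column accession/label frame. A protein mapped
# to several labels (e.g. a COPI/COPII cargo receptor) contributes one
# row per label, so per-route tallies treat routes independently.
expand_grouping <- function(grouping) {
  if (is.list(grouping)) {
    acc <- rep(names(grouping), lengths(grouping))
    lab <- unlist(grouping, use.names = FALSE)
  } else {
    acc <- names(grouping)
    lab <- as.character(grouping)
  }
  data.frame(accession = acc, label = lab)
}

#' Per-group means and medians of the disorder metrics
#'
#' One row per group label with the number of proteins and the mean and
#' median of disorder content, DBR residue ratio and LDR residue ratio at
#' `k` = 30 — the shape of the published per-group disorder summary.
#' Medians use the midpoint convention (average of the two central order
#' statistics for even n). Proteins mapped to several labels are counted
#' once per label.
#'
#' @param summaries List of [summarize_protein()] results or a
#'   [summary_table()] data frame.
#' @param grouping Named character vector or named list mapping accession
#'   to group label(s); every summarised accession must be grouped.
#' @return Data frame with columns `group_label`, `n_proteins`,
#'   `mean_dc`, `median_dc`, `mean_dbr`, `median_dbr`, `mean_ldr30`,
#'   `median_ldr30`.
#' @export
group_summary <- function(summaries, grouping) {
  df <- as_summary_df(summaries)
  g <- expand_grouping(grouping)
  ungrouped <- setdiff(df$accession, g$accession)
  if (length(ungrouped)) {
    stop(sprintf("accession '%s' has no group label", ungrouped[1]),
         call. = FALSE)
  }
  labels <- unique(g$label)
  rows <- lapply(labels, function(lab) {
    accs <- g$accession[g$label == lab]
    sub <- df[df$accession %in% accs, , drop = FALSE]
    if (!nrow(sub)) stop(sprintf("empty group '%s'", lab), call. = FALSE)
    data.frame(group_label = lab, n_proteins = nrow(sub),
               mean_dc = mean(sub$disorder_content),
               median_dc = median(sub$disorder_content),
               mean_dbr = mean(sub$dbr_residue_ratio),
               median_dbr = median(sub$dbr_residue_ratio),
               mean_ldr30 = mean(sub$ldr_ratio_30),
               median_ldr30 = median(sub$ldr_ratio_30))
  })
  do.call(rbind, rows)
}

#' Fraction of proteins carrying an LDR, per group and run length
#'
#' For each group label and each `k`, the fraction of proteins with at
#' least one long disordered region of at least `k` residues — the shape
#' of the published LDR-prevalence table whose last row holds the
#' whole-proteome background.
#'
#' @inheritParams group_summary
#' @param k_values LDR lengths to tabulate (must be present in the
#'   summaries).
#' @return Data frame with columns `group_label`, `n_proteins` and
#'   `frac_ldr_<k>` per `k`.
#' @export
ldr_prevalence <- function(summaries, grouping, k_values = c(30L, 50L, 100L)) {
  df <- as_summary_df(summaries)
  g <- expand_grouping(grouping)
  ungrouped <- setdiff(df$accession, g$accession)
  if (length(ungrouped)) {
    stop(sprintf("accession '%s' has no group label", ungrouped[1]),
         call. = FALSE)
  }
  cols <- paste0("has_ldr_", k_values)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("summaries lack column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  labels <- unique(g$label)
  rows <- lapply(labels, function(lab) {
    accs <- g$accession[g$label == lab]
    sub <- df[df$accession %in% accs, , drop = FALSE]
    if (!nrow(sub)) stop(sprintf("empty group '%s'", lab), call. = FALSE)
    out <- data.frame(group_label = lab, n_proteins = nrow(sub))
    for (i in seq_along(k_values)) {
      out[[paste0("frac_ldr_", k_values[i])]] <- mean(sub[[cols[i]]])
    }
    out
  })
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sample rank-sum test as used for comparing disorder metrics
#' between groups and routes. The exact null distribution is used for
#' tie-free samples with `n1 + n2 <= 12`; larger or tied samples use the
#' normal approximation with midrank ties, tie correction and continuity
#' correction. Two samples whose pooled values are all identical are
#' degenerate and return p = 1.
#'
#' @param a,b Numeric samples (`n >= 1` each).
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (a shifted
#'   relative to b).
#' @return A `"test_result"` list: `test`, `statistic` (Mann-Whitney W of
#'   sample a), `p_value`, `alternative`, `n1`, `n2`, `degenerate`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  if (any(is.na(c(a, b)))) stop("samples must not contain NA", call. = FALSE)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(structure(list(test = "rank_sum",
                          statistic = length(a) * length(b) / 2,
                          p_value = 1, alternative = alternative,
                          n1 = length(a), n2 = length(b),
                          degenerate = TRUE),
                     class = "test_result"))
  }
  ties <- any(duplicated(pooled))
  exact <- !ties && (length(a) + length(b) <= 12L)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alt, exact = exact,
                                     correct = TRUE))
  structure(list(test = "rank_sum", statistic = unname(wt$statistic),
                 p_value = wt$p.value, alternative = alternative,
                 n1 = length(a), n2 = length(b), degenerate = FALSE),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s (%s): statistic %.4g, p = %.4g (n1=%d, n2=%d)%s\n",
              x$test, x$alternative, x$statistic, x$p_value, x$n1, x$n2,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Hypergeometric enrichment test against a reference proteome
#'
#' Fisher's exact test on the 2x2 table contrasting the flagged fraction
#' of a protein group with a whole-proteome reference. By default the
#' reference counts are used as printed (whole proteome including the
#' group, the published construction); set `exclude_group = TRUE` to
#' subtract the group from the background first.
#'
#' @param k_group Flagged proteins in the group.
#' @param n_group Group size.
#' @param k_background Flagged proteins in the reference proteome.
#' @param n_background Reference proteome size.
#' @param alternative `"greater"` (enrichment, default), `"less"` or
#'   `"two_sided"`.
#' @param exclude_group Subtract the group's counts from the background
#'   before testing.
#' @return A `"test_result"` list; `statistic` is the sample odds ratio.
#' @export
enrichment_test <- function(k_group, n_group, k_background, n_background,
                            alternative = c("greater", "less", "two_sided"),
                            exclude_group = FALSE) {
  alternative <- match.arg(alternative)
  if (k_group > n_group || k_background > n_background) {
    stop("flagged count exceeds total", call. = FALSE)
  }
  if (n_background < n_group) {
    stop("background smaller than the group it is declared to contain",
         call. = FALSE)
  }
  if (exclude_group) {
    k_background <- k_background - k_group
    n_background <- n_background - n_group
    if (k_background < 0 || n_background < 1) {
      stop("background does not contain the group's counts", call. = FALSE)
    }
  }
  m <- matrix(c(k_group, n_group - k_group,
                k_background, n_background - k_background), nrow = 2)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  ft <- fisher.test(m, alternative = alt)
  or <- (m[1, 1] * m[2, 2]) / (m[2, 1] * m[1, 2])
  structure(list(test = "enrichment", statistic = unname(or),
                 p_value = ft$p.value, alternative = alternative,
                 n1 = n_group, n2 = n_background, degenerate = FALSE),
            class = "test_result")
}

#' Compare the three trafficking routes
#'
#' Runs all pairwise rank-sum comparisons of disorder content and DBR
#' residue ratio between route cohorts, plus the per-route LDR-prevalence
#' enrichment tests against the whole-proteome background at each `k`.
#' Raw p-values are reported (as in the published analysis); a
#' Benjamini-Hochberg adjusted column is emitted alongside for
#' transparency, separately within each test family.
#'
#' @inheritParams group_summary
#' @param background List with `n` (reference proteome size) and
#'   `n_with_ldr`, a vector named by `k` of reference proteins carrying
#'   an LDR of at least `k` residues.
#' @param k_values LDR lengths for the enrichment tests.
#' @param rank_sum_alternative Alternative for the pairwise rank-sum
#'   tests (two-sided by default).
#' @return List of two data frames: `rank_sum` (one row per metric and
#'   route pair) and `enrichment` (one row per route and `k`), both with
#'   `p_value` and `p_bh` columns.
#' @export
compare_pathways <- function(summaries, grouping, background,
                             k_values = c(30L, 50L, 100L),
                             rank_sum_alternative = "two_sided") {
  df <- as_summary_df(summaries)
  g <- expand_grouping(grouping)
  if (is.null(background$n) || is.null(background$n_with_ldr)) {
    stop("background must supply 'n' and 'n_with_ldr'", call. = FALSE)
  }
  routes <- intersect(VT_ROUTES, unique(g$label))
  if (length(routes) < 2L) {
    stop("grouping must define at least two routes", call. = FALSE)
  }
  route_values <- function(route, col) {
    df[[col]][df$accession %in% g$accession[g$label == route]]
  }

  rs_rows <- list()
  for (metric in c("disorder_content", "dbr_residue_ratio")) {
    for (i in seq_along(routes)) for (j in seq_along(routes)) {
      if (i >= j) next
      a <- route_values(routes[i], metric)
      b <- route_values(routes[j], metric)
      if (metric == "dbr_residue_ratio" && (anyNA(a) || anyNA(b))) next
      res <- rank_sum_test(a, b, rank_sum_alternative)
      rs_rows[[length(rs_rows) + 1L]] <- data.frame(
        metric = metric, group1 = routes[i], group2 = routes[j],
        n1 = res$n1, n2 = res$n2, statistic = res$statistic,
        p_value = res$p_value, alternative = res$alternative)
    }
  }
  rank_sum <- do.call(rbind, rs_rows)
  rank_sum$p_bh <- p.adjust(rank_sum$p_value, method = "BH")

  en_rows <- list()
  for (route in routes) {
    accs <- g$accession[g$label == route]
    sub <- df[df$accession %in% accs, , drop = FALSE]
    for (k in k_values) {
      kb <- background$n_with_ldr[[as.character(k)]]
      if (is.null(kb) || is.na(kb)) {
        stop(sprintf("background lacks LDR counts for k=%d", k), call. = FALSE)
      }
      res <- enrichment_test(sum(sub[[paste0("has_ldr_", k)]]), nrow(sub),
                             kb, background$n, alternative = "greater")
      en_rows[[length(en_rows) + 1L]] <- data.frame(
        route = route, k = k, k_group = sum(sub[[paste0("has_ldr_", k)]]),
        n_group = nrow(sub), k_background = kb, n_background = background$n,
        odds_ratio = res$statistic, p_value = res$p_value,
        alternative = res$alternative)
    }
  }
  enrichment <- do.call(rbind, en_rows)
  enrichment$p_bh <- p.adjust(enrichment$p_value, method = "BH")

  list(rank_sum = rank_sum, enrichment = enrichment)
}

#' Select the highly disordered proteins of a cohort
#'
#' A protein is selected when its disorder content is at least `dc_min`
#' (default 70%) or its LDR residue ratio (k = 30) reaches the LDR
#' cut-off. The cut-off combines a cohort-relative criterion (mean plus
#' `sd_mult` standard deviations) with an absolute one (`ldr_abs`,
#' default 50%): under the default `cutoff_rule = "min"` either criterion
#' suffices (cut-off = min of the two); `"max"` requires the stricter
#' one.
#'
#' @inheritParams group_summary
#' @param dc_min Disorder-content criterion.
#' @param ldr_abs Absolute LDR-ratio criterion.
#' @param sd_mult Multiplier on the cohort standard deviation.
#' @param cutoff_rule `"min"` (either criterion) or `"max"` (both).
#' @return Data frame with the rule components per protein
#'   (`disorder_content`, `ldr_ratio_30`, `ldr_cutoff`, `by_dc`,
#'   `by_ldr`) and the final `selected` flag.
#' @export
select_highly_disordered <- function(summaries, dc_min = 0.70,
                                     ldr_abs = 0.50, sd_mult = 2,
                                     cutoff_rule = c("min", "max")) {
  cutoff_rule <- match.arg(cutoff_rule)
  df <- as_summary_df(summaries)
  if (nrow(df) < 2L) {
    stop("need at least 2 summaries to define the cohort mean and sd",
         call. = FALSE)
  }
  rel <- mean(df$ldr_ratio_30) + sd_mult * sd(df$ldr_ratio_30)
  cutoff <- if (cutoff_rule == "min") min(rel, ldr_abs) else max(rel, ldr_abs)
  out <- data.frame(accession = df$accession,
                    disorder_content = df$disorder_content,
                    ldr_ratio_30 = df$ldr_ratio_30,
                    ldr_cutoff = cutoff,
                    by_dc = df$disorder_content >= dc_min,
                    by_ldr = df$ldr_ratio_30 >= cutoff)
  out$selected <- out$by_dc | out$by_ldr
  out
}

#' Classify the disorder context of each domain
#'
#' Labels every domain by whether the region(s) between it and the
#' protein termini are extended disordered stretches: a flank qualifies
#' when it holds at least `flank_min_len` countable residues with a
#' disorder fraction of at least `flank_disorder_min`. A domain whose
#' C-side flank qualifies is a structured island with a disordered
#' C-terminal arm (`island_C`); `island_N` and `island_both` analogously;
#' otherwise `embedded`. Overlapping domains are classified independently
#' with a warning.
#'
#' @param mask A [apply_tm_mask()] binary mask of the protein's disorder
#'   flags (e.g. `summary$mask`).
#' @param domains Data frame with columns `name`, `start`, `end` (and
#'   optionally `entity_class`).
#' @param flank_disorder_min Minimum disorder fraction of a qualifying
#'   flank.
#' @param flank_min_len Minimum countable flank length.
#' @return `domains` with added columns `n_flank_disorder`,
#'   `c_flank_disorder` (fractions, `NA` for absent flanks) and
#'   `context`.
#' @export
classify_domain_context <- function(mask, domains, flank_disorder_min = 0.70,
                                    flank_min_len = 30L) {
  stopifnot(inherits(mask, "binary_mask"))
  len <- length(mask$flags)
  seg <- segments(domains$start, domains$end)
  check_segments_within(seg, len, "domain")
  if (segments_overlap(seg)) {
    warning("overlapping domains; contexts computed per domain independently")
  }
  countable <- !mask$excluded
  dis <- mask$flags & countable
  flank_stats <- function(lo, hi) {
    if (lo > hi) return(c(n = 0, frac = NA_real_))
    idx <- lo:hi
    n <- sum(countable[idx])
    c(n = n, frac = if (n > 0) sum(dis[idx]) / n else NA_real_)
  }
  nf <- cf <- numeric(nrow(domains))
  context <- character(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    ns <- flank_stats(1L, seg$start[i] - 1L)
    cs <- flank_stats(seg$end[i] + 1L, len)
    nf[i] <- ns[["frac"]]; cf[i] <- cs[["frac"]]
    n_ok <- ns[["n"]] >= flank_min_len && !is.na(ns[["frac"]]) &&
      ns[["frac"]] >= flank_disorder_min
    c_ok <- cs[["n"]] >= flank_min_len && !is.na(cs[["frac"]]) &&
      cs[["frac"]] >= flank_disorder_min
    context[i] <- if (n_ok && c_ok) "island_both"
      else if (n_ok) "island_N"
      else if (c_ok) "island_C"
      else "embedded"
  }
  domains$n_flank_disorder <- nf
  domains$c_flank_disorder <- cf
  domains$context <- context
  domains
}
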