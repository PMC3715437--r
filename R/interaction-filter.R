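# Off-pathway interaction-partner filtering: confidence threshold,
# sequence-identity filter against the pathway set, greedy clustering of
# redundant partners, exclusion lists, and the per-route report.

#' Pairwise sequence identity (shorter-sequence denominator)
#'
#' Identity between two sequences under an optimal global alignment with
#' match score 1, mismatch 0 and no gap penalty, divided by the length of
#' the shorter sequence — the convention of greedy sequence-identity
#' clustering tools. With this scoring the optimal match count is the
#' longest common subsequence, computed via
#' [Biostrings::pairwiseAlignment()]. Symmetric in its arguments.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  alphabet <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  mat <- diag(1, length(alphabet))
  dimnames(mat) <- list(alphabet, alphabet)
  matches <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 0,
    scoreOnly = TRUE)
  matches / min(nchar(a), nchar(b))
}

#' Greedy sequence-identity clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted longest-first
#' (ties broken by lexicographic id); each sequence joins the first
#' existing cluster whose representative it matches at `threshold`
#' identity or better, otherwise it founds a new cluster. The
#' representative of each cluster is its founding (longest) member.
#'
#' @param sequences Named character vector (names = ids).
#' @param threshold Identity threshold in (0, 1].
#' @return List of clusters, each a list with `representative` (id) and
#'   `members` (ids including the representative, in joining order).
#' @export
greedy_cluster <- function(sequences, threshold = 0.70) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  if (!length(sequences)) return(list())
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("sequences must be named by id", call. = FALSE)
  }
  ord <- order(-nchar(sequences), ids)
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_id <- clusters[[ci]]$representative
      if (pairwise_identity(sequences[[i]], sequences[[rep_id]]) >= threshold) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(representative = ids[i], members = ids[i])
    }
  }
  clusters
}

#' Filter candidate interaction partners down to off-pathway ones
#'
#' Applies the partner-filtering cascade to a table of interaction
#' edges:
#'
#' 1. edges below `confidence_min` are dropped (`low_confidence`);
#' 2. partners with more than `identity_max` sequence identity to any
#'    pathway protein are dropped (`identity_to_pathway`), and the
#'    surviving partners of each source are greedily clustered at
#'    `identity_max`, keeping one representative per cluster
#'    (`cluster_duplicate`);
#' 3. partners whose id is on the exclusion list — the stand-in for
#'    manual curation, e.g. the small-GTPase family — are dropped
#'    (`exclusion_list`).
#'
#' Every input partner of a source appears exactly once across the kept
#' and removed lists, with its removal reason.
#'
#' @param edges Data frame from [read_interaction_edges()] (columns
#'   `source_accession`, `partner_id`, `partner_sequence`,
#'   `confidence`).
#' @param pathway_sequences Named character vector of all pathway protein
#'   sequences.
#' @param exclusion_ids Character vector of partner ids to drop in the
#'   curation step.
#' @param confidence_min Minimum edge confidence.
#' @param identity_max Identity ceiling for both the pathway filter and
#'   the clustering (strictly-greater removes; clustering keeps one
#'   representative per `>= identity_max` cluster).
#' @return Named list (by source accession) of `"filtered_partner_set"`
#'   objects: `source_accession`, `kept` (partner ids) and `removed`
#'   (data frame `partner_id`, `reason`).
#' @export
filter_offpathway <- function(edges, pathway_sequences,
                              exclusion_ids = character(),
                              confidence_min = 0.9, identity_max = 0.70) {
  if (!length(pathway_sequences)) {
    stop("pathway sequence set must be non-empty", call. = FALSE)
  }
  sources <- unique(edges$source_accession)
  # Identity of each distinct partner to the pathway set is reused
  # across sources.
  partner_seqs <- edges$partner_sequence[!duplicated(edges$partner_id)]
  names(partner_seqs) <- edges$partner_id[!duplicated(edges$partner_id)]
  hits_pathway <- vapply(names(partner_seqs), function(pid) {
    for (ps in pathway_sequences) {
      if (pairwise_identity(partner_seqs[[pid]], ps) > identity_max) {
        return(TRUE)
      }
    }
    FALSE
  }, TRUE)

  out <- lapply(sources, function(src) {
    sub <- edges[edges$source_accession == src, , drop = FALSE]
    kept <- character()
    removed <- data.frame(partner_id = character(), reason = character())
    drop <- function(ids, reason) {
      removed <<- rbind(removed,
                        data.frame(partner_id = ids,
                                   reason = rep(reason, length(ids))))
    }
    low <- sub$confidence < confidence_min
    drop(sub$partner_id[low], "low_confidence")
    sub <- sub[!low, , drop = FALSE]

    to_pathway <- hits_pathway[sub$partner_id]
    drop(sub$partner_id[to_pathway], "identity_to_pathway")
    sub <- sub[!to_pathway, , drop = FALSE]

    if (nrow(sub) > 1L) {
      seqs <- setNames(sub$partner_sequence, sub$partner_id)
      clusters <- greedy_cluster(seqs, identity_max)
      dup <- unlist(lapply(clusters,
                           function(cl) setdiff(cl$members, cl$representative)))
      if (length(dup)) {
        drop(dup, "cluster_duplicate")
        sub <- sub[!(sub$partner_id %in% dup), , drop = FALSE]
      }
    }

    excl <- sub$partner_id %in% exclusion_ids
    drop(sub$partner_id[excl], "exclusion_list")
    kept <- sub$partner_id[!excl]

    structure(list(source_accession = src, kept = kept, removed = removed),
              class = "filtered_partner_set")
  })
  names(out) <- sources
  out
}

#' @export
print.filtered_partner_set <- function(x, ...) {
  cat(sprintf("<filtered_partner_set> %s: %d kept, %d removed\n",
              x$source_accession, length(x$kept), nrow(x$removed)))
  invisible(x)
}

#' Build the per-route off-pathway interaction report
#'
#' Tallies kept off-pathway partners per source protein and per route,
#' and lists every source with at least `min_partners` kept partners
#' together with its disorder metrics — the shape of the published
#' moonlighting report. Per-route totals count (source, partner) edges;
#' the number of unique partners per route is reported alongside since
#' several sources may share a partner. Route means and medians are over
#' all proteins annotated to the route (proteins with no surviving
#' partner count as zero).
#'
#' @param filtered List from [filter_offpathway()].
#' @param summaries Summaries ([summary_table()] shape or list) for the
#'   source proteins.
#' @param records List of [protein_record()] annotations supplying route
#'   and group labels.
#' @param min_partners Report-row threshold on kept partners.
#' @return List with `per_route` (data frame: route, n_edges,
#'   n_unique_partners, mean/median per protein) and `rows` (data frame
#'   of report rows sorted by descending partner count, then
#'   accession).
#' @export
interaction_report <- function(filtered, summaries, records,
                               min_partners = 5L) {
  df <- as_summary_df(summaries)
  acc <- vapply(records, `[[`, "", "accession")
  counts <- setNames(integer(length(acc)), acc)
  kept_by_src <- lapply(filtered, `[[`, "kept")
  for (src in names(kept_by_src)) {
    if (!src %in% acc) stop(sprintf("source '%s' is not annotated", src),
                            call. = FALSE)
    counts[src] <- length(kept_by_src[[src]])
  }

  per_route <- do.call(rbind, lapply(VT_ROUTES, function(route) {
    in_route <- vapply(records, function(r) route %in% r$routes, TRUE)
    if (!any(in_route)) return(NULL)
    accs <- acc[in_route]
    partners <- unique(unlist(kept_by_src[intersect(names(kept_by_src), accs)]))
    data.frame(route = route, n_proteins = length(accs),
               n_edges = sum(counts[accs]),
               n_unique_partners = length(partners),
               mean_per_protein = mean(counts[accs]),
               median_per_protein = median(counts[accs]))
  }))

  rows <- NULL
  hot <- names(counts)[counts >= min_partners]
  if (length(hot)) {
    rec_by_acc <- setNames(records, acc)
    rows <- do.call(rbind, lapply(hot, function(a) {
      s <- df[df$accession == a, , drop = FALSE]
      if (!nrow(s)) stop(sprintf("no summary for source '%s'", a),
                         call. = FALSE)
      r <- rec_by_acc[[a]]
      data.frame(accession = a, gene_name = r$name,
                 route = paste(r$routes, collapse = ";"),
                 n_offpathway = unname(counts[a]),
                 length = s$length,
                 disorder_content = s$disorder_content,
                 n_ldr30 = s$n_ldr_30, n_dbr = s$n_dbr,
                 dbr_residue_ratio = s$dbr_residue_ratio,
                 functional_group = r$functional_group)
    }))
    rows <- rows[order(-rows$n_offpathway, rows$accession), , drop = FALSE]
    rownames(rows) <- NULL
  }
  list(per_route = per_route, rows = rows)
}

#' Arithmetic over an off-pathway interaction report
#'
#' Totals and per-route/per-group tallies over a report table of the
#' [read_interaction_report()] shape. `subset_groups`/`subset_routes`
#' and `exclude_accessions` carve out sub-tallies such as the
#' single-chain clathrin adaptors (clathrin-route ASP rows minus the AP-2
#' complex subunits).
#'
#' @param report Data frame with at least `accession`, `route`,
#'   `n_offpathway`, `functional_group`.
#' @param subset_routes,subset_groups Optional filters for the subset
#'   tally.
#' @param exclude_accessions Accessions removed from the subset tally.
#' @return List with `total_interactions`, `n_proteins`,
#'   `per_route` (data frame route/n_proteins/n_interactions), and when a
#'   subset is requested, `subset_n_proteins` and
#'   `subset_interactions`.
#' @export
offpathway_totals <- function(report, subset_routes = NULL,
                              subset_groups = NULL,
                              exclude_accessions = character()) {
  out <- list(total_interactions = sum(report$n_offpathway),
              n_proteins = nrow(report))
  routes <- sort(unique(report$route))
  out$per_route <- do.call(rbind, lapply(routes, function(r) {
    sub <- report[report$route == r, , drop = FALSE]
    data.frame(route = r, n_proteins = nrow(sub),
               n_interactions = sum(sub$n_offpathway))
  }))
  if (!is.null(subset_routes) || !is.null(subset_groups) ||
      length(exclude_accessions)) {
    sub <- report
    if (!is.null(subset_routes)) {
      sub <- sub[sub$route %in% subset_routes, , drop = FALSE]
    }
    if (!is.null(subset_groups)) {
      sub <- sub[sub$functional_group %in% subset_groups, , drop = FALSE]
    }
    sub <- sub[!(sub$accession %in% exclude_accessions), , drop = FALSE]
    out$subset_n_proteins <- nrow(sub)
    out$subset_interactions <- sum(sub$n_offpathway)
  }
  out
}
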