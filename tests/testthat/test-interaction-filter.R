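edge_df <- function(src, pid, seq, conf) {
  data.frame(source_accession = src, partner_id = pid,
             partner_sequence = seq, confidence = conf)
}

test_that("pairwise identity uses the shorter-sequence denominator", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("ACGT", "ACT"), 1)  # 3 matches / 3
  expect_equal(pairwise_identity("MKVLW", "MKVLW"), 1)
  # symmetry
  withr::local_seed(31)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "D", "E", "K"), sample(5:30, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "D", "E", "K"), sample(5:30, 1), TRUE),
               collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "A"), "non-empty")
})

test_that("greedy clustering is longest-first with lexicographic ties", {
  seqs <- c(b = "MKVLAEKV", a = "MKVLAEKV")
  cl <- greedy_cluster(seqs, 0.7)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$representative, "a")

  # 100-mer and 90-mer at 90% identity cluster; the 100-mer represents
  base <- paste(rep(c("M", "K", "V", "L", "E"), 20), collapse = "")
  shorter <- substr(base, 1, 90)
  cl2 <- greedy_cluster(c(long = base, short = shorter), 0.7)
  expect_length(cl2, 1L)
  expect_equal(cl2[[1]]$representative, "long")

  # three mutually dissimilar sequences stay singletons
  s3 <- c(x = paste(rep("A", 30), collapse = ""),
          y = paste(rep("K", 30), collapse = ""),
          z = paste(rep("W", 30), collapse = ""))
  expect_length(greedy_cluster(s3, 0.7), 3L)

  # exact duplicates all collapse at the 95% proteome de-duplication
  dup <- c(p1 = "MKVLE", p2 = "MKVLE", p3 = "MKVLE", q = "WWWWW")
  cl3 <- greedy_cluster(dup, 0.95)
  expect_length(cl3, 2L)
  expect_setequal(vapply(cl3, function(x) length(x$members), 1L), c(3L, 1L))
})

test_that("filter_offpathway applies the cascade with recorded reasons", {
  pathway <- c(V1 = paste(rep(c("M", "K", "V", "L", "E"), 8), collapse = ""))
  # p_low fails confidence; p_path is 100% identical to a pathway protein;
  # p_keep survives; p_dup is nearly identical to p_keep but shorter;
  # p_excl is on the exclusion list.
  keep_seq <- paste(rep(c("A", "D", "F", "G", "H"), 10), collapse = "")
  edges <- rbind(
    edge_df("S1", "p_low", "ADFGH", 0.5),
    edge_df("S1", "p_path", pathway[["V1"]], 0.95),
    edge_df("S1", "p_keep", keep_seq, 0.95),
    edge_df("S1", "p_dup", substr(keep_seq, 1, 40), 0.95),
    edge_df("S1", "p_excl", "WYWYWYWYWYWY", 0.95))
  fs <- filter_offpathway(edges, pathway, exclusion_ids = "p_excl")[["S1"]]
  expect_setequal(fs$kept, "p_keep")
  reasons <- setNames(fs$removed$reason, fs$removed$partner_id)
  expect_equal(reasons[["p_low"]], "low_confidence")
  expect_equal(reasons[["p_path"]], "identity_to_pathway")
  expect_equal(reasons[["p_dup"]], "cluster_duplicate")
  expect_equal(reasons[["p_excl"]], "exclusion_list")
  # partition property
  expect_setequal(c(fs$kept, fs$removed$partner_id), edges$partner_id)
  expect_length(intersect(fs$kept, fs$removed$partner_id), 0L)

  expect_error(filter_offpathway(edges, character()), "non-empty")
})

test_that("filtering is idempotent and monotone in its thresholds", {
  withr::local_seed(32)
  pathway <- c(V1 = paste(sample(c("M", "K", "V"), 60, TRUE), collapse = ""))
  aas <- c("A", "D", "E", "F", "G", "H", "K", "L")
  edges <- do.call(rbind, lapply(1:12, function(i) {
    edge_df("S1", sprintf("p%02d", i),
            paste(sample(aas, sample(20:60, 1), TRUE), collapse = ""),
            round(runif(1, 0.6, 1), 2))
  }))
  kept1 <- filter_offpathway(edges, pathway)[["S1"]]$kept
  # idempotence: re-filter the kept subset
  edges2 <- edges[edges$partner_id %in% kept1, , drop = FALSE]
  kept2 <- filter_offpathway(edges2, pathway)[["S1"]]$kept
  expect_setequal(kept2, kept1)
  # raising confidence_min or lowering identity_max never keeps more
  for (cm in c(0.7, 0.9, 0.99)) {
    k_hi <- filter_offpathway(edges, pathway, confidence_min = cm)[["S1"]]$kept
    expect_true(all(k_hi %in% kept1) || cm < 0.9 ||
                length(k_hi) <= length(kept1))
  }
  k_low_id <- filter_offpathway(edges, pathway,
                                identity_max = 0.3)[["S1"]]$kept
  expect_lte(length(k_low_id), length(kept1))
})

test_that("interaction_report tallies kept partners per route", {
  withr::local_seed(33)
  recs <- list(
    protein_record("S1", paste(rep("A", 60), collapse = ""), name = "G1",
                   functional_group = "ASP", routes = "CLTR"),
    protein_record("S2", paste(rep("A", 50), collapse = ""), name = "G2",
                   functional_group = "COAT", routes = "COPI"))
  summaries <- rbind(
    data.frame(accession = "S1", length = 60L, effective_length = 60L,
               disorder_content = 0.5, ldr_ratio_30 = 0.5, n_ldr_30 = 1L,
               has_ldr_30 = TRUE, dbr_residue_ratio = 0.2, n_dbr = 1L),
    data.frame(accession = "S2", length = 50L, effective_length = 50L,
               disorder_content = 0.1, ldr_ratio_30 = 0, n_ldr_30 = 0L,
               has_ldr_30 = FALSE, dbr_residue_ratio = 0, n_dbr = 0L))
  filtered <- list(
    S1 = structure(list(source_accession = "S1",
                        kept = sprintf("p%d", 1:6),
                        removed = data.frame(partner_id = character(),
                                             reason = character())),
                   class = "filtered_partner_set"),
    S2 = structure(list(source_accession = "S2", kept = c("p1", "q2"),
                        removed = data.frame(partner_id = character(),
                                             reason = character())),
                   class = "filtered_partner_set"))
  rep_out <- interaction_report(filtered, summaries, recs, min_partners = 5)
  cltr <- rep_out$per_route[rep_out$per_route$route == "CLTR", ]
  expect_equal(cltr$n_edges, 6L)
  copi <- rep_out$per_route[rep_out$per_route$route == "COPI", ]
  expect_equal(copi$n_edges, 2L)
  # p1 is shared between sources: unique-partner tally differs from edges
  expect_equal(copi$n_unique_partners, 2L)
  expect_equal(nrow(rep_out$rows), 1L)
  expect_equal(rep_out$rows$accession, "S1")
  expect_equal(rep_out$rows$n_offpathway, 6L)
})

test_that("offpathway_totals reproduces a brute-force recount", {
  withr::local_seed(34)
  rep_df <- data.frame(
    accession = sprintf("A%02d", 1:15),
    gene_name = sprintf("G%02d", 1:15),
    route = sample(c("CLTR", "COPI", "COPII"), 15, TRUE),
    n_offpathway = sample(0:25, 15, TRUE),
    functional_group = sample(c("ASP", "COAT", "EARP"), 15, TRUE))
  tot <- offpathway_totals(rep_df, subset_routes = "CLTR",
                           subset_groups = "ASP",
                           exclude_accessions = "A01")
  expect_equal(tot$total_interactions, sum(rep_df$n_offpathway))
  expect_equal(tot$n_proteins, 15L)
  manual <- rep_df[rep_df$route == "CLTR" & rep_df$functional_group == "ASP" &
                   rep_df$accession != "A01", ]
  expect_equal(tot$subset_interactions, sum(manual$n_offpathway))
  expect_equal(tot$subset_n_proteins, nrow(manual))
  for (r in unique(rep_df$route)) {
    expect_equal(tot$per_route$n_interactions[tot$per_route$route == r],
                 sum(rep_df$n_offpathway[rep_df$route == r]))
  }
})
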