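tse_fixture <- function() read_tse_table(extdata("tse_human.tsv"))

test_that("select_tses applies the switch-score threshold to coding exons", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    transcript_id = paste0("t", 1:4),
                    switch_score = c(0.24, 0.25, 0.9, 0.9),
                    route = "CLTR", functional_group = "ASP",
                    coding = c(TRUE, TRUE, TRUE, FALSE),
                    protein_start = 1L, protein_end = 10L)
  expect_message(sel <- select_tses(tab), "non-coding")
  expect_equal(sel$gene, c("g2", "g3"))  # 0.24 is below the boundary

  withr::local_seed(41)
  tab2 <- data.frame(gene = sprintf("g%d", 1:50), transcript_id = "t",
                     switch_score = round(runif(50), 2), route = "CLTR",
                     functional_group = "ASP", coding = TRUE,
                     protein_start = 1L, protein_end = 10L)
  sel2 <- select_tses(tab2, min_switch = 0.5)
  expect_equal(sel2$gene, tab2$gene[tab2$switch_score >= 0.5])
})

test_that("exon-to-protein mapping follows the codon-majority rule", {
  # exon 2 spans CDS bases 11-30 -> residues 4-10 by hand enumeration
  span <- map_exon_to_protein(c(10, 20, 15), 2)
  expect_equal(c(span$start, span$end), c(4L, 10L))

  # single-exon CDS of 30 bases -> residues 1-10
  span2 <- map_exon_to_protein(30, 1)
  expect_equal(c(span2$start, span2$end), c(1L, 10L))

  # a 1-base exon contributes no residue under the majority rule
  span3 <- map_exon_to_protein(c(9, 1, 11), 2)
  expect_equal(nrow(span3), 0L)
  expect_true(attr(span3, "empty_span"))

  # trailing partial codon warns
  expect_warning(map_exon_to_protein(c(10, 10), 1), "multiple of 3")
  expect_error(map_exon_to_protein(c(10, 20), 3), "out of range")
})

test_that("consecutive exon spans tile the protein without overlap", {
  withr::local_seed(42)
  for (rep in 1:20) {
    n_res <- sample(20:200, 1)
    n_exons <- sample(2:6, 1)
    cuts <- sort(sample(seq_len(3 * n_res - 1), n_exons - 1))
    lens <- diff(c(0L, cuts, 3L * n_res))
    covered <- integer()
    for (e in seq_len(n_exons)) {
      span <- map_exon_to_protein(lens, e)
      if (nrow(span)) covered <- c(covered, span$start:span$end)
    }
    expect_false(any(duplicated(covered)))
    # under the majority rule, the only residues no exon can claim are
    # those whose codon is split one base each across three exons
    exon_of_base <- rep(seq_len(n_exons), lens)
    three_way <- vapply(seq_len(n_res), function(r) {
      length(unique(exon_of_base[(3 * r - 2):(3 * r)])) == 3L
    }, TRUE)
    expect_setequal(covered, seq_len(n_res)[!three_way])
  }
})

test_that("tse_disorder counts disordered residues inside the span", {
  mask <- apply_tm_mask(c(rep(TRUE, 16), rep(FALSE, 20), rep(TRUE, 10)))
  full <- tse_disorder(segments(1, 36), mask)
  expect_equal(full$fraction, 16 / 36)
  expect_equal(formatC(100 * full$fraction, format = "f", digits = 2),
               "44.44")
  expect_equal(tse_disorder(segments(1, 16), mask)$fraction, 1)
  expect_equal(tse_disorder(segments(17, 36), mask)$fraction, 0)

  # TM residues leave numerator and denominator; fully excluded span flags
  masked <- apply_tm_mask(rep(TRUE, 30), segments(11, 20))
  part <- tse_disorder(segments(6, 20), masked)
  expect_equal(part$n_countable, 5L)
  gone <- tse_disorder(segments(11, 20), masked)
  expect_false(gone$defined)
  expect_true(is.na(gone$fraction))
})

test_that("whole-protein tse_disorder equals disorder_content", {
  withr::local_seed(43)
  len <- 150
  scores <- runif(len)
  p <- protein_record("X", paste(rep("A", len), collapse = ""),
                      tm_segments = segments(40, 60))
  s <- summarize_protein(p, score_track(scores))
  d <- tse_disorder(segments(1, len), s$mask)
  expect_equal(d$fraction, s$disorder_content)
})

test_that("DBR association separates overlap from the 5-residue flank", {
  # published boundary cases
  a <- tse_dbr_association(segments(667, 674), segments(649, 666))
  expect_equal(nrow(a$overlapping), 0L)
  expect_equal(nrow(a$flank_only), 1L)
  b <- tse_dbr_association(segments(333, 341), segments(342, 352))
  expect_equal(nrow(b$flank_only), 1L)
  cc <- tse_dbr_association(segments(255, 269), segments(246, 270))
  expect_equal(nrow(cc$overlapping), 1L)
  expect_equal(nrow(cc$flank_only), 0L)
  # a DBR 6 residues upstream is out of reach at flank = 5
  d <- tse_dbr_association(segments(100, 120), segments(80, 93))
  expect_equal(nrow(d$overlapping) + nrow(d$flank_only), 0L)

  # widening the flank never shrinks the associated set
  withr::local_seed(44)
  for (i in 1:20) {
    span <- segments(50, 70)
    dbrs <- segments(sample(1:100, 5), sample(101:140, 5))
    sizes <- vapply(c(0, 5, 10, 25), function(fl) {
      x <- tse_dbr_association(span, dbrs, fl)
      nrow(x$overlapping) + nrow(x$flank_only)
    }, 1L)
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("tse_structure + tse_report pool residue counts correctly", {
  # two 10-residue exons, 9 and 0 disordered -> pooled 45%
  masks <- list(
    A1 = apply_tm_mask(c(rep(TRUE, 9), rep(FALSE, 11))),
    A2 = apply_tm_mask(rep(FALSE, 20)))
  summaries <- lapply(names(masks), function(a) {
    structure(list(accession = a, mask = masks[[a]],
                   dbr_segments = segments()), class = "disorder_summary")
  })
  names(summaries) <- names(masks)
  tses <- data.frame(gene = c("g1", "g2"), transcript_id = c("t1", "t2"),
                     accession = c("A1", "A2"), switch_score = 0.9,
                     route = c("CLTR", "COPI;COPII"),
                     functional_group = "ASP", coding = TRUE,
                     protein_start = c(1L, 1L), protein_end = c(10L, 10L),
                     cds_exon_lengths = NA, tse_exon_index = NA)
  rows <- tse_structure(tses, summaries)
  rep_out <- tse_report(rows, proteome_disorder_reference = 0.2281)
  expect_equal(rep_out$pooled_disorder, 0.45)
  expect_equal(rep_out$total_residues, 20L)
  # the multi-route exon counts once per route
  expect_setequal(rep_out$per_route$route, c("CLTR", "COPI", "COPII"))
  expect_equal(rep_out$per_route$n_tses[rep_out$per_route$route == "COPI"], 1L)
  # reference flag
  expect_equal(rep_out$rows$more_disordered_than_reference, c(TRUE, FALSE))
})

test_that("the bundled TSE table parses and matches its recorded annotations", {
  tab <- tse_fixture()
  expect_equal(nrow(tab), 26L)
  expect_true(all(tab$coding))
  expect_true(all(tab$switch_score >= 0.25))
  gga1 <- tab[tab$gene == "GGA1", ][1, ]
  expect_equal(c(gga1$protein_start, gga1$protein_end), c(278L, 313L))
  tmed2 <- tab[tab$gene == "TMED2", ]
  expect_equal(strsplit(tmed2$route, ";")[[1]], c("COPI", "COPII"))
})
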