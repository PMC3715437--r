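# Cohort-level summaries and tests. Summaries are built directly as
# summary_table()-shaped frames where the per-protein machinery is not
# under test.

fake_summaries <- function(dc, dbr = rep(0, length(dc)),
                           ldr30 = rep(0, length(dc)),
                           has30 = ldr30 > 0, has50 = rep(FALSE, length(dc)),
                           has100 = rep(FALSE, length(dc)),
                           acc = sprintf("P%03d", seq_along(dc))) {
  data.frame(accession = acc, length = 200L, effective_length = 200L,
             disorder_content = dc,
             ldr_ratio_30 = ldr30, n_ldr_30 = as.integer(has30),
             has_ldr_30 = has30,
             ldr_ratio_50 = 0, n_ldr_50 = 0L, has_ldr_50 = has50,
             ldr_ratio_100 = 0, n_ldr_100 = 0L, has_ldr_100 = has100,
             dbr_residue_ratio = dbr, n_dbr = 0L)
}

test_that("group_summary computes means and midpoint medians per label", {
  df <- fake_summaries(c(0.10, 0.20, 0.30, 0.1, 0.2, 0.3, 0.4))
  grouping <- setNames(c(rep("g3", 3), rep("g4", 4)), df$accession)
  gs <- group_summary(df, grouping)
  g3 <- gs[gs$group_label == "g3", ]
  expect_equal(g3$n_proteins, 3L)
  expect_equal(g3$mean_dc, 0.20)
  expect_equal(g3$median_dc, 0.20)
  g4 <- gs[gs$group_label == "g4", ]
  expect_equal(g4$median_dc, 0.25)  # even-n midpoint convention

  expect_error(group_summary(df, setNames(rep("g", 6), df$accession[-1])),
               "no group label")
})

test_that("group_summary recovers a planted cohort mean", {
  withr::local_seed(21)
  dc <- pmin(1, pmax(0, rnorm(100, 0.28, 0.05)))
  df <- fake_summaries(dc)
  gs <- group_summary(df, setNames(rep("cohort", 100), df$accession))
  expect_lt(abs(gs$mean_dc - 0.28), 0.015)
})

test_that("ldr_prevalence counts proteins with LDRs per k", {
  has30 <- c(rep(TRUE, 6), rep(FALSE, 4))
  df <- fake_summaries(rep(0.5, 10), has30 = has30)
  pr <- ldr_prevalence(df, setNames(rep("g", 10), df$accession))
  expect_equal(pr$frac_ldr_30, 0.6)
  expect_equal(pr$frac_ldr_50, 0)
  expect_equal(pr$frac_ldr_100, 0)
  # prevalences non-increasing in k by construction of has_ldr
  expect_true(pr$frac_ldr_30 >= pr$frac_ldr_50 &&
              pr$frac_ldr_50 >= pr$frac_ldr_100)
})

test_that("rank_sum_test matches hand-enumerated exact p-values", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), "less")$p_value, 1 / 6)
  expect_equal(rank_sum_test(1:3, 4:6, "two_sided")$p_value, 0.10)
  deg <- rank_sum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("rank_sum_test equals exhaustive enumeration for small tie-free samples", {
  withr::local_seed(22)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    if (n2 < 1) next
    vals <- sample(seq_len(50), n1 + n2)  # tie-free
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(rank_sum_test(a, b, alt)$p_value,
                   ranksum_enum(a, b, alt),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d %s", n1, n2, alt))
    }
  }
})

test_that("enrichment_test matches direct hypergeometric summation", {
  expect_equal(enrichment_test(0, 10, 50, 100, "greater")$p_value, 1)
  expect_equal(enrichment_test(5, 10, 50, 100, "greater")$p_value,
               hyper_enum(5, 10, 50, 100, "greater"))
  # group fully flagged, background none flagged outside the group:
  # p collapses to 1 / C(n_background, n_group)
  p <- enrichment_test(6, 6, 6, 40, "greater", exclude_group = TRUE)$p_value
  expect_equal(p, 1 / choose(40, 6))

  withr::local_seed(23)
  for (i in 1:60) {
    n_b <- sample(20:400, 1)
    n_g <- sample(5:min(100, n_b), 1)
    k_b <- sample(0:n_b, 1)
    k_g <- sample(0:n_g, 1)
    for (alt in c("greater", "less")) {
      expect_equal(enrichment_test(k_g, n_g, k_b, n_b, alt)$p_value,
                   hyper_enum(k_g, n_g, k_b, n_b, alt),
                   tolerance = 1e-9)
    }
  }
  expect_error(enrichment_test(5, 100, 20, 50), "background smaller")
})

test_that("enrichment tails overlap at the observed value", {
  withr::local_seed(24)
  for (i in 1:30) {
    n_b <- sample(20:200, 1); n_g <- sample(2:20, 1)
    k_b <- sample(0:n_b, 1); k_g <- sample(0:n_g, 1)
    pg <- enrichment_test(k_g, n_g, k_b, n_b, "greater")$p_value
    pl <- enrichment_test(k_g, n_g, k_b, n_b, "less")$p_value
    expect_gte(pg + pl, 1 - 1e-9)
  }
})

test_that("compare_pathways detects a planted route contrast", {
  withr::local_seed(25)
  dc <- c(pmin(1, pmax(0, rnorm(30, 0.28, 0.08))),
          pmin(1, pmax(0, rnorm(30, 0.09, 0.08))))
  df <- fake_summaries(dc, has30 = dc > 0.3)
  grouping <- setNames(rep(c("CLTR", "COPI"), each = 30), df$accession)
  bg <- list(n = 20213, n_with_ldr = c(`30` = 9217, `50` = 6693,
                                       `100` = 3675))
  res <- compare_pathways(df, grouping, bg)
  rs <- res$rank_sum[res$rank_sum$metric == "disorder_content", ]
  expect_lt(rs$p_value, 0.01)
  expect_equal(nrow(res$enrichment), 6L)  # 2 routes x 3 k
  expect_true(all(c("p_value", "p_bh") %in% names(res$enrichment)))
  expect_error(compare_pathways(df, grouping, list(n = 100)), "background")
})

test_that("compare_pathways power is monotone in the planted effect size", {
  withr::local_seed(26)
  power_at <- function(delta) {
    mean(replicate(40, {
      dc1 <- pmin(1, pmax(0, rnorm(30, 0.15 + delta, 0.08)))
      dc2 <- pmin(1, pmax(0, rnorm(30, 0.15, 0.08)))
      rank_sum_test(dc1, dc2)$p_value < 0.05
    }))
  }
  pw <- vapply(c(0, 0.08, 0.2), power_at, 1)
  expect_true(all(diff(pw) >= 0))
})

test_that("a group at the background rate shows no one-sided enrichment", {
  p <- enrichment_test(5, 10, 500, 1000, "greater")$p_value
  expect_gt(p, 0.4)
})

test_that("the highly-disordered selection rule applies either criterion", {
  df <- fake_summaries(c(0.75, 0.40, 0.10, 0.2, 0.15),
                       ldr30 = c(0.10, 0.55, 0.05, 0.0, 0.0))
  sel <- select_highly_disordered(df)
  expect_true(sel$selected[1])   # >= 70% disorder content
  expect_true(sel$selected[2])   # LDR ratio >= 50% absolute cut-off
  expect_false(sel$selected[3])
  # cut-off is min(mean + 2 sd, 0.50) under the default reading
  expect_equal(unique(sel$ldr_cutoff),
               min(mean(df$ldr_ratio_30) + 2 * sd(df$ldr_ratio_30), 0.5))
  # the strict reading is available
  sel_max <- select_highly_disordered(df, cutoff_rule = "max")
  expect_equal(unique(sel_max$ldr_cutoff),
               max(mean(df$ldr_ratio_30) + 2 * sd(df$ldr_ratio_30), 0.5))
  expect_error(select_highly_disordered(df[1, , drop = FALSE]), "at least 2")
})

test_that("domain context classification labels structured islands", {
  # N-terminal domain, highly disordered remainder -> island_C
  withr::local_seed(27)
  flags <- c(rep(FALSE, 150), runif(450) < 0.9)
  mask <- apply_tm_mask(flags)
  dom <- data.frame(name = "ENTH", start = 1L, end = 150L)
  expect_equal(classify_domain_context(mask, dom)$context, "island_C")

  # central domain with ordered flanks -> embedded
  mask2 <- apply_tm_mask(c(rep(FALSE, 100), rep(TRUE, 20), rep(FALSE, 100)))
  dom2 <- data.frame(name = "D", start = 101L, end = 120L)
  expect_equal(classify_domain_context(mask2, dom2)$context, "embedded")

  # central domain flanked by long disordered arms on both sides
  mask3 <- apply_tm_mask(c(rep(TRUE, 300), rep(FALSE, 120), rep(TRUE, 300)))
  dom3 <- data.frame(name = "Sec16", start = 301L, end = 420L)
  expect_equal(classify_domain_context(mask3, dom3)$context, "island_both")

  # short disordered flank does not qualify
  mask4 <- apply_tm_mask(c(rep(TRUE, 10), rep(FALSE, 200)))
  dom4 <- data.frame(name = "D", start = 11L, end = 210L)
  expect_equal(classify_domain_context(mask4, dom4)$context, "embedded")

  expect_warning(
    classify_domain_context(mask3, data.frame(name = c("a", "b"),
                                              start = c(301L, 310L),
                                              end = c(420L, 430L))),
    "overlapping")
})
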