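# StringDB-style ingest, coverage filtering, aggregation, one-sample
# tests, BH adjustment, redundancy resolution, overlap matrices.

write_stringdb <- function(rows, path) {
  header <- paste("category", "term ID", "term description",
                  "observed gene count", "background gene count",
                  "matching proteins in your network (labels)", sep = "\t")
  writeLines(c(header, rows), path)
}

test_that("StringDB parsing splits labels and validates counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stringdb(c(
    "GO Process\tT01\talpha\t5\t10\tP1,P2,P3,P4,P5",
    "KEGG\tT02\tbeta\t3\t20\tP1, P2,P6"
  ), path)
  rec <- parse_stringdb_table(path)
  expect_identical(nrow(rec), 2L)
  expect_length(rec$matching_labels[[1]], 5)
  expect_identical(rec$matching_labels[[2]], c("P1", "P2", "P6"))

  # count disagreement triggers a recount with a warning naming the line
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_stringdb("GO Process\tT01\talpha\t4\t10\tP1,P2", path2)
  expect_warning(rec2 <- parse_stringdb_table(path2), "line")
  expect_identical(rec2$observed_gene_count, 2L)

  # missing required column is a format error naming it
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("category\tterm ID", "KEGG\tT01"), path3)
  expect_error(parse_stringdb_table(path3), "background gene count")
})

test_that("ontology filter enforces the source whitelist and 25% coverage", {
  rec <- make_records(list(T1 = paste0("P", 1:5), T2 = paste0("P", 1:4),
                           T3 = paste0("P", 1:5)),
                      sources = c("GO Process", "KEGG", "Pfam"))
  rec$background_gene_count <- c(20L, 20L, 5L)
  out <- filter_ontologies(rec)
  # 5/20 = 25% retained at the boundary; 4/20 dropped; Pfam dropped outright
  expect_setequal(out$term_id, "T1")
  expect_equal(out$coverage_pct, 25)
})

test_that("one-sample t-test matches the closed form and flags degeneracy", {
  res <- ontology_t_test(c(1, 2, 3))
  expect_equal(res$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)
  sym <- ontology_t_test(c(-1, 0, 1))
  expect_equal(sym$t_statistic, 0, tolerance = 1e-12)
  expect_equal(sym$p_value, 1, tolerance = 1e-12)
  flat <- ontology_t_test(c(0.5, 0.5, 0.5))
  expect_false(flat$testable)
  expect_true(is.na(flat$p_value))
})

test_that("aggregation averages members present in each fold-change table", {
  rec <- make_records(list(T1 = c("P1", "P2", "P2"), T2 = c("P3", "P9")))
  ab <- tibble::tibble(protein_id = c("P1", "P2", "P3"),
                       fc_scaled = c(0.2, 0.4, -1))
  tu <- tibble::tibble(protein_id = "P1", fc_scaled = 5)
  out <- aggregate_fcs(rec, ab, tu)
  t1 <- out[out$term_id == "T1", ]
  expect_equal(t1$mean_abundance_fc, 0.3, tolerance = 1e-12)  # duplicates dropped
  expect_identical(t1$n_abundance, 2L)
  expect_equal(t1$mean_turnover_fc, 5)
  expect_identical(t1$n_turnover, 1L)
  t2 <- out[out$term_id == "T2", ]
  expect_identical(t2$n_abundance, 1L)
  expect_false(t2$testable)  # single member: untestable, flagged not errored
  # member ordering does not change the means
  rec_shuffled <- make_records(list(T1 = c("P2", "P2", "P1")))
  expect_equal(aggregate_fcs(rec_shuffled, ab, tu)$mean_abundance_fc, 0.3,
               tolerance = 1e-12)
  # a term with no quantified member is dropped with a reason
  rec0 <- make_records(list(T9 = "P99"))
  out0 <- aggregate_fcs(rec0, ab)
  expect_identical(nrow(out0), 0L)
  expect_identical(attr(out0, "dropped_terms"), "T9")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  # brute-force step-up oracle: sort ascending, take running minima of
  # m p_(j) / j from the largest p down, cap at 1
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 1
    for (i in rev(seq_len(m))) {
      running <- min(running, m * p[o[i]] / i)
      adj[o[i]] <- running
    }
    adj
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  expect_identical(bh_adjust(0.7), 0.7)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in seq_len(1000)) {
    p <- runif(sample(1:40, 1))
    a <- bh_adjust(p)
    expect_lt(max(abs(a - bh_brute(p))), 1e-12)
    expect_true(all(a >= p))
    expect_true(all(diff(a[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))
})

test_that("redundancy resolution keeps the largest term per cluster", {
  members <- list(T_big = paste0("P", 1:30), T_small = paste0("P", 1:12),
                  T_lone = paste0("Q", 1:8))
  rec <- make_records(members)
  summaries <- tibble::tibble(
    term_id = names(members),
    n_abundance = c(30L, 12L, 8L),
    significant = TRUE
  )
  out <- resolve_redundancy(summaries, rec)
  # 12/12 of the smaller set shared -> clustered; size 30 represents
  expect_true(out$representative[out$term_id == "T_big"])
  expect_false(out$representative[out$term_id == "T_small"])
  expect_true(out$representative[out$term_id == "T_lone"])
  expect_identical(out$cluster[out$term_id == "T_big"],
                   out$cluster[out$term_id == "T_small"])

  # three-way tie on size: lexicographically first of the largest wins
  members3 <- list(T_b = paste0("P", 1:10), T_a = paste0("P", 1:10),
                   T_c = paste0("P", 1:8))
  rec3 <- make_records(members3)
  sum3 <- tibble::tibble(term_id = names(members3),
                         n_abundance = c(10L, 10L, 8L), significant = TRUE)
  out3 <- resolve_redundancy(sum3, rec3)
  expect_identical(out3$term_id[out3$representative %in% TRUE], "T_a")

  # disjoint significant terms each represent themselves
  rec_d <- make_records(list(A = "P1", B = "P2"))
  sum_d <- tibble::tibble(term_id = c("A", "B"), n_abundance = c(1L, 1L),
                          significant = TRUE)
  expect_true(all(resolve_redundancy(sum_d, rec_d)$representative))

  # non-significant terms are left unflagged
  sum_ns <- dplyr::mutate(sum_d, significant = FALSE)
  expect_true(all(is.na(resolve_redundancy(sum_ns, rec_d)$representative)))
})

test_that("overlap matrix reports row-normalized shared percentages", {
  rec <- make_records(list(A = paste0("P", 1:4), B = c("P1", "P2")))
  m <- overlap_matrix(rec)
  expect_equal(diag(m), c(A = 100, B = 100))
  expect_equal(m["A", "B"], 50)
  expect_equal(m["B", "A"], 100)
  msym <- overlap_matrix(rec, normalize = "min")
  expect_equal(msym["A", "B"], 100)
  rec_d <- make_records(list(A = "P1", B = "P2"))
  expect_equal(overlap_matrix(rec_d)["A", "B"], 0)
  expect_error(overlap_matrix(make_records(list(A = "P1"))), "two terms")
})
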