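toy_table <- function() {
  ab <- matrix(c(
    100, 90, NA, NA,    # P1: exclusive to w/o N
    50, NA, 60, NA,     # P2: one replicate in each condition
    10, 20, 30, 40,     # P3: everywhere
    NA, NA, 5, 6        # P4: exclusive to w/ N
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("P", 1:4),
                  c("M1 w/o N", "M2 w/o N", "M1 w/ N", "M2 w/ N")))
  protein_table(ab)
}

toy_map <- setNames(rep(c("w/o N", "w/ N"), each = 2),
                    c("M1 w/o N", "M2 w/o N", "M1 w/ N", "M2 w/ N"))

test_that("within-sample ranking: most abundant is rank 1, ties averaged", {
  expect_equal(rank_within_sample(c(A = 10, B = 5, C = 1)),
               c(A = 1, B = 2, C = 3))
  expect_equal(rank_within_sample(c(A = 5, B = 5, C = 2)),
               c(A = 1.5, B = 1.5, C = 3))
  expect_equal(rank_within_sample(c(A = 5, B = 5, C = 2), ties = "competition"),
               c(A = 1, B = 1, C = 3))
  expect_equal(rank_within_sample(c(X = 3)), c(X = 1))
  expect_length(rank_within_sample(numeric(0)), 0)
  expect_error(rank_within_sample(c(A = 1, B = NA)), "ND")
})

test_that("ranking is the exact inverse-sort permutation on distinct abundances", {
  set.seed(11)
  for (n in c(5, 50, 1000)) {
    x <- setNames(sample(seq_len(10 * n), n), paste0("L", seq_len(n)))
    r <- rank_within_sample(x)
    # sort-based brute-force oracle
    expect_equal(unname(r[order(-x)]), seq_len(n))
    expect_equal(sort(unname(r)), seq_len(n))
    expect_equal(sum(r), n * (n + 1) / 2)
  }
})

test_that("ranking is invariant under strictly monotone transforms", {
  set.seed(2)
  x <- setNames(rlnorm(100), paste0("L", 1:100))
  r <- rank_within_sample(x)
  expect_equal(rank_within_sample(log(x)), r)
  expect_equal(rank_within_sample(x^3), r)
  expect_equal(rank_within_sample(exp(x / max(x))), r)
})

test_that("rank summaries give per-condition mean/SD, ND, and single-replicate flags", {
  ab <- matrix(c(10, 14, NA, NA), nrow = 1,
               dimnames = list("P1", names(toy_map)))
  # build a table where P1 has ranks 10 and 14: pad with filler proteins
  filler <- matrix(rep(seq(1000, 1, length.out = 20), 4), ncol = 4,
                   dimnames = list(paste0("F", 1:20), names(toy_map)))
  # place P1 so that its abundance ranks 10th and 14th in the two samples
  # (9 resp. 13 filler proteins above it)
  tab <- protein_table(rbind(P1 = c(filler[10, 1] + 0.5, filler[13, 2] - 0.5, NA, NA),
                             filler))
  s <- summarize_ranks(tab, toy_map)
  p1 <- s[s$locus_tag == "P1" & s$condition == "w/o N", ]
  expect_equal(p1$mean_rank, 12)
  expect_equal(p1$sd_rank, abs(10 - 14) / sqrt(2), tolerance = 1e-12)  # sample SD, n = 2
  expect_equal(p1$detected_replicates, 2L)

  s_half <- summarize_ranks(tab, toy_map, sd_method = "half_range")
  expect_equal(s_half$sd_rank[s_half$locus_tag == "P1" &
                                s_half$condition == "w/o N"], 2)

  p1_nd <- s[s$locus_tag == "P1" & s$condition == "w/ N", ]
  expect_true(is.na(p1_nd$mean_rank))          # ND in the other condition
  expect_equal(p1_nd$detected_replicates, 0L)

  s2 <- summarize_ranks(toy_table(), toy_map)
  p2 <- s2[s2$locus_tag == "P2" & s2$condition == "w/o N", ]
  expect_true(p2$single_replicate)
  expect_equal(p2$sd_rank, 0)

  expect_error(summarize_ranks(toy_table(), c(bogus = "w/o N")), "unknown sample")
})

test_that("exclusive proteins require full detection in A and none in B", {
  s <- summarize_ranks(toy_table(), toy_map)
  expect_equal(exclusive_proteins(s, "w/o N", "w/ N"), "P1")
  expect_equal(exclusive_proteins(s, "w/ N", "w/o N"), "P4")
  # P2 (one replicate each side) is in neither strict list
  expect_length(intersect(exclusive_proteins(s, "w/o N", "w/ N"),
                          exclusive_proteins(s, "w/ N", "w/o N")), 0)
  # relaxed threshold admits single-replicate detections
  expect_setequal(exclusive_proteins(s, "w/o N", "w/ N", min_detected = 1), "P1")
  expect_error(exclusive_proteins(s, "nope", "w/ N"), "absent")
})

test_that("synthetic tables plant an exactly recoverable exclusive set", {
  syn <- synthesize_protein_tables(n_proteins = 300, n_exclusive = 25,
                                   n_replicates = 2, seed = 99L)
  s <- summarize_ranks(syn$table, syn$condition_map)
  got <- exclusive_proteins(s, "w/o N", "w/ N")
  expect_identical(got, syn$exclusive)
  expect_length(exclusive_proteins(s, "w/ N", "w/o N"), 0)

  none <- synthesize_protein_tables(n_proteins = 100, n_exclusive = 0, seed = 5L)
  s0 <- summarize_ranks(none$table, none$condition_map)
  expect_length(exclusive_proteins(s0, "w/o N", "w/ N"), 0)

  again <- synthesize_protein_tables(n_proteins = 300, n_exclusive = 25,
                                     n_replicates = 2, seed = 99L)
  expect_identical(syn$table$abundance, again$table$abundance)

  expect_error(synthesize_protein_tables(n_proteins = 10, n_exclusive = 11),
               "exceed")
})

test_that("protein tables round-trip through CSV", {
  syn <- synthesize_protein_tables(n_proteins = 40, n_exclusive = 5, seed = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_protein_table(syn$table, path)
  back <- read_protein_table(path)
  expect_equal(back$abundance, syn$table$abundance)
  expect_equal(back$psm, syn$table$psm)
  expect_equal(back$confidence, syn$table$confidence)
})

test_that("reference normalization rescales abundances but not ranks", {
  syn <- synthesize_protein_tables(n_proteins = 50, n_exclusive = 0, seed = 8L)
  ref <- syn$table$locus_tags[1]
  norm <- normalize_to_reference(syn$table, ref)
  expect_equal(norm$abundance[ref, ], rep(1, 4), ignore_attr = TRUE)
  expect_equal(duofilm:::rank_matrix(norm), duofilm:::rank_matrix(syn$table))
  expect_error(normalize_to_reference(syn$table, "NOPE"), "not in table")
})

test_that("the ranking report mirrors the published layout", {
  syn <- synthesize_protein_tables(n_proteins = 20, n_exclusive = 3, seed = 4L)
  rep_ <- ranking_report(syn$table, syn$condition_map)
  expect_true(all(c("locus_tag", "rank_w/o N", "rank_w/ N") %in% names(rep_)))
  excl_rows <- rep_[rep_$locus_tag %in% syn$exclusive, ]
  expect_true(all(excl_rows[["rank_w/ N"]] == "ND"))
  expect_true(all(grepl("±", excl_rows[["rank_w/o N"]])))
})

test_that("invalid protein tables are rejected", {
  ab <- matrix(1:4, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  expect_error(protein_table(ab), "unique")
  ab2 <- matrix(c(0, 1, 2, 3), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(protein_table(ab2), "> 0")
})
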