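make_hits <- function(e, cov, ids = paste0("h", seq_along(e))) {
  data.frame(subject_id = ids, e_value = e, query_coverage = cov,
             percent_identity = 50, stringsAsFactors = FALSE)
}

test_that("hit filtering applies both cutoffs and preserves order", {
  p <- curation_params()
  expect_equal(filter_hits(make_hits(1e-25, 50), p), "h1")     # both pass
  expect_equal(filter_hits(make_hits(1e-10, 90), p), character(0))  # e-value fails
  # 6 hits: 2 fail coverage, 1 fails e-value -> 3 survive
  hits <- make_hits(e = c(1e-30, 1e-25, 1e-5, 1e-40, 1e-22, 1e-21),
                    cov = c(80,    20,   85,   90,    35,    41))
  expect_equal(filter_hits(hits, p), c("h1", "h4", "h6"))
  # duplicate subject ids collapse to first occurrence
  dup <- make_hits(e = c(1e-30, 1e-30), cov = c(80, 80), ids = c("h1", "h1"))
  expect_equal(filter_hits(dup, p), "h1")
})

test_that("hit filtering is monotone under cutoff relaxation", {
  set.seed(21)
  hits <- make_hits(e = 10^stats::runif(40, -40, -5),
                    cov = stats::runif(40, 0, 100))
  strict <- filter_hits(hits, curation_params(e_max = 1e-25, cov_min = 60))
  relaxed_e <- filter_hits(hits, curation_params(e_max = 1e-20, cov_min = 60))
  relaxed_cov <- filter_hits(hits, curation_params(e_max = 1e-25, cov_min = 40))
  expect_true(all(strict %in% relaxed_e))
  expect_true(all(strict %in% relaxed_cov))
  expect_true(all(relaxed_e %in% hits$subject_id))
})

test_that("dedupe collapses exact duplicates to the first-seen record", {
  seqs <- homolog_set(id = c("a", "b", "c"),
                      sequence = c("MKVL", "MKVL", "MRRW"))
  out <- dedupe(seqs)
  expect_equal(out$id, c("a", "c"))
  distinct <- homolog_set(id = c("x", "y"), sequence = c("MKVL", "MRRW"))
  expect_equal(nrow(dedupe(distinct)), 2)
  # output size equals number of distinct sequence strings
  set.seed(31)
  pool <- vapply(1:4, function(i) random_seq(12), character(1))
  draw <- sample(pool, 10, replace = TRUE)
  hs <- homolog_set(id = paste0("s", 1:10), sequence = draw)
  expect_equal(nrow(dedupe(hs)), length(unique(draw)))
})

test_that("pairwise identity uses the shorter-sequence denominator and is symmetric", {
  expect_equal(pairwise_identity("MKVLRR", "MKVLRR"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("MKVLRR", "MKVL"), 1.0)  # 4 matches / 4
  set.seed(41)
  for (i in 1:5) {
    a <- random_seq(sample(8:30, 1)); b <- random_seq(sample(8:30, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "MK"), "empty")
})

test_that("greedy clustering matches the exhaustive oracle on small random sets", {
  seqs <- homolog_set(id = c("a", "b"), sequence = c("MKVLW", "MKVLW"))
  expect_equal(nrow(greedy_cluster(seqs, 0.8)), 1)
  far <- homolog_set(id = c("a", "b"), sequence = c("AAAAA", "CCCCC"))
  expect_equal(nrow(greedy_cluster(far, 0.8)), 2)

  set.seed(51)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    # families of mutated copies so identities straddle the threshold
    base <- random_seq(30)
    seqs <- vapply(seq_len(n), function(i) {
      chars <- strsplit(base, "", fixed = TRUE)[[1]]
      k <- sample(0:12, 1)
      if (k > 0) {
        idx <- sample(length(chars), k)
        chars[idx] <- sample(c("A", "C", "D", "E", "G"), k, replace = TRUE)
      }
      paste(chars, collapse = "")
    }, character(1))
    hs <- homolog_set(id = paste0("s", seq_len(n)), sequence = seqs)
    thr <- 0.8
    reps <- greedy_cluster(hs, thr)
    oracle <- oracle_greedy(hs, thr)
    expect_setequal(reps$id, oracle$founder_ids)
    expect_identical(attr(reps, "clusters")[oracle$order_ids], oracle$assign)
    # every member is within threshold of its founder; founders mutually apart
    assign <- attr(reps, "clusters")
    for (id in names(assign)) {
      if (id != assign[id]) {
        expect_gt(pairwise_identity(hs$sequence[hs$id == id],
                                    hs$sequence[hs$id == assign[id]]), thr)
      }
    }
  }
})

test_that("representative count is non-increasing as the threshold relaxes", {
  set.seed(61)
  base <- random_seq(25)
  seqs <- vapply(1:7, function(i) {
    chars <- strsplit(base, "", fixed = TRUE)[[1]]
    idx <- sample(25, sample(2:10, 1))
    chars[idx] <- sample(c("A", "C", "D"), length(idx), replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  hs <- homolog_set(id = paste0("s", 1:7), sequence = seqs)
  counts <- vapply(c(0.95, 0.8, 0.6, 0.4, 0.2),
                   function(th) nrow(greedy_cluster(hs, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the full curation recipe chains the stages and records counts", {
  seqs <- homolog_set(
    id = paste0("s", 1:5),
    sequence = c("MKVLWENQ", "MKVLWENQ", "CCDEGNQW", "MKVLWENL", "WWNNQQEE")
  )
  hits <- data.frame(subject_id = paste0("s", 1:5),
                     e_value = c(1e-30, 1e-30, 1e-30, 1e-30, 1e-5),
                     query_coverage = c(80, 80, 80, 80, 90),
                     percent_identity = 50)
  out <- curate(hits, seqs, curation_params(), exclude = "s3")
  counts <- attr(out, "counts")
  expect_equal(unname(counts["filtered"]), 4)         # s5 fails e-value
  expect_equal(unname(counts["after_blocklist"]), 3)  # s3 excluded manually
  expect_equal(unname(counts["deduped"]), 2)          # s2 duplicates s1
  expect_equal(unname(counts["representatives"]), 1)  # s4 within 0.8 of s1
})
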