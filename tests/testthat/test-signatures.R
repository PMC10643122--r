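test_that("motif compilation implements the degenerate-pattern language", {
  m <- compile_motif("WxxGϕxϕ")
  expect_length(motif_matches(m, "WAAGLAV"), 1)      # L, V hydrophobic
  expect_length(motif_matches(m, "WAAGDAV"), 0)      # D not hydrophobic
  expect_length(motif_matches("[ST]P", "XTPX"), 1)   # bracketed set
  expect_length(motif_matches("hxxGhxh", "WAAGLAV"), 1)  # ASCII alias for the class
  expect_error(compile_motif("W*G"), "illegal symbol")
  expect_error(compile_motif("Wx"), "at least 3 characters")
  # overlapping matches are all reported
  expect_equal(motif_matches("AAA", "AAAAA"), 1:3)
})

test_that("anchors resolve to the match nearest the expected position", {
  up <- function(...) anchor_spec("probe", "WGW", ...)
  seq1 <- paste0(strrep("A", 119), "WGW", strrep("A", 50))
  hit <- find_anchor(seq1, up(expected_position = 100, search_window = 300))
  expect_equal(hit$start, 120)

  # matches at 90 and 130, expected 100 -> 90 wins (distance 10 < 30)
  seq2 <- paste0(strrep("A", 89), "WGW", strrep("A", 37), "WGW", strrep("A", 20))
  hit2 <- find_anchor(seq2, up(expected_position = 100))
  expect_equal(hit2$start, 90)

  # equidistant matches resolve toward the N terminus and are flagged
  seq3 <- paste0(strrep("A", 89), "WGW", strrep("A", 17), "WGW", strrep("A", 20))
  hit3 <- find_anchor(seq3, up(expected_position = 100))
  expect_equal(hit3$start, 90)
  expect_true(hit3$tie)

  expect_error(find_anchor(strrep("A", 50), up()), class = "anchor_not_found")
  # matches outside the window do not count
  seq4 <- paste0(strrep("A", 400), "WGW", "AAA")
  expect_error(find_anchor(seq4, up(expected_position = 10, search_window = 50)),
               class = "anchor_not_found")
  # manual override bypasses the search entirely
  hit4 <- find_anchor(strrep("A", 50), up(manual_position = 7))
  expect_equal(hit4$start, 7)
})

test_that("intervening residue counts exclude the boundary elements", {
  # upstream occupies 10-13, downstream starts at 20 -> 6 intervening
  s <- paste0(strrep("A", 9), "WGWC", "DEDEDE", "YWY", strrep("A", 10))
  up <- anchor_spec("up", "WGWC")
  down <- anchor_spec("down", "YWY")
  m <- intervening_length(s, up, down)
  expect_equal(m$length, 6)
  expect_equal(m$segment, "DEDEDE")

  # immediately adjacent anchors -> 0
  s0 <- paste0("AAA", "WGWC", "YWY", "AAA")
  expect_equal(intervening_length(s0, up, down)$length, 0)

  # out-of-order anchors are an error
  srev <- paste0("AAA", "YWY", "DDD", "WGWC", "AAA")
  expect_error(intervening_length(srev, up, down), "out of order")
})

test_that("intervening length is invariant under padding outside the anchor span", {
  core <- paste0("WGWC", "DEDEDEDEDE", "YWY")
  up <- anchor_spec("up", "WGWC")
  down <- anchor_spec("down", "YWY")
  for (pad in c(0, 5, 40)) {
    s <- paste0(strrep("A", pad), core, strrep("A", pad))
    expect_equal(intervening_length(s, up, down)$length, 10)
  }
})

test_that("inclusive interval lengths follow the residues a-b idiom", {
  expect_equal(interval_length(1048, 1082), 35)
  expect_equal(interval_length(7, 7), 1)
  expect_equal(interval_length(1791, 1907), 117)
  expect_error(interval_length(10, 9), ">=")
})

test_that("basic-patch scanning merges windows and trims to basic residues", {
  expect_equal(nrow(scan_basic_patches("AAAA")), 0)
  expect_equal(nrow(scan_basic_patches("AKR")), 0)  # shorter than the window
  p <- scan_basic_patches("AKRKA")
  expect_equal(nrow(p), 1)
  expect_equal(c(p$start, p$end), c(2, 4))
  p2 <- scan_basic_patches("RKHR")
  expect_equal(c(p2$start, p2$end), c(1, 4))
  # restricted basic set drops histidine-dependent patches
  p3 <- scan_basic_patches("AKHKA", patch_rule(basic_set = c("K", "R")))
  expect_equal(nrow(p3), 0)
})

test_that("patch scanner agrees with the brute-force window oracle", {
  set.seed(71)
  rule <- patch_rule()
  # enriched alphabet so patches actually occur
  alpha <- c("A", "G", "S", "K", "R", "H", "K", "R")
  for (i in 1:300) {
    s <- random_seq(sample(1:120, 1), alphabet = alpha)
    got <- scan_basic_patches(s, rule)
    want <- oracle_scan_patches(s)
    expect_identical(got$start, as.integer(want$start))
    expect_identical(got$end, as.integer(want$end))
  }
})

test_that("patch detection is monotone under rule relaxation", {
  set.seed(81)
  alpha <- c("A", "G", "K", "R", "N")
  covers <- function(runs, pos) any(runs$start <= pos & pos <= runs$end)
  for (i in 1:50) {
    s <- random_seq(40, alphabet = alpha)
    strict <- scan_basic_patches(s, patch_rule(min_basic = 3, basic_set = c("K", "R")))
    lower_min <- scan_basic_patches(s, patch_rule(min_basic = 2, basic_set = c("K", "R")))
    wider_set <- scan_basic_patches(s, patch_rule(min_basic = 3))
    if (nrow(strict) > 0) {
      for (r in seq_len(nrow(strict))) {
        expect_true(covers(lower_min, strict$start[r]))
        expect_true(covers(wider_set, strict$start[r]))
      }
    }
  }
})

test_that("region patch calls exclude anchor residues and give NA on anchor loss", {
  up <- anchor_spec("up", "WGWC")
  down <- anchor_spec("down", "YWY")
  planted <- paste0("AAA", "WGWC", "DEKRKDE", "YWY", "AAA")
  expect_true(region_has_patch(planted, up, down))
  # basic residues only inside the anchors themselves -> no patch
  up_basic <- anchor_spec("up", "KRKC")
  down_basic <- anchor_spec("down", "RKR")
  bare <- paste0("AAA", "KRKC", "DEDEDED", "RKR", "AAA")
  expect_false(region_has_patch(bare, up_basic, down_basic))
  # missing anchor -> NA, not FALSE
  expect_true(is.na(region_has_patch("AAAAAAAA", up, down)))
})

test_that("key-residue calls key on positions with the allowed sets", {
  specs <- list(key_residue_spec("P1", 1064, c("S", "T")),
                key_residue_spec("F", 1065, "F"),
                key_residue_spec("P2", 1074, c("S", "T")),
                key_residue_spec("P3", 1075, c("S", "T")))
  s <- strrep("A", 1100)
  substr(s, 1064, 1064) <- "S"
  substr(s, 1065, 1065) <- "F"
  substr(s, 1074, 1074) <- "T"
  substr(s, 1075, 1075) <- "S"
  out <- key_residue_presence(s, specs, loop_interval = c(1048, 1082))
  expect_true(all(out$present))
  # the phosphosites (positions 1064, 1074, 1075) all fall in the loop
  expect_equal(sum(c(1064, 1074, 1075) >= 1048 & c(1064, 1074, 1075) <= 1082), 3)
  expect_equal(out$count_in_interval, 4)  # F at 1065 is inside too

  mut <- s
  substr(mut, 1065, 1065) <- "A"
  expect_false(key_residue_presence(mut, specs)$present[["F"]])
  expect_error(key_residue_presence("MKV", specs), "beyond")
})

test_that("alignment-column mapping flags gaps at key positions", {
  aln <- msa(ids = c("ref", "hit", "gapped"),
             aligned = c("MK-VST", "MKAVST", "MKAV-T"))
  specs <- list(key_residue_spec("P1", 4, c("S", "T")),
                key_residue_spec("P2", 5, c("S", "T")))
  # ref residue 4 = S sits in column 5; residue 5 = T in column 6
  expect_equal(map_ref_to_column(aln, "ref", c(4, 5)), c(5, 6))
  out <- key_residue_presence_msa(aln, "hit", "ref", specs)
  expect_true(all(out$present))
  g <- key_residue_presence_msa(aln, "gapped", "ref", specs)
  expect_false(g$present[["P1"]])
  expect_true("P1" %in% g$flags)
  expect_error(map_ref_to_column(aln, "ref", 99), "beyond")
})

test_that("column frequencies normalise over non-gap residues", {
  aln <- msa(ids = paste0("s", 1:4), aligned = c("RR", "RR", "KR", "-R"))
  cf <- column_frequencies(aln)
  expect_equal(cf$freq[[1]][["R"]], 2 / 3)
  expect_equal(cf$freq[[1]][["K"]], 1 / 3)
  expect_equal(cf$gap_fraction[1], 1 / 4)
  expect_equal(cf$freq[[2]][["R"]], 1.0)
  # all-gap columns are marked, frequencies absent
  aln2 <- msa(ids = c("a", "b"), aligned = c("M-K", "M-R"))
  cf2 <- column_frequencies(aln2)
  expect_true(cf2$all_gap[2])
  expect_null(cf2$freq[[2]])
  # sums to 1 on random alignments
  set.seed(91)
  rows <- vapply(1:6, function(i) random_seq(30), character(1))
  cf3 <- column_frequencies(msa(paste0("r", 1:6), rows))
  sums <- vapply(cf3$freq, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("the most conserved window finds a planted invariant motif", {
  set.seed(101)
  n <- 12
  rows <- vapply(seq_len(n), function(i) random_seq(60), character(1))
  # plant an invariant hexamer at columns 31-36
  rows <- vapply(rows, function(r) {
    substr(r, 31, 36) <- "WGYWGY"
    r
  }, character(1), USE.NAMES = FALSE)
  cf <- column_frequencies(msa(paste0("s", 1:n), rows))
  win <- most_conserved_window(cf, 6)
  expect_equal(unname(win), c(31, 36))
  # k = column count -> full range
  full <- most_conserved_window(cf, 60)
  expect_equal(unname(full), c(1, 60))
  # ties resolve leftmost: identical rows make every window perfect
  cfu <- column_frequencies(msa(c("a", "b"), c("MKVLW", "MKVLW")))
  expect_equal(unname(most_conserved_window(cfu, 3)), c(1, 3))
})

test_that("measure_features builds the per-sequence table with NA on anchor loss", {
  spec <- family_spec(subst_rate = 0, seed = 15)
  fam <- gen_family(spec)
  segs <- family_measurement_segments(spec)
  tab <- measure_features(fam$records, segs)
  expect_equal(tab$id, fam$truth$id)
  expect_identical(tab$wd40_loop_len, fam$truth$wd40_loop_len)
  expect_identical(tab$corb_loop_len, fam$truth$corb_loop_len)
  expect_identical(tab$patch1_patch, fam$truth$patch1_patch)
  # a sequence with no anchors yields NA columns, not errors
  alien <- homolog_set("alien", strrep("A", 200))
  tab2 <- measure_features(alien, segs)
  expect_true(all(is.na(tab2$wd40_loop_len)))
  expect_true(is.na(tab2$patch1_patch))
})
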