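test_that("random pure-birth trees are binary, labeled and reproducible", {
  cherry <- gen_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_equal(cherry$Nnode, 1)

  t50 <- gen_tree(50, seed = 2)
  expect_equal(t50$Nnode, 49)  # binary: n - 1 internal nodes
  expect_true(all(t50$ufboot >= 50 & t50$ufboot <= 100))
  expect_true(all(t50$edge.length >= 0))

  a <- write_newick(gen_tree(20, seed = 9))
  b <- write_newick(gen_tree(20, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, write_newick(gen_tree(20, seed = 10))))
})

test_that("planted loop lengths are recovered exactly at zero substitution rate", {
  clades <- lrrksig:::.default_clades()
  for (cl in names(clades)) clades[[cl]]$loops$wd40_loop <- c(112L, 112L)
  spec <- family_spec(clades = clades, subst_rate = 0, seed = 5)
  fam <- gen_family(spec)
  segs <- family_measurement_segments(spec)
  tab <- measure_features(fam$records, segs)
  expect_true(all(tab$wd40_loop_len == 112))
  expect_identical(tab$corb_loop_len, fam$truth$corb_loop_len)
  expect_identical(tab$alphac_len, fam$truth$alphac_len)
})

test_that("patch planting probability 1 yields detection in every member", {
  clades <- lrrksig:::.default_clades()
  clades$LRRK2$patch_prob <- c(patch1 = 1, patch2 = 1, patch3 = 1)
  spec <- family_spec(clades = clades, subst_rate = 0, seed = 6)
  fam <- gen_family(spec)
  tab <- measure_features(fam$records, family_measurement_segments(spec))
  lrrk2 <- tab[tab$clade == "LRRK2", ]
  expect_true(all(lrrk2$patch1_patch))
  expect_true(all(lrrk2$patch2_patch))
  expect_true(all(lrrk2$patch3_patch))
})

test_that("a basic-free background yields zero false-positive patches", {
  spec <- family_spec(subst_rate = 0.05, seed = 7)  # default background excludes K/R/H
  fam <- gen_family(spec)
  tab <- measure_features(fam$records, family_measurement_segments(spec))
  truth <- fam$truth
  for (s in c("patch1", "patch2", "patch3")) {
    col <- paste0(s, "_patch")
    expect_identical(tab[[col]], truth[[col]])
  }
})

test_that("key residues planted in one clade are recovered through the alignment", {
  # background additionally excludes S/T/F so key calls cannot arise by chance
  bg <- c("A", "C", "D", "E", "G", "I", "L", "M", "N", "P", "Q", "V", "W", "Y")
  spec <- family_spec(subst_rate = 0, seed = 9, background = bg)
  fam <- gen_family(spec)
  tab <- measure_features(fam$records, family_measurement_segments(spec),
                          key_specs = NULL)
  # via direct positions: reference member is the first LRRK1 sequence
  ref_id <- fam$truth$id[fam$truth$clade == "LRRK1"][1]
  ref_row <- fam$truth[fam$truth$id == ref_id, ]
  keys <- lrrksig:::.default_keys()
  specs <- lapply(names(keys), function(k) {
    off <- keys[[k]]$offset
    # key position in the reference = corb upstream anchor end + offset
    pos <- ref_row$corb_loop_up + nchar(spec$segments$corb_loop$up) - 1L + off
    key_residue_spec(k, pos, keys[[k]]$allowed)
  })
  # every LRRK1 member, addressed through the true alignment, carries all keys
  for (id in fam$truth$id[fam$truth$clade == "LRRK1"]) {
    out <- key_residue_presence_msa(fam$msa, id, ref_id, specs)
    expect_true(all(out$present), info = id)
  }
  # a short-loop clade lacks them (gap or background residue at the column)
  for (id in fam$truth$id[fam$truth$clade == "Amoebozoa"][1:3]) {
    out <- key_residue_presence_msa(fam$msa, id, ref_id, specs)
    expect_false(any(out$present), info = id)
  }
})

test_that("family generation is bit-reproducible and truth-consistent", {
  s1 <- gen_family(family_spec(seed = 12))
  s2 <- gen_family(family_spec(seed = 12))
  expect_identical(s1$records$sequence, s2$records$sequence)
  expect_identical(s1$msa$aligned, s2$msa$aligned)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_identical(s1$truth, s2$truth)
  expect_identical(degap(s1$msa$aligned), s1$records$sequence)
  # anchors recorded in truth point at the planted instantiations
  spec <- family_spec(seed = 12)
  i <- 1
  up <- spec$segments$wd40_loop$up
  expect_equal(substr(s1$records$sequence[i], s1$truth$wd40_loop_up[i],
                      s1$truth$wd40_loop_up[i] + nchar(up) - 1L), up)
})

test_that("mass-event simulation honours the equilibrium fraction and the seed", {
  sets <- gen_mass_events(600, 100, n_events = 5000, monomer_kda = 225,
                          sd_kda = 20, replicates = 3, seed = 3)
  expect_length(sets, 3)
  p_true <- attr(sets, "true_p")
  expect_equal(p_true, equilibrium_fraction(600, 100)$p)
  # empirical dimer fraction within binomial 99% bounds
  for (ev in sets) {
    frac <- mean(ev$masses > 1.5 * 225)
    bounds <- stats::qbinom(c(0.005, 0.995), 5000, p_true) / 5000
    expect_gte(frac, bounds[1])
    expect_lte(frac, bounds[2])
  }
  # sd = 0 -> exactly two mass values
  noiseless <- gen_mass_events(600, 100, 500, 225, 0, 1, seed = 4)
  expect_setequal(unique(noiseless[[1]]$masses), c(225, 450))
  # determinism
  again <- gen_mass_events(600, 100, n_events = 5000, monomer_kda = 225,
                           sd_kda = 20, replicates = 3, seed = 3)
  expect_identical(sets[[2]]$masses, again[[2]]$masses)
})
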