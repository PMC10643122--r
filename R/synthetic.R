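# Synthetic protein-family and mass-event generators with planted ground
# truth, used to validate every analysis stage end to end.

#' Generate a random pure-birth tree with synthetic support values
#'
#' Yule (pure-birth) topology with the birth-process branch lengths, tip
#' labels `t1..tn`, and synthetic dual support values (SH-aLRT and
#' ultrafast bootstrap) drawn uniformly on \[50, 100\] for every internal
#' node. Bit-reproducible under `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return A `support_tree` (see [read_newick()]).
#' @export
gen_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree$shalrt <- round(stats::runif(tree$Nnode, 50, 100), 1)
  tree$ufboot <- round(stats::runif(tree$Nnode, 50, 100))
  tree$node.label <- paste0(tree$shalrt, "/", tree$ufboot)
  class(tree) <- c("support_tree", "phylo")
  tree
}

.default_segments <- function() {
  list(
    wd40_loop = list(up = "WPSNEVW", down = "FDNQWGC", patch = FALSE),
    corb_loop = list(up = "YGWNDQM", down = "WAAGLAV", patch = FALSE),
    alphac    = list(up = "ELMDNSF", down = "VQWGYPD", patch = FALSE),
    patch1    = list(up = "NWGDQAF", down = "CYPWNES", patch = TRUE),
    patch2    = list(up = "QGWFNDY", down = "PSWCEGN", patch = TRUE),
    patch3    = list(up = "DFWGNQC", down = "YEWNSPG", patch = TRUE)
  )
}

.default_keys <- function() {
  # offsets inside the COR-B loop mirror the reference spacing of the
  # phosphosites (P1, P2, P3) and the back-pocket Phe within a ~35-residue
  # autoinhibitory loop
  list(
    P1 = list(segment = "corb_loop", offset = 17L, allowed = c("S", "T")),
    F  = list(segment = "corb_loop", offset = 18L, allowed = "F"),
    P2 = list(segment = "corb_loop", offset = 27L, allowed = c("S", "T")),
    P3 = list(segment = "corb_loop", offset = 28L, allowed = c("S", "T"))
  )
}

.default_clades <- function() {
  list(
    LRRK1 = list(
      n = 12L,
      loops = list(wd40_loop = c(110L, 120L), corb_loop = c(30L, 40L),
                   alphac = c(30L, 36L), patch1 = c(8L, 14L),
                   patch2 = c(8L, 14L), patch3 = c(8L, 14L)),
      patch_prob = c(patch1 = 0, patch2 = 0, patch3 = 0),
      keys = c(P1 = "S", F = "F", P2 = "T", P3 = "S")
    ),
    LRRK2 = list(
      n = 12L,
      loops = list(wd40_loop = c(8L, 16L), corb_loop = c(14L, 18L),
                   alphac = c(18L, 24L), patch1 = c(8L, 14L),
                   patch2 = c(8L, 14L), patch3 = c(8L, 14L)),
      patch_prob = c(patch1 = 1, patch2 = 1, patch3 = 1),
      keys = c(P1 = NA, F = NA, P2 = NA, P3 = NA)
    ),
    LRRK3 = list(
      n = 10L,
      loops = list(wd40_loop = c(8L, 16L), corb_loop = c(28L, 38L),
                   alphac = c(30L, 36L), patch1 = c(8L, 14L),
                   patch2 = c(8L, 14L), patch3 = c(8L, 14L)),
      patch_prob = c(patch1 = 0, patch2 = 0, patch3 = 0),
      keys = c(P1 = NA, F = NA, P2 = NA, P3 = NA)
    ),
    LRRK4 = list(
      n = 8L,
      loops = list(wd40_loop = c(8L, 16L), corb_loop = c(30L, 40L),
                   alphac = c(18L, 24L), patch1 = c(8L, 14L),
                   patch2 = c(8L, 14L), patch3 = c(8L, 14L)),
      patch_prob = c(patch1 = 0, patch2 = 0, patch3 = 0),
      keys = c(P1 = NA, F = NA, P2 = NA, P3 = NA)
    ),
    Amoebozoa = list(
      n = 8L,
      loops = list(wd40_loop = c(8L, 16L), corb_loop = c(15L, 25L),
                   alphac = c(18L, 24L), patch1 = c(8L, 14L),
                   patch2 = c(8L, 14L), patch3 = c(8L, 14L)),
      patch_prob = c(patch1 = 0, patch2 = 0, patch3 = 0),
      keys = c(P1 = NA, F = NA, P2 = NA, P3 = NA)
    )
  )
}

#' Specification of a synthetic clade-structured protein family
#'
#' The default emulates a five-clade LRRK-like family: a long WD40 loop
#' and an extended (> 27 residue) COR-B loop carrying the key residues in
#' one clade, three planted basic patches in a second, an extended COR-B
#' loop alone in a third, and short segments elsewhere. Sequences follow
#' the template `flank + [anchor, loop, anchor, flank] per segment`; loop
#' lengths are drawn per clade from discrete uniform ranges.
#'
#' The background alphabet excludes basic residues by default so that no
#' basic patch can arise outside a planted one.
#'
#' @param clades named list of clade specs (`n`, `loops`, `patch_prob`,
#'   `keys`); see the default for the shape.
#' @param segments ordered named list of segment specs with literal
#'   anchor instantiations `up`/`down` and a `patch` flag marking the
#'   regions queried for basic patches.
#' @param keys named list of key-residue declarations
#'   (`segment`, `offset` within the loop, `allowed` set).
#' @param flank_len length of the random flank after each segment (and
#'   before the first).
#' @param background residues used for flanks and loop backgrounds.
#' @param subst_rate per-position substitution probability applied
#'   outside anchors and planted features.
#' @param seed integer RNG seed.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(clades = .default_clades(),
                        segments = .default_segments(),
                        keys = .default_keys(),
                        flank_len = 20L,
                        background = setdiff(setdiff(AA_ALPHABET, "X"),
                                             DEFAULT_BASIC),
                        subst_rate = 0.01,
                        seed = 1L) {
  for (seg in segments) {
    if (nchar(seg$up) < 3 || nchar(seg$down) < 3) {
      stop("anchor instantiations must be at least 3 residues", call. = FALSE)
    }
  }
  for (cl_name in names(clades)) {
    cl <- clades[[cl_name]]
    if (any(cl$patch_prob < 0 | cl$patch_prob > 1)) {
      stop("patch probabilities must be in [0, 1]", call. = FALSE)
    }
    for (s in names(cl$loops)) {
      rng <- cl$loops[[s]]
      if (rng[1] > rng[2]) stop("loop range lo > hi for ", s, call. = FALSE)
    }
    for (k in names(keys)) {
      if (!is.na(cl$keys[[k]])) {
        seg <- keys[[k]]$segment
        if (cl$loops[[seg]][1] < keys[[k]]$offset) {
          stop("clade ", cl_name, ": loop ", seg,
               " can be shorter than key-residue offset for ", k, call. = FALSE)
        }
      }
    }
  }
  if (subst_rate < 0 || subst_rate > 1) stop("subst_rate must be in [0, 1]", call. = FALSE)
  structure(list(clades = clades, segments = segments, keys = keys,
                 flank_len = as.integer(flank_len), background = background,
                 subst_rate = subst_rate, seed = as.integer(seed)),
            class = "family_spec")
}

.rand_res <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic family with planted ground truth
#'
#' Emits unaligned sequences, the true alignment (loops right-padded with
#' gaps to the family-wide maximum, so gap placement is known by
#' construction), a clade-structured tree, and a truth table holding the
#' planted segment lengths, patch calls, key residues and anchor
#' positions of every member. Deterministic under the spec's seed.
#'
#' @param spec a [family_spec()].
#' @return A list of class `family_sim`: `records` ([homolog_set()]),
#'   `msa` ([msa()]), `tree`, `truth` (`data.frame`), `clade_map`.
#' @export
gen_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  seg_names <- names(spec$segments)
  clade_names <- names(spec$clades)

  # clade subtrees joined on a pectinate backbone with full support
  subtrees <- lapply(seq_along(clade_names), function(ci) {
    cl <- spec$clades[[ci]]
    if (cl$n >= 2) {
      t <- gen_tree(cl$n, seed = spec$seed + ci)
      t$tip.label <- paste0(clade_names[ci], "_", seq_len(cl$n))
      sub("\\;$", "", write_newick(t))
    } else {
      paste0(clade_names[ci], "_1:1")
    }
  })
  nwk <- subtrees[[1]]
  if (length(subtrees) > 1) {
    for (i in 2:length(subtrees)) {
      nwk <- paste0("(", nwk, ":1,", subtrees[[i]], ":1)100/100")
    }
  }
  tree <- read_newick(paste0(nwk, ";"))

  set.seed(spec$seed)
  patch_rule_default <- patch_rule()
  members <- list()
  truth_rows <- list()
  # family-wide max loop length per segment is needed for gap padding;
  # draw all loop lengths first
  draw <- list()
  for (cl_name in clade_names) {
    cl <- spec$clades[[cl_name]]
    for (i in seq_len(cl$n)) {
      id <- paste0(cl_name, "_", i)
      lens <- vapply(seg_names, function(s) {
        rng <- cl$loops[[s]]
        rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
      }, integer(1))
      draw[[id]] <- list(clade = cl_name, lens = lens)
    }
  }
  max_len <- vapply(seg_names, function(s) {
    max(vapply(draw, function(d) d$lens[[s]], integer(1)))
  }, integer(1))

  seqs <- character(0)
  aligned <- character(0)
  ids <- character(0)
  clades_v <- character(0)
  for (id in names(draw)) {
    cl_name <- draw[[id]]$clade
    cl <- spec$clades[[cl_name]]
    lens <- draw[[id]]$lens
    plain <- .rand_res(spec$flank_len, spec$background)
    gapped <- plain
    pos <- nchar(plain)
    truth <- list(id = id, clade = cl_name)
    for (s in seg_names) {
      seg <- spec$segments[[s]]
      loop_len <- lens[[s]]
      loop <- strsplit(.rand_res(loop_len, spec$background), "", fixed = TRUE)[[1]]
      protected <- logical(loop_len)
      # plant a basic patch: a contiguous run of min_basic basic residues
      planted_patch <- FALSE
      if (isTRUE(seg$patch)) {
        prob <- cl$patch_prob[[s]]
        if (!is.null(prob) && stats::runif(1) < prob) {
          run <- patch_rule_default$min_basic
          start <- sample(seq_len(loop_len - run + 1L), 1L)
          loop[start:(start + run - 1L)] <-
            sample(patch_rule_default$basic_set, run, replace = TRUE)
          protected[start:(start + run - 1L)] <- TRUE
          planted_patch <- TRUE
        }
        truth[[paste0(s, "_patch")]] <- planted_patch
      }
      # plant key residues
      for (k in names(spec$keys)) {
        kd <- spec$keys[[k]]
        if (kd$segment == s) {
          res <- cl$keys[[k]]
          if (!is.na(res)) {
            loop[kd$offset] <- res
            protected[kd$offset] <- TRUE
            truth[[paste0(k, "_present")]] <- res %in% kd$allowed
          } else {
            truth[[paste0(k, "_present")]] <- FALSE
          }
        }
      }
      # point substitutions on unprotected loop positions
      if (spec$subst_rate > 0 && loop_len > 0) {
        hit <- stats::runif(loop_len) < spec$subst_rate & !protected
        if (any(hit)) {
          loop[hit] <- sample(spec$background, sum(hit), replace = TRUE)
        }
      }
      loop <- paste(loop, collapse = "")
      flank <- .rand_res(spec$flank_len, spec$background)
      truth[[paste0(s, "_len")]] <- loop_len
      truth[[paste0(s, "_up")]] <- pos + 1L
      truth[[paste0(s, "_down")]] <- pos + nchar(seg$up) + loop_len + 1L
      plain <- paste0(plain, seg$up, loop, seg$down, flank)
      gapped <- paste0(gapped, seg$up, loop,
                       strrep("-", max_len[[s]] - loop_len), seg$down, flank)
      pos <- pos + nchar(seg$up) + loop_len + nchar(seg$down) + nchar(flank)
    }
    ids <- c(ids, id)
    clades_v <- c(clades_v, cl_name)
    seqs <- c(seqs, plain)
    aligned <- c(aligned, gapped)
    truth_rows[[id]] <- as.data.frame(truth, stringsAsFactors = FALSE)
  }
  records <- homolog_set(id = ids, sequence = seqs,
                         species = paste("synthetic taxon", ids),
                         clade = clades_v)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(records = records,
                 msa = msa(ids, aligned),
                 tree = tree,
                 truth = truth,
                 clade_map = data.frame(id = ids, clade = clades_v,
                                        stringsAsFactors = FALSE)),
            class = "family_sim")
}

#' Measurement segment specs matching a family spec
#'
#' Builds the [anchor_spec()] pairs that the signatures stage needs to
#' re-measure a generated family: each segment's literal anchor
#' instantiations become literal motif patterns.
#'
#' @param spec a [family_spec()].
#' @return Named list of segments suitable for [measure_features()].
#' @export
family_measurement_segments <- function(spec = family_spec()) {
  out <- lapply(names(spec$segments), function(s) {
    seg <- spec$segments[[s]]
    list(upstream = anchor_spec(paste0(s, "_up"), seg$up),
         downstream = anchor_spec(paste0(s, "_down"), seg$down),
         scan_patches = isTRUE(seg$patch))
  })
  names(out) <- names(spec$segments)
  out
}

#' Simulate mass-photometry event sets from a monomer-dimer equilibrium
#'
#' The particle dimer fraction `p` comes from [equilibrium_fraction()];
#' each landing event is a dimer with probability `p`, and its measured
#' mass is Gaussian around the species mass. Deterministic under `seed`.
#'
#' @param kd dissociation constant, nM.
#' @param c_total total monomer-equivalent concentration, nM.
#' @param n_events events per replicate.
#' @param monomer_kda monomer mass, kDa.
#' @param sd_kda mass measurement noise s.d., kDa.
#' @param replicates number of independent replicates.
#' @param seed integer RNG seed.
#' @return A list of [mass_events()], one per replicate, with attribute
#'   `true_p` (the generating dimer fraction).
#' @export
gen_mass_events <- function(kd, c_total, n_events = 5000L, monomer_kda = 225,
                            sd_kda = 20, replicates = 3L, seed = 1L) {
  if (kd <= 0 || c_total <= 0 || n_events <= 0 || monomer_kda <= 0 ||
      sd_kda < 0 || replicates < 1) {
    stop("all generator parameters must be positive (sd_kda may be 0)",
         call. = FALSE)
  }
  p <- equilibrium_fraction(kd, c_total)$p
  set.seed(seed)
  sets <- lapply(seq_len(replicates), function(r) {
    dimer <- stats::runif(n_events) < p
    masses <- stats::rnorm(n_events, mean = monomer_kda * (1 + dimer),
                           sd = sd_kda)
    masses <- pmax(masses, .Machine$double.eps)
    mass_events(masses, c_total = c_total, replicate = r)
  })
  attr(sets, "true_p") <- p
  sets
}
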