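---
title: "Structural signatures and dimerization equilibria of LRRK-family proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural signatures and dimerization equilibria of LRRK-family proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrksig)
```

## The scientific problem

The LRRK (leucine-rich repeat kinase) family — LRRK1 and LRRK2 in
vertebrates, plus related clades in other metazoans and in Amoebozoa —
shares a common domain architecture (LRR, ROC GTPase, COR, kinase, WD40),
yet the two human paralogs are regulated very differently. Several of the
features that distinguish them are *lengths of variable segments between
conserved boundary elements*: a long, disordered WD40-domain loop; an
extended COR-B loop that threads into the kinase active site and plugs its
back pocket with a phenylalanine; an elongated αC helix in the kinase
N-lobe. Others are *short sequence signatures*: clusters of basic residues
("basic patches") in the ROC domain that mediate microtubule binding, and
the phosphosites in the COR-B loop whose modification relieves
autoinhibition. Finally, the oligomeric state matters: full-length LRRK1
forms an autoinhibited homodimer whose dissociation constant can be
estimated from single-particle mass-photometry measurements.

This package implements all of those measurements as a tested pipeline:
curation of a homolog set, motif-anchored segment-length measurement,
sliding-window basic-patch detection, key-residue calls, per-clade
summaries over a support-annotated phylogeny, and a Gaussian-mixture /
law-of-mass-action estimator of the dimerization Kd. A synthetic family
generator with planted ground truth closes the loop: every analysis stage
is validated against data whose true answer is known by construction.

The repository is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions,
writing their tables under `results/`. All computation lives in `R/` so
that tests and the reproduction script exercise exactly the code the
drivers run.

## Homolog-set curation

Curation mirrors the standard recipe for assembling a protein family from
homology searches:

1. **Significance/coverage filter** (`filter_hits()`): keep hits with
   e-value ≤ `e_max` (default 1 × 10⁻²⁰) and query coverage ≥ `cov_min`
   (default 40%). The coverage floor ensures retained homologs span the
   ROC–COR–kinase core rather than matching a single domain.
2. **Duplicate removal** (`dedupe()`): exact sequence duplicates collapse
   to the first-seen record.
3. **Greedy redundancy reduction** (`greedy_cluster()`): a CD-HIT-style
   scheme — sort by length descending (ties broken by id), each sequence
   joins the first representative with identity *strictly above* the
   threshold (default 0.8), otherwise founds a new cluster.

Pairwise identity is computed from a global alignment with match 1,
mismatch 0 and linear gap penalty −1 (the alignment is used only to locate
matched positions), divided by the **shorter** sequence's length. The
shorter-sequence denominator is the convention of greedy clustering tools:
a fragment fully contained in a longer sequence scores 1 and is absorbed.
The scoring scheme is deliberately minimal and fixed so results are
reproducible; with the default 0.8 threshold the clustering is insensitive
to reasonable variations of it.

Removal of "poorly aligning" sequences is inherently a judgment call, so
it is exposed as an explicit id blocklist (`curate(..., exclude = ...)`)
rather than an automatic criterion.

At desk scale the exhaustive pairwise scheme is quadratic; the bundled
analyses run on families of ~50 representatives, which completes in
seconds. Nothing in the implementation caps the family size.

## Motif-anchored segment measurement

Variable segments cannot be measured from a multiple alignment directly —
alignment programs place gaps arbitrarily inside disordered loops — so
lengths are measured between **boundary elements**: short, well-conserved
motifs flanking the segment. The motif language (`compile_motif()`) has
four token types: a literal residue, `x` (any residue), `ϕ` (hydrophobic
class, ASCII alias `h`), and a bracketed set such as `[ST]`. The
hydrophobic class defaults to {A, V, L, I, M, F, W, Y, C} and is
configurable; the canonical example is the `WxxGϕxϕ` element bounding the
COR-B loop on its C-terminal side.

`find_anchor()` resolves a motif to a position: all (possibly
overlapping) matches are enumerated; if an expected position is declared,
the match nearest to it within the search window wins, with equidistant
candidates resolved toward the N terminus (deterministic, and flagged).
The default window of ±300 residues is wide enough to absorb large
clade-specific offsets — the motivating case being a clade whose
C-terminal boundary element sits 200+ residues further from the N-terminal
element than in any other clade. For cases where even that fails, a
`manual_position` override bypasses the search entirely, mirroring
placement by inspection.

Two length conventions coexist and are pinned by tests:

- **Intervening length** (`intervening_length()`): residues *strictly
  between* the two boundary elements, excluding both. This is the unit of
  cross-homolog loop comparison.
- **Inclusive interval length** (`interval_length()`): `end − start + 1`,
  for explicitly numbered regions in the "residues a–b" idiom. The
  reference COR-B loop, residues 1,048–1,082, is 35 residues by this
  convention — satisfying both the >27-residue conservation bound and the
  ≥26-residue mechanistic bound for the back-pocket autoinhibition.

## Basic patches and key residues

A basic patch is ≥ `min_basic` basic residues within a sliding window of
`window` residues (defaults 3-in-4). The basic set defaults to
{K, R, H} — "basic amino acids" without further qualification — and can be
restricted to {K, R} for a stricter physiological reading; patch detection
is monotone under either relaxation, a property the tests assert.
`scan_basic_patches()` merges overlapping qualifying windows and trims
each merged run to span from its first to its last basic residue, so the
reported interval describes patch content rather than window framing.
Segments shorter than the window carry no patches by definition.
`region_has_patch()` applies the scanner to the segment between two
anchors; when an anchor cannot be found the call is `NA` — absence of
evidence, never coerced to `FALSE`.

Key residues (`key_residue_spec()`) are declared by *position* in a
reference numbering with an allowed residue set. The three COR-B
phosphosites are declared at positions 1064, 1074 and 1075 with allowed
set {S, T}: published descriptions disagree on which of the three is the
threonine, but agree on the positions, so the implementation keys on
positions and accepts either hydroxyl residue. The back-pocket
phenylalanine is `{F}` at 1065. Positions can be addressed directly or
mapped through an alignment column via the cumulative non-gap count of a
designated reference row; a gap at the mapped column yields `FALSE` plus
an explicit flag.

Consensus conservation is summarised by `column_frequencies()` (per-column
frequencies over non-gap residues, gap fraction reported separately,
all-gap columns marked) and `most_conserved_window()`, which maximises the
mean modal-residue frequency over a contiguous window, ties resolving to
the leftmost — the machinery used to locate the most conserved N-terminal
motif of a clade.

## Phylogeny annotation

Trees arrive as Newick with support labels; dual labels `"x/y"` are read
as (SH-aLRT, ultrafast bootstrap), single labels as ultrafast bootstrap
alone. The star convention for figures — one star above 75% support, two
stars at 100% — is implemented by `support_class()`, keyed to the
ultrafast-bootstrap value when both are present (that is the value the
display convention refers to); SH-aLRT values remain on the tree for
reporting. Whether the convention should fall back to SH-aLRT when the
two disagree is not defined anywhere authoritative; keying on UFboot is
this package's fixed choice.

Clade membership is user-declared (`clade_map`), not inferred: clades are
assigned by inspection of the tree, and the package's job is to summarise
features per declared clade (`clade_summary()`: counts, length
min/median/max, fraction exceeding a threshold, boolean fractions) and to
*check* each clade's monophyly rather than assume it. Summaries are
invariant to tip order and rotation. Trees are used as provided;
`root_on_outgroup()` offers explicit re-rooting on a named tip set, as
done on the only non-metazoan clade.

## Mass-photometry Kd estimation

Mass photometry yields one mass per particle-landing event; histogram
modes correspond to oligomeric species. The estimator is:

1. **Two-component Gaussian-mixture fit** (`fit_mass_mixture()`) by
   expectation–maximization. Initialization is deterministic: component
   `i` of `k` starts at the mass quantile `(i − 0.5)/k`, with equal
   weights and the pooled standard deviation. With histogram modes
   separated by a full monomer mass this initialization lands each
   component on the correct side of the valley, so no random restarts (and
   hence no seed) are needed; convergence is declared when the
   log-likelihood improves by < 1e-8 or after 500 iterations. Degenerate
   fits (weight < 1e-3 or s.d. < 0.1 kDa) are flagged and the consumer
   falls back to threshold classification at 1.5× the monomer mass.
2. **Dimer particle fraction** (`dimer_fraction()`): the weight of the
   component nearest twice the monomer mass (required within 25%
   relative). The fraction is by particle count — the quantity a
   landing-event histogram measures — not mass-weighted. Higher oligomers
   are ignored; the two-component model reflects a monomer/dimer system.
3. **Law-of-mass-action inversion** (`kd_from_fraction()`): for
   M + M ⇌ D with p = [D]/([M]+[D]) and C = [M] + 2[D],

   Kd = [M]²/[D] = C·(1−p)²/(p·(1+p)).

   p = 0 is an error ("no dimer observed, Kd unbounded"); p = 1 returns 0.

The forward model (`equilibrium_fraction()`) solves the same law for
given Kd and C: [M] = 2C/(1 + √(1 + 8C/Kd)) — the rationalised root,
which avoids the floating-point cancellation of the textbook
(√(1+x) − 1) form when 8C/Kd is small — and the tests assert that
inversion∘forward is the identity to 1e-9 relative error over a log grid,
with mass conservation [M] + 2[D] = C holding to the same tolerance.
At Kd = 600 nM and C = 100 nM the model gives [M] ≈ 79.1 nM,
[D] ≈ 10.4 nM, p ≈ 0.1165 — the regime of the reference assay, whose
estimate is 0.6 μM.

`estimate_kd()` chains the three steps per replicate and reports the
replicate mean. Per-replicate event counts and histogram binning are not
standardised anywhere; the simulations use 5,000 events per replicate and
3 replicates as a realistic single-measurement campaign, and the EM fit
operates on raw masses so no binning choice enters the estimate.

## The synthetic generator

`gen_family()` emits a clade-structured family in which every quantity the
pipeline measures is planted and recorded: sequences follow the template
`flank [anchor loop anchor flank] ...` per segment, loop lengths are drawn
per clade from discrete uniform ranges, basic patches are planted (as a
contiguous run of basic residues) with a per-clade probability, and key
residues are written at fixed loop offsets in the clades that carry them.
The default family mirrors the biological contrast under study: a
LRRK1-like clade with a ~110–120-residue WD40 loop, a 30–40-residue COR-B
loop and all four key residues; a LRRK2-like clade with short loops and
all three basic patches; a LRRK3-like clade sharing only the extended
COR-B loop; a LRRK4-like clade; and an Amoebozoa-like outgroup. Sizes
(12/12/10/8/8) keep the family at desk scale while giving each clade
enough members for fraction statistics.

Two choices keep the ground truth exact. First, the true alignment is
built by construction — loops are right-padded with gaps to the
family-wide maximum — rather than recomputed with an aligner, so gap
placement is known and de-gapping a row reproduces the member's sequence
exactly. Second, the background alphabet excludes basic residues by
default, so a basic patch can only exist where one was planted and
false-positive tests are clean. Point substitutions apply outside anchors
and planted features at a configurable rate (default 1%).

What the generator does **not** emulate: realistic substitution processes
(no LG/JTT-style models), indel evolution beyond the planted
variable-length loops, alignment error (the truth alignment is perfect by
construction), compositional bias, or anchor degeneration. Consequently,
passing recovery tests demonstrates that the measurement machinery is
correct *given findable anchors and a sane alignment*; it does not
demonstrate robustness to the alignment ambiguity of deeply diverged real
families — which is precisely why anchors are user-declared, overridable
and conservative in real use.

`gen_mass_events()` draws each particle as a dimer with the equilibrium
probability p and adds Gaussian mass error (default s.d. 20 kDa, a typical
instrument width at these masses). All generators are bit-reproducible
under their seed.

## Numerical and design choices

- Residue coordinates are 1-based and explicit intervals inclusive
  throughout; the two length conventions are documented above and pinned
  by tests.
- Gap characters: `'-'` canonical, `'.'` accepted on read and normalised,
  since both occur in common alignment dialects.
- Hit tables: both headered TSV and headerless BLAST-style tabular input
  are accepted (column indices configurable), since significance cutoffs,
  not file layouts, are the substance.
- Anchor tie-breaks are N-terminal and flagged; anchor failure propagates
  as `NA` measurements, never fabricated zeros.
- EM initialization is deterministic by quantiles (no jitter): restarts
  add nothing for well-separated mass modes, and removing randomness
  removes a reproducibility knob that would otherwise need reporting.
- The `curate → features → annotate → massphot` orchestration
  (`run_pipeline()`) validates its config before any stage runs, never
  mutates inputs, writes only under its output directory, and records a
  manifest with input md5 hashes, seed and per-stage counts; identical
  config and inputs give identical outputs.
- Problem sizes in the bundled analyses and tests — 50-member families,
  5,000 events × 3 replicates — are the package's chosen desk scale:
  large enough that fraction statistics and mixture fits are stable,
  small enough that the full suite runs in well under a minute.

## Known limitations

- Anchors must be declared by the user; there is no automatic discovery
  of well-aligning regions. This matches how such analyses are actually
  done (and audited), but means a new family requires expert input.
- The Kd estimator assumes a pure monomer–dimer system and a single
  assay concentration; titration-series fitting and higher-oligomer
  models are out of scope.
- Monophyly checks use the unrooted-tree sense for clades spanning the
  root when trees arrive unrooted; re-root explicitly with
  `root_on_outgroup()` when rooting matters.
- The identity scheme underlying clustering is fixed (match/mismatch/gap
  = 1/0/−1); it is not meant to reproduce any specific scoring matrix,
  only to give a stable, documented notion of percent identity.
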