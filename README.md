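# lrrksig

Comparative structural-signature analysis for the LRRK (leucine-rich
repeat kinase) protein family, and estimation of a homodimerization
dissociation constant from single-particle mass-photometry events.

## What it does, and for whom

LRRK1 and LRRK2 share a domain layout (LRR–ROC–COR–kinase–WD40) but are
regulated differently, and several of the features that distinguish them
are measurable directly from sequence once you know where to look:

- the length of variable segments (a long WD40-domain loop, an extended
  autoinhibitory COR-B loop, the αC-helix region) measured as the number
  of **intervening residues between conserved boundary motifs**;
- **basic patches** — ≥ 3 basic residues within a 4-residue window — in
  the ROC domain, which mediate microtubule binding in LRRK2;
- **key residues**: the phenylalanine that plugs the kinase back pocket
  and the three phosphosites in the COR-B loop;
- the distribution of all of the above across a **support-annotated
  phylogeny** of the family, summarised per clade.

Separately, full-length LRRK1 dimerizes, and mass photometry (one mass
per particle-landing event) lets you estimate the dimerization Kd: fit
two Gaussians to the mass histogram, read off the dimer particle fraction
p, and invert the law of mass action for M + M ⇌ D:

    p = [D] / ([M] + [D]),   C = [M] + 2[D],   Kd = [M]²/[D]
    ⇒  Kd = C · (1 − p)² / (p · (1 + p))

The package is aimed at molecular evolution / structural biology workflows
where these measurements need to be reproducible, testable and auditable
rather than done by hand in an alignment viewer. Every stage is validated
against a synthetic family generator that plants loops, patches and key
residues with known ground truth.

## Layout

- `R/` — the package: sequence/tree I/O (`read_fasta`, `read_newick`,
  `read_hit_table`), curation (`filter_hits`, `dedupe`, `greedy_cluster`,
  `curate`), signatures (`compile_motif`, `find_anchor`,
  `intervening_length`, `scan_basic_patches`, `key_residue_presence`,
  `measure_features`), phylogeny annotation (`support_class`,
  `annotate_tips`, `clade_summary`), mass photometry
  (`fit_mass_mixture`, `dimer_fraction`, `kd_from_fraction`,
  `equilibrium_fraction`, `estimate_kd`), synthetic data (`gen_tree`,
  `gen_family`, `gen_mass_events`) and orchestration (`run_pipeline`,
  `validate_config`).
- `analysis/` — numbered narrative drivers (`01_simulate_family.R` …
  `05_massphot.R`) that run the workflow end to end and write tables
  under `results/`.
- `vignettes/lrrk-signatures.Rmd` — the methods account: models,
  conventions, parameter defaults and their rationale, limitations.
- `tests/testthat/` — the test suite, including brute-force oracles for
  the patch scanner and the greedy clustering, and planted-truth
  recovery tests.

## Worked example

Estimate a dimerization Kd from simulated mass-photometry replicates at a
100 nM assay concentration (the bundled `analysis/05_massphot.R` driver):

```r
library(lrrksig)

eq <- equilibrium_fraction(kd = 600, c_total = 100)   # forward model, nM
# [M] = 79.13 nM, [D] = 10.44 nM, dimer particle fraction p = 0.1165

sets <- gen_mass_events(kd = 600, c_total = 100, n_events = 5000,
                        monomer_kda = 225, sd_kda = 20, replicates = 3,
                        seed = 505)
estimate_kd(sets, monomer_kda = 225)
```

```
Dimerization Kd estimate (monomer-dimer equilibrium)
  replicates: 3
  replicate 1: n = 5000, dimer fraction p = 0.1174, Kd = 593.8 nM
  replicate 2: n = 5000, dimer fraction p = 0.1128, Kd = 627.1 nM
  replicate 3: n = 5000, dimer fraction p = 0.1160, Kd = 603.6 nM
  pooled Kd: 608.2 nM = 0.61 uM
```

Each replicate's 5,000 particle masses are fitted with a two-component
Gaussian mixture; the dimer component's weight is the particle fraction
p, and the law-of-mass-action inversion turns (p, C) into a Kd. The
pooled estimate, 0.61 μM, recovers the generating 600 nM within 1.4%.

On the sequence side:

```r
s <- paste0("AAA", "WGWC", "DEKRKDE", "YWY", "AAA")   # anchors flank the loop
seg <- intervening_length(s, anchor_spec("up", "WGWC"),
                          anchor_spec("down", "YWY"))
seg$length                       # 7 intervening residues
scan_basic_patches(seg$segment)  # one patch: positions 3-5 (K R K)
interval_length(1048, 1082)      # 35 — the COR-B loop, "residues a-b" style
```

Running the five `analysis/` drivers in order simulates a 50-member,
five-clade family, curates it (duplicates and near-identical variants
removed: 55 → 50 representatives), measures every segment and patch
(100% agreement with planted truth), summarises the clades on the tree
(all five monophyletic; extended COR-B loops confined to the LRRK1/3/4-like
clades; all three basic patches only in the LRRK2-like clade), and writes
the Kd estimate above.

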