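# crefdual

Dual eigen-analysis of promoter cis-regulatory element frequency (CREF)
matrices in R.

## The problem

Closely related species (the textbook case: humans and the other great
apes) have nearly identical transcription factors, yet differ sharply in
regulatory phenotypes. Much of that difference lives in the *proximal
cis-regulatory sequence*: which motifs occur near each gene's
transcription start site, and how often. `crefdual` is for researchers
who want to analyse that layer quantitatively across species:

1. **Build** a genes x motifs count matrix `Ctilde` (the CREF matrix) by
   scanning 1501-bp promoter windows (1000 bp upstream to 500 bp
   downstream of the 5'-most TSS) with a PWM library, using MATCH-style
   information-weighted similarity scores (MSS/CSS) with configurable
   minFN/minFP thresholds.
2. **Decompose** it robustly, `Ctilde = C + S` with
   `min ||C||_* + lambda ||S||_1` solved by inexact augmented Lagrange
   multipliers (IALM), then SVD the low-rank part into polarized *dual
   eigen-modules* `(rho_k, u_k, v_k)` — a gene-eigenvector and a
   motif-eigenvector per level, level 0 being a skipped baseline.
3. **Quantify stability** through relative spectral gaps
   `d_k = (rho_k - rho_{k+1}) / rho_k` and first-order eigenvector
   perturbation theory (sensitivity grows like `1 / d_k`): a
   near-degenerate pair can rotate qualitatively — a *saltation* —
   under a small perturbation.
4. **Compare species** along motif-eigenvectors: sign-aligned Pearson
   correlations, Deming (errors-in-variables) fits, rotation angles
   within the reference 2-D eigen-plane, and a
   conserved / divergent / saltation call per level.
5. **Interpret modules** by one-sided Wilcoxon rank-sum enrichment of
   gene sets at eigenvector poles, and by transposable-element motif
   content: motifs present on repeat (Alu/SVA-like) consensus sequences
   (MPA), their pole counts per level, cross-species relative changes,
   Jaccard similarity of motif sets, and overlap of promoter windows
   with repeat insertions.

A first-class synthetic-data module generates every input — count
matrices with planted low-rank structure, sparse corruption and Poisson
count noise; matched species pairs with a planted eigenvector rotation;
promoter and repeat sequences with exactly planted motif occurrences;
gene sets with controllable pole enrichment — so the entire pipeline is
testable end to end without downloading a genome.

## Worked example

Two synthetic species differing by a planted 40-degree rotation of the
level-(2,3) motif-eigenvector pair sitting on a 2% spectral gap:

```r
library(crefdual)

base <- planted_model(1000, 120, spectrum = planted_spectrum(1000, 120, 4),
                      noise_model = "none", seed = 1)
scenario <- saltation_scenario(base, rotated_pair = c(2, 3),
                               rotation_deg = 40, gap_fraction = 0.02)
pair <- gen_species_pair(scenario)

dec_a <- decompose_cref(pair$a$cref, n_levels = 4)
dec_b <- decompose_cref(pair$b$cref, n_levels = 4)
compare_species(dec_a, dec_b, levels = 1:3)
```

```
  level     r sign_flipped slope intercept angle_deg out_of_plane    d_a    d_b
1     1 1.000         TRUE     1  9.64e-06  2.13e-04     4.49e-05 0.1007 0.0962
2     2 0.759         TRUE     1 -8.60e-06  4.06e+01     1.95e-04 0.0183 0.0203
3     3 0.759         TRUE     1  8.73e-06  4.03e-04     4.24e-01 0.1793 0.1833
      label
1 conserved
2 saltation
3 divergent
```

Level 1 is untouched: correlation 1, rotation ~0. Level 2 carries the
planted saltation: its correlation drops to 0.759 (= cos 40 degrees),
the recovered rotation is 40.6 degrees, its gap `d = 0.018` is
near-degenerate, and it is labelled `saltation`. Level 3, the other
member of the rotated pair, loses correlation too but sits on a wide gap
(0.18), hence `divergent`.

Gene sets planted at the positive pole of the level-2 gene-eigenvector
are detected by the rank-based Wilcoxon test, null sets are not:

```r
sets <- gen_gene_sets(module_at(dec_a, 2)$gene_vector, n_sets = 4,
                      strength = 1, set_size = 25, seed = 2)
enrich_all(dec_a, sets$sets, levels = 2, poles = "positive")
```

```
      set level     pole n_members n_unresolved statistic        p
1 set_001     2 positive        25            0     24112 3.08e-17
2 set_002     2 positive        25            0     23999 6.01e-17
3 set_003     2 positive        25            0      9188 9.82e-01
4 set_004     2 positive        25            0     10807 8.34e-01
```

The same stages run end to end from files (FASTA + GFF3 + TRANSFAC +
GMT + repeat FASTA) through `run_pipeline(cref_config(...))`, which
writes TSV outputs and a checksummed manifest; a thin command-line
wrapper lives in `inst/cli/cref.R`.

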