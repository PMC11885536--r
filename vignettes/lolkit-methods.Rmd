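---
title: "lolkit: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lolkit: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lolkit)
```

# The problem

In proteobacteria, lipoproteins destined for the outer membrane (OM) are
extracted from the inner membrane, carried across the periplasm by the
chaperone LolA, and inserted by the OM lipoprotein LolB. In Bacteroidota —
a phylum whose surface biology (Type IX secretion, gliding motility,
polysaccharide utilization) leans heavily on OM and surface lipoproteins —
the Lol components diverged so far that LolB escapes detection by sequence
similarity altogether. `lolkit` packages the in-silico strategy that works
anyway: two proteins that fold alike collect largely the same *structural
templates* in a profile/structure search, even when their sequences no
longer align. The package compares such template hit lists, classifies the
resulting candidates' signal peptides, profiles their physico-chemistry,
quantifies OM proteome perturbations in deletion mutants, and maps family
conservation across species.

`lolkit` deliberately consumes *tables*, not databases: hit lists from a
profile search, quantified label-free (LFQ) summaries, and homology-search
hit tables are inputs. Running the searches, predicting structures, and
quantifying spectra are out of scope, as are wet-lab readouts.

# Template-fingerprint discovery

For protein $p$ with hit list $\{(t, E_{p,t})\}$, the significant set at
cutoff $c$ is $S_c(p) = \{t : E_{p,t} \le c\}$, with $c = 10^{-3}$ by
default. Against a reference $r$, every proteome protein is scored by
$\mathrm{overlap} = |S_c(p) \cap S_c(r)|$ and
$\mathrm{Jaccard} = |S_c(p) \cap S_c(r)| / |S_c(p) \cup S_c(r)|$, ranked by
overlap, then Jaccard, then protein id — a deterministic total order.

Design choices worth knowing:

* **"Identical templates" is read permissively.** Selecting candidates
  "with identical templates" is ambiguous between set identity and
  non-empty intersection. The default is intersection
  (`min_overlap = 1`) because the point of the method is *distant*
  homologs, whose hit lists erode at the edges; strict identity remains
  recoverable through the `identical_sets` flag.
* **The cutoff is inclusive** ($\le c$), the usual convention; the boundary
  is unit-tested.
* **Both hit lists are thresholded by default.** Whether the original
  procedure thresholded one list or both is not recorded; thresholding both
  is symmetric and is the default, with `threshold_query = FALSE` available
  to compare the reference's significant set against full proteome lists.
* Duplicate (query, template) rows collapse to their minimum E-value.

The ranking is verified against an independent brute-force oracle that
materialises every pairwise intersection, over an exhaustive enumeration of
all subset assignments for small universes plus randomized proteomes up to
6 proteins × 8 templates.

# Signal-peptide classification

The classifier is a transparent, rule-based surrogate for neural
signal-peptide predictors, which cannot be embedded here. Rules live in one
object (`annotation_rules()`) shared with the sequence generator:

* **SPII (lipoprotein):** the lipobox `[LVIFMSTAG][ASTVIG][GAS]C` — the
  standard prokaryotic consensus — must lie entirely within residues
  10–40 (both motif start and the terminal Cys inside the window; the
  window semantics were an open choice and this is the one implemented).
  The leftmost match wins; the Cys is the cleavage position (first mature,
  lipidated residue).
* **SPI:** a 7-residue window in residues 1–35 with mean Eisenberg
  hydrophobicity ≥ 0.5 (the h-region), followed by an `A-x-A` cleavage
  motif within residues 15–45 and downstream of the h-region — a classical
  von Heijne-style rule. The first mature residue is the position after
  the motif.
* **Precedence SPII > SPI**, since lipoprotein signals also contain an
  h-region.
* Sequences shorter than 30 residues classify `NONE` with a warning;
  non-canonical residues are an error naming the position.

**LES (lipoprotein export signal).** Bacteroidota surface lipoproteins
carry an export signal immediately after the lipidated Cys. Its consensus
is not defined by this package's sources, so no biological default is
hard-coded: `les_pattern` is fully configurable, and the shipped value
(`"DSS"` within 10 residues after the Cys) is an explicitly *synthetic
placeholder* shared with the generator. Users annotating real proteomes
must supply the consensus for their organism.

# Physico-chemical profiling

All statistics are sequence- or residue-set level surrogates for
structure-based calculations (electrostatic surface mapping, per-structure
pKa) that are out of scope:

* **Hydrophobic set** = residues with positive Eisenberg normalized
  consensus value, tying the set to the published scale rather than an
  arbitrary list. Leu+Ile fraction is reported separately because strongly
  hydrophobic enrichment in these two residues is the discriminating
  signal between the Bacteroidota and proteobacterial Lol proteins; Lys and
  Arg fractions are reported because an Arg→Lys shift changes surface
  charge chemistry at equal net charge.
* **Net charge** is a Henderson–Hasselbalch sum over D, E, C, Y (negative)
  and K, R, H (positive) with a fixed textbook pKa table
  (`pka_table()`); termini (pKa 9.0 / 2.0) are off by default because
  profiles are typically computed on internal selections. Charge is
  monotone non-increasing in pH. One numerical caveat: within the allowed
  pH range `[0, 14]`, arginine (pKa 12.48) never fully deprotonates, so
  the high-pH limit $-|\{D,E,C,Y\}|$ is attained exactly only for Arg-free
  sequences; Arg's residual occupancy follows the closed form and is
  tested as such.
* **Gradient calls**: lipoprotein hand-off from chaperone to receptor is
  favoured "downhill" in hydrophobicity, so the call thresholds
  $\Delta h = h_{\mathrm{acceptor}} - h_{\mathrm{donor}}$ (hydrophobic
  fractions) against a neutral band $\varepsilon = 0.01$ — below typical
  composition sampling noise for domains of ≥ 100 residues
  ($\sqrt{0.25/100} = 0.05$ per profile, so a 0.01 band only suppresses
  ties, not signal). Swapping donor and acceptor maps FAVORABLE ↔
  UNFAVORABLE.
* **Selections are inputs.** Concave/convex cavity faces come from manual
  inspection of structural models; no residue lists can be derived here, so
  selections arrive as 1-based index sets (`"1-10,25"` or `ALL`) and the
  package computes nothing about 3-D surfaces.

# Differential abundance

LFQ summaries carry a linear fold change (mutant/WT) and either a p-value
or a significance score with $\mathrm{sig} = -10\log_{10}(p)$ (so the
conventional threshold 20 is exactly $p = 0.01$; both representations are
accepted and cross-checked to $10^{-6}$ when present together). The filter
keeps records with $\max(\mathrm{FC}, 1/\mathrm{FC}) \ge 1.5$ **and**
$\mathrm{sig} \ge 20$, inclusive:

* **Two-sided fold change** is forced by the biology: depleted proteins
  (FC < 1, e.g. mislocalized gliding-motility lipoproteins) count as
  significant, so the threshold applies to the max-ratio statistic.
* **No multiple-testing correction** is applied by the filter itself — it
  mirrors a fixed significance-score cutoff as used by LFQ suites — but
  `add_bh_adjustment()` provides a Benjamini–Hochberg column for users who
  want one.
* Tallies report counts per localization class, per-category up/down
  splits, and the no-signal share as an integer percentage rounded
  half-up, matching how such shares are reported (402 of 609 → 66%).

# Conservation profiling

Hits at E ≤ 0.001 are assigned to query families by smallest E-value; an
exact tie across families goes to the lexicographically first and is
flagged `ambiguous`. This deterministic rule replaces manual curation by
structure comparison and genomic-neighborhood inspection — it will not
reproduce curated homolog lists exactly, which is why ambiguous cases are
surfaced for review rather than silently resolved. The presence matrix
stores counts, not booleans, so multi-copy families (paralog expansions)
remain visible; presence is `count > 0`. Summaries report per-family
species coverage and the species carrying a "core" complement (default
LolA1 + LolB1, the chaperone/receptor pair).

# The synthetic world

The generators state one fixed world; their defaults were chosen once and
are not tuned against test outcomes:

* **Hit profiles**: template universe and reference-set sizes are supplied
  per experiment (benchmarks use 1000 templates and a 20-template
  reference, the scale at which chance overlap is negligible);
  significant E-values are drawn log-uniformly on $[10^{-30}, 10^{-4}]$
  (spanning magnitudes like real searches), noise hits on
  $[10^{-2}, 10]$. Each planted homolog shares exactly
  $\lceil \rho K \rceil$ of the reference's $K$ templates; background
  proteins draw Poisson-distributed template sets uniformly from the
  universe. When $\lceil \rho K \rceil = 0$ with planted homologs, the
  plant is unrecoverable by construction and the generator says so
  (warning plus truth-table note) instead of pretending otherwise.
* **Sequences**: 20-letter uniform background (composition statistics stay
  testable), lengths 80–200 (typical for LolA/LolB-sized carriers),
  signal architectures built from the same rules the classifier applies,
  and rejection sampling guaranteeing every emitted sequence classifies as
  planted. Agreement of 1.0 in the round-trip test therefore establishes
  *self-consistency* of generator and classifier — not accuracy against
  real signal peptides, which only an external predictor could measure.
* **Abundance**: per-protein baseline $\log_2$ abundance
  $\sim N(20, 1)$ across proteins (typical LFQ intensity scale),
  replicates $\sim N(\mathrm{baseline} + \delta \cdot \mathrm{DE}, \sigma)$
  with $\sigma = 0.5$ by default, five replicates per condition (the
  design of the emulated experiments), Welch's two-sample t-test as the
  p-value generator (the LFQ suite uses ANOVA; with two groups these
  coincide up to the pooling choice). Missing values, peptide-level
  rollup, and normalization artifacts of real LFQ data are *not*
  emulated.
* **Species hits**: planted counts receive sub-cutoff E-values; Poisson
  decoys above the cutoff exercise the threshold.

All generators are deterministic given the single integer seed in their
spec; determinism is itself a tested invariant.

# Degenerate inputs and numerical conventions

Empty proteomes, empty FASTA files, zero-row filters and all-zero matrices
return typed empty results rather than errors; a reference with no
significant template at the cutoff is an error (the comparison is
undefined); records missing both p-value and significance are an error
naming the protein. All threshold comparisons are inclusive. Ranking and
tie-break orders are total, so outputs are reproducible byte for byte.

# Limitations

* The SPI/SPII rules are surrogates; on real proteomes a dedicated signal
  peptide predictor will disagree on edge cases (short h-regions,
  signal anchors, twin-arginine signals are not modelled).
* The LES default is a placeholder, not biology.
* Net charge ignores structural context; the hydrophobic gradient uses
  composition only, not surface geometry.
* Family assignment by best E-value approximates manual paralog curation;
  `ambiguous` flags where it is least trustworthy.
* Full-scale discovery counts from the motivating study (numbers of LolA/
  LolB candidates, significant proteins per mutant, homologs across 30
  species) depend on external proteomes, template-database snapshots and
  deposited raw data; they are workflow expectations, not desk-scale test
  assertions.
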