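# lolkit

Tools for finding and characterising remote homologs of the bacterial
lipoprotein-sorting proteins **LolA** (periplasmic chaperone) and **LolB**
(outer-membrane receptor) in Bacteroidota, and for profiling the
outer-membrane (OM) proteome consequences of deleting them. In this phylum
the Lol components have diverged so far that ordinary sequence similarity
fails; candidates are instead discovered by comparing **structural-template
hit lists** ("template fingerprints"). The package is aimed at
bioinformaticians studying envelope biogenesis, lipoprotein sorting and the
Type IX secretion system in diderm bacteria.

## What it computes

**Template-fingerprint discovery.** Each protein *p* in a proteome carries a
hit list of structural templates with E-values. With significant sets
*S(p) = { t : E(p, t) ≤ c }* at cutoff *c = 10⁻³*, a reference protein *r*
(e.g. *E. coli* LolB) yields candidates ranked by

- overlap = |S(p) ∩ S(r)|, then
- Jaccard = |S(p) ∩ S(r)| / |S(p) ∪ S(r)|, then id;

`identical_sets` flags S(p) = S(r). Applied at full scale this procedure
recovers the known Bacteroidota LolA homologs and proposes new LolB
candidates; at desk scale the package validates it on synthetic hit lists
with planted homologs.

**Envelope annotation.** A transparent rule-based classifier assigns
`NONE` / `SPI` / `SPII`: SPII when the lipobox
`[LVIFMSTAG][ASTVIG][GAS]C` lies within residues 10–40 (the terminal Cys is
the lipidated mature N-terminus); otherwise SPI when a ≥7-residue h-region
with mean Eisenberg hydrophobicity ≥ 0.5 in residues 1–35 is followed by an
`A-x-A` site in residues 15–45. SPII lipoproteins are further flagged for a
configurable lipoprotein export signal (LES) just after the Cys
(surface-exposed, `SPII-LES`).

**Physico-chemistry.** Per-selection residue composition, hydrophobic
fraction (residues with positive Eisenberg consensus value), Leu+Ile and
Lys/Arg fractions, mean Eisenberg hydrophobicity, Henderson–Hasselbalch net
charge (fixed pKa set: D 3.65, E 4.25, C 8.3, Y 10.07, K 10.53, R 12.48,
H 6.0), and the hydrophobic-gradient direction of a donor→acceptor pair:
`FAVORABLE` when the acceptor's hydrophobic fraction exceeds the donor's by
more than ε = 0.01.

**Differential abundance.** The label-free proteomics filter
`max(FC, 1/FC) ≥ 1.5` **and** `significance = −10·log₁₀(p) ≥ 20`
(two-sided, inclusive; 20 ↔ p = 0.01), with tallies by localization class
(`NO_SP`, `SPI`, `SPII`, `SPII_LES`) and per-category up/down splits.

**Conservation.** Homology-search hits at E ≤ 0.001 are assigned to query
families (best E-value, lexicographic tie-break flagged `ambiguous`) and
tabulated into a species × family homolog-count matrix with coverage
summaries.

Every input has a seeded synthetic generator with planted ground truth
(`sim_hit_profiles()`, `sim_sequences()`, `sim_abundance()`,
`sim_species_hits()`), so the whole pipeline is testable offline.

## Worked example

```r
library(lolkit)

spec <- hit_profile_sim_spec(n_proteins = 50, n_templates = 1000,
                             ref_template_count = 20,
                             planted_ids = c("P0007", "P0021"),
                             overlap_fraction = 0.6, background_rate = 2,
                             seed = 7)
sim <- sim_hit_profiles(spec)
head(shared_template_candidates(sim$proteome, sim$reference, cutoff = 1e-3), 3)
#>   protein_id reference_id overlap jaccard identical_sets shared_templates
#> 1 P0021      REF               12  0.545  FALSE          T00090;T00168;...
#> 2 P0007      REF               12  0.522  FALSE          T00022;T00090;...
#> 3 P0031      REF                1  0.0476 FALSE          T00467
```

Both planted homologs (sharing ⌈0.6·20⌉ = 12 of the reference's 20
significant templates) rank first; the best background protein shares a
single template by chance. Annotating planted lipoprotein sequences:

```r
seqs <- sim_sequences(sequence_sim_spec(6, c(SPII = 0.5, SPII_LES = 0.5), seed = 7))
annotate_fasta(seqs$sequences)
#> annotated 6 sequences: SPII=2, SPII-LES=4
#>   protein_id sp_class cleavage_pos lipobox_start lipobox_end les_present
#> 1 S0001      SPII               20            17          20 FALSE
#> 2 S0002      SPII               21            18          21 TRUE
#> ...
```

`cleavage_pos` is the lipidated Cys; `les_present` separates surface-exposed
(SPII-LES) from periplasm-facing lipoproteins. Filtering a synthetic
two-condition OM proteome (500 proteins, 10% with a planted 2 log₂-unit
shift):

```r
ab <- sim_abundance(abundance_sim_spec(500, de_fraction = 0.1, log2_shift = 2, seed = 7))
tally_abundance(apply_abundance_filter(ab$summary, fc_min = 1.5, sig_min = 20))
#> tally: 44 significant proteins (41% without signal peptide)
#>   NO_SP     18
#>   SPI       8
#>   SPII      11
#>   SPII_LES  7
```

The 44 significant proteins are close to the 50 planted shifts (the filter
is strongly powered at this effect size), and the percentage line is the
no-signal share used to diagnose intracellular leakage into OM fractions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch against the installed package:
planted-homolog discovery and ranking, signal-peptide annotation of planted
sequences, a donor→acceptor gradient call, the differential-abundance filter
and tally on a 1000-protein synthetic table, and a 10-species conservation
matrix — logging each stage's headline numbers and writing the JSON report
to `--out`.

See `vignettes/lolkit-methods.Rmd` for the models, parameter choices and
limitations.
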