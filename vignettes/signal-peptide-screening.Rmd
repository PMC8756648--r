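---
title: "Signal-peptide screening analytics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-peptide screening analytics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spscreen)
```

## The problem this package addresses

Sec signal peptides (SPs) are short N-terminal extensions — typically 10–52
residues in lactic acid bacteria — that commit a protein to the general
secretion pathway and are removed by signal peptidase I (SPase I) during
export. Because a signal peptide's secretion performance with a given
cargo protein cannot be predicted from its sequence, the practical route to
a well-secreting production strain is a *genome-wide screen*: predict every
SP in the host's proteome, fuse each to the target enzyme, and measure
extracellular activity clone by clone against a benchmark SP.

`spscreen` implements the computational side of such a screen for hosts like
*Lactiplantibacillus plantarum* and *Pediococcus acidilactici*: sequence
property analytics, group statistics, cross-strain similarity, plate-screen
shortlisting and in-silico construct assembly. The wet-lab steps
(transformation, fluorescent protease assays, sequencing) and the external
predictors (signal peptide and transmembrane-helix prediction) are out of
scope; the package consumes their outputs.

## Records and coordinates

A signal-peptide record stores the sequence *up to the residue immediately
before the cleavage site*, plus up to two retained downstream residues. All
coordinates are 1-based: a cleavage site "between k and k+1" means the SP
comprises residues `1..k`, so the cleavage position always equals
`nchar(sp_seq)`. Arrow-notation cells (`"MQLLK...SGLA↓AS"`) and predictor
tables are both normalised into this representation; the ASCII pipe `|` is
accepted as an arrow dialect so fixtures stay plain text.

Sequences are restricted to the 20 standard one-letter codes. The ambiguity
codes X/U/B/Z are rejected by default and, when admitted via
`allow_ambiguous = TRUE`, count as neither charged nor hydrophobic — the
property definitions below enumerate standard residues only.

## Per-peptide properties

For a signal peptide $s = s_1 s_2 \ldots s_L$:

* **N-domain**: $s_1 \ldots s_m$ where $m$ is the position of the last K or
  R in $s$. If $s$ contains no K/R, $m = 1$: the N-domain collapses to the
  initial residue (charge contribution 0 for the usual Met). This fallback
  never occurs in the published screen data; index 1 was chosen to keep
  $1 \le m \le L$ rather than invent an empty domain.
* **Net charge**: $\sum_{i \le m} q(s_i)$ with $q(K) = q(R) = +1$,
  $q(D) = q(E) = -1$, all other residues 0. Histidine is neutral and the
  free N-terminal amino group contributes nothing — both choices are
  confirmed by the printed per-row charges of the screen's
  characterisation table. A `positive_count` mode sums only the +1 terms
  (see "Published idiosyncrasies").
* **Hydrophobicity**: $100 \cdot |\{i : s_i \in
  \{G,A,V,L,I,M,F,W,P\}\}| / L$, rounded half-up to an integer.
* **Ala-X-Ala motif**: TRUE iff $s_{L-2} = s_L = A$ — the canonical SPase I
  recognition pattern at positions −3/−1 relative to the cleavage site;
  position −2 is unconstrained and the retained downstream residues are
  never consulted.
* **Transmembrane helix**: an externally supplied flag (2-column TSV or a
  named logical vector). Helix prediction is a modelling task of its own;
  the package ingests the calls of a dedicated predictor and reports `NA`
  where none is given, rather than cloning such a model badly.

### Rounding

Half-up rounding is used wherever the published table prints integers or
one-decimal means (e.g. 57.5% → 58, mean 68.15 → 68.2). Binary floating
point makes naive `floor(x + 0.5)` unreliable exactly at the `.5`
boundaries that matter, so integer percentages are computed in exact
integer arithmetic and decimal means through a representation-safe helper.
Group mean hydrophobicity is taken over the per-peptide *integer*
percentages, because that is demonstrably how the published group averages
were formed (1363/20 = 68.15).

## Group statistics

`group_summary()` reproduces the footer of the characterisation table:
per-group means (one decimal), motif percentage, and helix percentage over
peptides with known flags only. `group_compare()` runs two-sided two-sample
t-tests on length, net charge and hydrophobicity between the secreting and
non-secreting groups.

`student_t()` implements the test in closed form, in both the
pooled-variance ("Student's") and unequal-variance (Welch) variants, with
explicit conventions for degenerate inputs: when both samples have zero
variance, p is 1 for equal means and 0 for unequal means, each with a loud
warning. These conventions matter for screening triplicates, where constant
readings occur; `stats::t.test()` — which errors on constant data — serves
as the independent cross-check in the test suite.

**Which variant is the default?** For the bare operation, pooled — the
textbook reading of "Student's t-test". For `group_compare()`, Welch.
Recomputing the published t-test row (p = 0.34 / 0.25 / 0.99 for length /
charge / hydrophobicity) settles the question empirically: the pooled form
gives 0.48 / 0.37 / 0.99, while Welch gives 0.335 / 0.250 / 0.985 on the
printed columns and 0.347 / 0.240 / 0.985 on the recomputed columns — the
printed row to within ±0.02 either way. The published values were evidently
produced with the unequal-variance form (the default of common statistical
software), so the group comparison follows it; the pooled variant remains
one argument away. Under both variants every p-value exceeds 0.05: no
sequence property separates secreting from non-secreting signal peptides,
which is the screen's motivating observation.

## Published idiosyncrasies in the characterisation table

The packaged 29-peptide fixture preserves the printed values verbatim, and
the regression tests document three reproducible discrepancies rather than
hide them:

1. **Net charges.** Six printed charges disagree with the literal "signed
   sum up to the last K/R" rule. Four rows (LP_23680, PA_18600, PA_10610,
   PA_14540) have a stray K/R in the C-region, immediately before the
   cleavage site, that the printed value does not count — consistent with
   the authors ending the N-domain before the hydrophobic core. Two rows
   (PA_13510, PA_07000) carry an acidic residue inside the N-domain that
   the printed value does not subtract; these match the `positive_count`
   mode. The package implements the stated rule as the default and exposes
   the counting variant.
2. **PA_07000's length.** The table prints 38; the printed sequence has 37
   residues. The computed pipeline reports 37.
3. **Motif/helix ticks.** Rows with a single tick are typographically
   ambiguous between the motif and helix columns; the printed group
   percentages (50% / 67% motif, 100% / 89% helix) disambiguate them, and
   the recomputed motif flags reproduce those percentages exactly.

None of these rows feed the quantities the acceptance script reports for
the net-charge group means.

## Cross-strain comparison

Strain peptide sets are true sets (exact string equality,
case-insensitive): the published screen's comparison script matched
predicted SPs between strains without an identity threshold, and presence
values as low as 1.9% in its cross-strain table corroborate exact matching.
`percent_shared()` reports $100 \cdot |A \cap B| / |A \cup B|$ — the
Jaccard index in percent, one decimal — with shared counts alongside;
`presence_table()` gives the fraction of panel strains containing each
query peptide.

Heatmap ordering uses average-linkage (UPGMA) clustering on the distance
$100 - \mathrm{percent}$. The published heatmap came from a web tool whose
exact rendering is not chased; the exported matrix is the contract. Leaf
order is made fully deterministic: strains are sorted lexicographically
before clustering and every merge is rotated so the subtree containing the
lexicographically smallest strain comes first, which fixes the order even
under tied merge heights.

The published genome-panel similarity figures (51.1 ± 8.4% within
*L. plantarum*, 45.3 ± 14.6% within *P. acidilactici*) require 179 external
genome assemblies and a specific predictor version, so they are not
desk-reproducible; the machinery is instead validated against a brute-force
membership oracle and constructive panels with exactly planted Jaccard
values (below).

## Plate-screen analysis

Improvement of a clone over the benchmark-SP control is
$(\bar{x}_{\mathrm{clone}} - \bar{x}_{\mathrm{ctrl}}) /
\bar{x}_{\mathrm{ctrl}}$ on fluorescence intensity units. Controls are
aggregated per plate by default — each plate is normalised to its own
control wells, absorbing plate effects — with a global-control mode
available, since screens report normalisation "over the control" without
fixing the scope. Shortlist thresholds are inclusive (≥ 20%, ≥ 50%), so
raising the threshold can only shrink the shortlist. Shortlisted clones
are collapsed to unique signal peptides with clone counts (a 126-colony
shortlist typically collapses to a dozen distinct SPs), and oversampling is
reported as colonies picked over library size (1630/155 ≈ 10.5-fold,
1179/110 ≈ 10.7-fold — both above the 10-fold coverage target). Second-round
confirmation takes triplicates and requires a positive increase with
p < 0.05.

## Construct design

Expression cassettes follow the screen's library design: RBS `AGGAGG`, a
spacer, the signal-peptide CDS taken verbatim from the source genome (no
back-translation), the **two retained codons** encoding the residues
downstream of the cleavage site, and the mature-protein CDS ending at
exactly one stop. Promoter and terminator are modelled as vector-resident
context — the cassette replaces a reporter between an existing promoter and
terminator — so they are part of the user-supplied vector sequence, not of
the fragment. The RBS–start spacing is configurable with a 7 nt default;
the study states the RBS sequence but not the spacing, and 6–8 nt is the
usual Shine–Dalgarno offset. The junction between the retained codons and
the mature CDS is a direct fusion (no linker is described).

`build_fusion()` re-translates every DNA part and refuses any construct
whose translation disagrees with its peptide record — the guard against
library cross-contamination. Note that translation here uses the plain
codon table (`no.init.codon`): alternative initiators like CTG must not
silently read as Met inside internal parts. `assemble()` performs the
20 bp-overlap assembly in silico: base-by-base homology check (first
mismatching position reported), uniqueness of the landing sites in the
vector, and a circular product of length
$|\mathrm{vector}| + |\mathrm{fragment}| - 2 \cdot \mathrm{overlap}$.
Constructs and assemblies serialise to a minimal GenBank flat file
(1-based inclusive feature coordinates, labelled parts) that the package
reads back losslessly.

## Synthetic data and what passing tests mean

Every input class has a seeded generator with planted ground truth:

* `gen_signal_peptides()` emulates the tripartite SP architecture: Met + a
  charged N-domain (2–8 residues, K/R-enriched, ending in K/R), a
  hydrophobic H-domain (10–18 residues from the hydrophobic class) and a
  polar C-domain (4–8 residues) whose −3/−1 positions become alanine with
  probability `p_axa`. The default `p_axa = 0.34` is the genome-wide motif
  frequency observed among the 155 predicted *L. plantarum* SPs (53/155).
* `gen_strain_panel()` builds panels *constructively*: a shared core plus
  disjoint private peptides sized so each pair realises exactly the target
  Jaccard $J = c / (2s - c)$. Exactness is the point — similarity tests
  need no tolerance — so infeasible targets are rejected with the nearest
  feasible suggestion instead of being approximated.
* `gen_plate()` models fluorescence as
  $\mu (1 + \mathrm{effect})(1 + \varepsilon)$ with multiplicative
  zero-mean Gaussian noise truncated at 0 (default CV 5%), spread over
  96-well plates with 8 control wells each: the simplest model consistent
  with intensity-unit readouts.
* `gen_proteome()` plants SPs inside synthetic proteins with matching
  prediction rows, so the extraction path can be verified end to end.

These generators reproduce the *mechanics* of real screen data — planted
effects, planted sharing, plate structure — but not its biology: no codon
usage, GC content, phylogenetic correlation between strains, or
heavy-tailed assay noise. Passing the planted-recovery suite therefore
demonstrates correctness of the computations, not that a real screen will
show 10 clean hits; with real data the noise model and control behaviour
must be judged from the controls themselves.

## Problem sizes and runtime choices

The test suite and acceptance script are sized to run comfortably on one
CPU: 100 random panels of up to 10 strains × 50 peptides for the
similarity oracle, 200 seeded simulations for shortlist power (3-replicate
clones at 5% CV — at which planted effects of twice the threshold are
recovered in every run and planted nulls never), a 155-member synthetic
fusion library mirroring the *L. plantarum* library scale, and exhaustive
$\binom{8}{4}$ permutation tests as the small-sample oracle for the t
statistic.

## Known limitations

* Exact-match sharing only; the optional percent-identity matching some
  comparative analyses might want is not implemented.
* The N-domain rule is operational (last K/R), not biophysical; H/C-domain
  boundaries are not modelled at all.
* The GenBank writer emits the minimal subset the package itself reads;
  it is not a general GenBank library.
* No growth normalisation (e.g. by optical density) in plate analysis —
  screens of this design normalise by controls only.

## A complete run

```{r example, eval = FALSE}
tab <- table1_signal_peptides()
props <- property_table(tab, helix_flags = setNames(tab$tm_helix, tab$id))
group_summary(props, setNames(tab$group, tab$id))
group_compare(props, setNames(tab$group, tab$id))

panel <- gen_strain_panel(n_strains = 4, set_size = 30,
                          target_jaccard = 0.5, seed = 42)
percent_shared(panel)$percent
cluster_order(percent_shared(panel))$order

plate <- gen_plate(n_clones = 96, noise_cv = 0.05,
                   effects = c(clone_0007 = 0.6, clone_0033 = 0.3),
                   seed = 42)
shortlist(screen_improvements(plate), threshold = 0.2)
```
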