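---
title: "Methods: structure-aware missense pathogenicity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware missense pathogenicity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

`pathomiss` classifies missense variants of disease-associated proteins as
disease-causing or neutral. The premise is structural: pathogenic missense
variants are enriched in buried, helical, well-ordered regions, tend to
destabilise folding (negative ΔΔG), and perturb the hydrophobic and polar
contact environment of the mutated residue. The classifier is a weighted
gradient-boosted tree ensemble over four feature families computed from the
canonical sequence and a predicted monomer structure, plus externally
supplied predictor scores. One *generic* model serves all proteins;
*per-protein* models are trained on the same data with the target
protein's rows up-weighted 11:1, and a routing rule decides which model
answers for
each protein, with a fallback to the generic model for proteins whose
weighted model degrades (the shipped default routes APOE and PSEN2 that
way).

## Conventions

* Residue numbering is 1-based and equal to canonical-sequence position;
  structures are assumed renumbered to match (the convention of predicted
  monomer models). Only the 20 canonical residues are accepted;
  selenocysteine and ambiguity codes are rejected loudly.
* Per-residue model confidence (pLDDT, 0–100) is read from the
  alpha-carbon B-factor, one value per residue, no averaging — predicted
  models write identical per-atom values.
* "Disease-causing" is the positive class in every metric.
* ΔΔG sign convention: > 0 stabilizing, < 0 destabilizing, = 0 neutral.

# Feature families

**Sequence features.** Two residue-group schemes are built in: the
five-group biochemical scheme (hydrophobic A F I L M V W Y; polar N Q S T;
negative D E; positive H K R; special C G P) used for wild-type/mutant
indicator features such as `hydrophobic_mt`, and a seven-group scheme
(hydrophobic A L M; aliphatic I V; aromatic F Y W; long-polar E Q K R;
short-polar H S T C; short-charged-polar D N; structure-breaking G P) used
by the neighboring amino-acid frequency. That frequency counts each
group's members among the seven residues before and seven after the site
(site excluded, window truncated at the termini) and divides by the *full
protein length*. The length normalisation deliberately couples a local
count to global protein size; it is implemented exactly as stated upstream
and flagged here because it makes the feature length-dependent.

Property scales come from an AAindex-format catalog
(`inst/extdata/aaindex1_builtin.txt`) plus isoelectric point, molecular
weight and molecular volume. For each scale the matrix carries the raw
wild-type and mutant values and sliding-window deltas for windows of 1, 3,
5 and 7 residues (`<table>_delta_<k>` with half-width k = 0..3): the
wild-type property is averaged over the window (truncated at the ends — no
padding, since pseudo-residues would fabricate chemistry), the mutant
property is the raw table value, and the `_norm` variant divides by
sequence length. Substitution matrices (BLOSUM62, sourced from Biostrings)
contribute `<table>_sub` scores.

*Honesty note on the catalog*: the accessions `MEIH800101`, `VASM830102`
and `CHAM830107` are named by the final feature set but their reference
values could not be obtained in this build environment; the bundled file
carries clearly-labelled synthetic stand-in values (chemically plausible,
documented in the file's `D` lines). Feature *names* are faithful; those
three value sets are approximations and any analysis leaning on their
exact numbers should re-parse a genuine AAindex file through
`parse_aaindex()`, which accepts the standard flat-file format.

**Structural descriptors.** Relative solvent accessibility is
Shrake–Rupley sphere sampling (probe 1.4 Å, 100 deterministic
golden-spiral directions per atom, van der Waals radii C 1.70 / N 1.55 /
O 1.52 / S 1.80 Å) normalised by the theoretical max-ASA table (Tien et
al. 2013), bundled and swappable. Residue depth is the mean distance of a
residue's atoms to a sampled molecular surface (the van der Waals surface
points of solvent-exposed atoms); exposed atoms sit within roughly their
own radius of the surface, buried atoms approach the cluster radius.
Secondary structure re-implements the Kabsch–Sander criterion: amide
hydrogens are inferred from geometry (1 Å from N, opposite the preceding
carbonyl), the electrostatic energy E = 0.084·332·(1/rON + 1/rCH − 1/rOH −
1/rCN) kcal/mol defines a hydrogen bond at E < −0.5, n-turns give helices
and bridge patterns give strands. The 8-state alphabet is collapsed to 3
states — (H, G, I) → H, (E, B) → E, rest → C — because the downstream
analyses work at the helix/strand/coil level. Torsions are standard
dihedrals, undefined at termini and across chain breaks (CA–CA > 4.5 Å).
Disorder scores are provider inputs, not computed here; re-implementing a
disorder predictor's energy estimation is out of scope.

**Contacts and graph-based signatures.** Mutant structures are produced by
an idealized side-chain swap: the mutated residue's side chain is replaced
by an internal-coordinate template (NeRF construction with standard bond
lengths/angles; rings placed exactly planar) grown from the existing
N–CA–C frame, with no refinement. This replaces a full mutant-modelling
step; externally modelled mutant structures can be registered and take
precedence. Contact typing uses explicit geometric criteria (hydrogen bond
≤ 3.5 Å donor–acceptor with ≥ 90° at the donor; polar ≤ 4.0 Å; weak polar
= carbon to acceptor ≤ 4.0 Å; hydrophobic ≤ 4.5 Å between
hydrophobic-class atoms; aromatic = ring centroids ≤ 6.0 Å; ionic ≤ 4.0 Å
between opposite ionizable classes). The upstream tools name no numbers,
so these thresholds are configuration, pinned by tests. Atoms of the site
residue and backbone-bonded neighbours (|Δposition| ≤ 1) are never contact
partners: covalent geometry is not an interaction. WT counts export as
`IT<Type>`, mutant-minus-WT deltas as `ITd_<Type>`.

Graph-based signatures assign each heavy atom one or more of eight
pharmacophore classes (editable TSV map) and count, for every unordered
class pair, the site-vs-rest atom pairs within each cutoff of a 1.00–11.00
Å grid in 0.50 Å steps (components like `Aro:Sul-11.00`; cumulative in the
cutoff by construction). Eight change components (e.g. `Neg`) record the
WT→mutant difference in the residue's atom count per class — *atoms*, not
residues; the upstream description is ambiguous and atoms were chosen
because the swap operates on atoms. The grid and the site-vs-all
environment definition are likewise undocumented upstream; both are
package decisions recorded here.

**Providers.** ΔΔG from four stability predictors, SIFT, SNAP2, PSSM and
disorder scores arrive as TSV tables keyed by (protein, position, wt, mt).
Tables are validated (duplicate keys, bounded ranges, declared schemas)
and report coverage. A mutation lacking a required score is excluded from
the matrix with a logged reason, never silently imputed; median imputation
exists but is off by default. Which of the four ΔΔG columns enters a model
is left to feature selection — all four are offered.

# Modeling and evaluation

The learner is gradient-boosted trees for logistic loss with the
hyperparameters fixed upstream by a halving search: 80 estimators,
learning rate 0.1, depth 7. No boosting package with sample-weight support
is available in the build environment, so the core is a compact Rcpp
implementation: exact greedy splits maximizing weighted squared-error
reduction of the current gradients, Newton leaf updates (Σw·g / Σw·h,
clipped at ±8), no subsampling. The absence of subsampling makes every fit
bit-deterministic for fixed data and weights; the configured seed is
recorded in the model as provenance, not consumed. Tie-breaks in split
search favour the first feature and smallest threshold scanned, so column
order never silently changes a fit's reproducibility.

Greedy forward selection adds, at each step, the candidate whose refit
maximizes validation MCC, stopping when no candidate improves by more than
1e-6 or at a 30-feature cap; ties break by candidate order. The objective
(MCC) and the stopping rule are package decisions — the upstream
description names greedy selection but not its objective; MCC was chosen
to match the cutoff-calibration objective used for external predictors.

Data splits are grouped by unique (protein, position): groups are shuffled
with a seeded generator and partitions filled greedily to 60/20/20 group
counts. Fractions are over *groups*, not mutations, because redundancy is
defined on positions. Cross-validation pools out-of-fold predictions and
computes metrics once on the pool rather than averaging per-fold, which is
more stable at the small per-fold counts grouped folding produces. The
validation partition drives feature selection; cross-validation is
reported on the remainder — the upstream interaction of the two is
unstated, and this is the documented choice.

Cutoff calibration for external predictor scores scans all midpoints
between adjacent sorted unique scores (plus ±∞) and returns the
MCC-maximizing cutoff, smallest on ties, with an orientation flag for
scores where low means pathogenic. Published fixed cutoffs (SIFT 0.05,
SNAP2 0.0, PROVEAN −2.5) are honored by thresholding directly.

Group comparisons use the unpaired two-tailed Wilcoxon rank-sum test. The
upstream analysis names a *signed-rank* test for two independent phenotype
groups, which is a paired procedure misapplied to unpaired data; this
package implements the statistically appropriate unpaired test and
therefore will not numerically reproduce those published p-values.

# The synthetic world

The generator states one world and the tests live in it: 3 fixture
proteins of 40 residues (ideal α-helices, φ = −57°, ψ = −47°, pLDDT drawn
uniformly in 70–95), 40 mutations per protein sampled uniformly over
distinct (position, mutant) pairs, labels from a planted rule flipped with
probability ε = 0.05 (ε = 0 in the "separable" preset), and provider
tables with the pathogenic class's ΔΔG mean shifted 1 kcal/mol negative.
The default rule labels a site disease-causing when its 15-residue window
holds ≥ 2 aliphatic (I/V) residues — deliberately the signal carried by
`aliphatic_freq`, the pipeline's own feature, so selection tests have a
recoverable ground truth; an alternative rule keys on mutant
hydrophobicity, and a per-protein rule inversion supports the
weight-tuning experiments. Sample sizes and noise were chosen once as
desk-scale defaults a simulation study would call modest but adequate
(n = 120 labeled mutations; binomial checks use 3-σ bands) and are not
revisited.

What a green test establishes: that the machinery recovers a planted,
learnable signal end to end; that weighting 11:1 specialises a model
towards a protein whose rule disagrees with the majority; that the
descriptors obey their geometric invariants on ideal structures. What it
does not establish: real-data performance. The fixtures are single ideal
helices — no beta sheets, no loops with realistic irregularity, no
predicted-model error modes, no correlated label noise, and provider
scores are parametric draws rather than real predictor outputs. The
published benchmark numbers for this kind of pipeline require the curated
mutation spreadsheets, predicted structures for the full protein panel and
live third-party predictors, all out of scope here, which is why the
machine-readable acceptance-target list is empty and acceptance is
property-based.

# Numerical choices and degenerate inputs

* Sphere sampling is deterministic (golden spiral); RSA is therefore
  exactly reproducible and can slightly exceed 1 for very exposed
  residues (max-ASA tables are conventions, not suprema).
* Dihedrals are reported in (−180, 180]; the φ of the first and ψ of the
  last residue are NA, mapped to 0 in feature matrices (the `ss_*`
  indicators carry the structural signal there).
* Proline donates no amide hydrogen bond; residues with missing backbone
  atoms are forced to coil with a warning rather than erroring.
* Contact typing with an empty neighborhood returns the zero profile;
  a 3-residue chain has no contact partners at its centre by the
  exclusion rule.
* `optimize_cutoff` refuses constant scores; `train` refuses single-class
  labels; `compute_metrics` reports NA for undefined class-conditional
  rates instead of fabricating values.
* Seeds: every stochastic operation (splits, folds, generators) takes an
  explicit integer seed and restores the caller's RNG state; derived
  seeds stay far below 2^31.

# Known limitations

* The side-chain swap places idealized rotamers with no packing
  refinement; buried mutant contacts are approximate. Registering
  externally modelled mutant structures is supported and preferable when
  available.
* The Kabsch–Sander re-implementation covers helices, bridges and ladders
  in their 3-state collapse; it does not reproduce full 8-state output or
  the reference program's bend/turn classes.
* Residue depth uses the sampled accessible surface rather than a true
  molecular-surface triangulation; absolute depths differ from
  surface-mesh implementations by up to about an atom radius, while
  orderings (the feature's job) are preserved.
* Three AAindex accessions ship synthetic stand-in values, as flagged
  above.
* The seven-algorithm comparison that originally justified gradient
  boosting is reproducible only in configuration shape, not shipped as
  alternative learners.
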