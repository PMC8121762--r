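---
title: "Methods: models, filters and design choices in pepatlas"
author: "pepatlas maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, filters and design choices in pepatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepatlas)
```

This vignette explains the scientific assumptions behind each stage of the
package, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices that were
genuinely open.

## Coordinates and peptide naming

All peptide coordinates are 1-based inclusive positions on the *prepro*
sequence, signal peptide included. This matches the field's naming habit
("p59-79" for a peptide spanning prepro residues 59–79) and avoids the
ambiguity of mature-chain numbering when the signal-peptide boundary is
uncertain. Labels append `a` for C-terminally amidated species
(`peptide_label("ChgA", 435, 462, TRUE)` → `"ChgA p435-462a"`).

## Mass arithmetic

Masses are monoisotopic throughout, as appropriate for high-resolution
identifications; residue masses are embedded constants accurate to 1e-8 Da
so that 65-residue peptides stay within 1e-4 Da of an elemental-composition
computation. The registry covers the modification set relevant to gut
peptides: C-terminal amidation (−0.98402 Da), N-terminal pyroglutamate from
Gln (−17.02655) and Glu (−18.01056), N-terminal acetylation (+42.01057),
carbamidomethyl-Cys (+57.02146, the fixed alkylation), phosphorylation
(+79.96633, S/T/Y) and Ser/Thr octanoylation (+126.10447) / decanoylation
(+154.13577, the ghrelin-type acyls). Non-canonical letters (B, J, O, U, X,
Z) are rejected rather than approximated, and Ile/Leu are treated as
distinct — upstream high-resolution identification is assumed to have
resolved them. m/z uses the proton mass 1.007276 Da.

## Homolog alignment and projection

Mouse/human prepropeptide pairs are aligned globally (Needleman–Wunsch) under
BLOSUM62 with affine gap cost: a gap of length $L$ costs $10 + L$. The match
line marks identity with `|` and "chemical similarity" with `:`; similarity
is defined as a positive BLOSUM62 score for a non-identical pair, a concrete
rule chosen because figure-style legends never define the term. Interval
projection maps a residue range to the smallest covering interval on the
partner sequence; its coverage fraction (non-gap images / interval length)
distinguishes confidently projected intervals from ones straddling gaps.
The alignment itself is delegated to `Biostrings::pairwiseAlignment`; the
match line, coordinate maps and projections are computed here and are tested
against a brute-force enumeration of all alignments on small instances.

## Terminus classification

Prohormone convertases cleave after mono- and dibasic (K/R) sites and
carboxypeptidase-E then removes the exposed basics, so an observed mature
C-terminus can sit up to two residues upstream of the true cut. The
classifier therefore looks at the pair of residues immediately upstream of
the cut for N-termini, and for C-termini also considers effective cuts up to
two K/R residues downstream. Amidated termini are produced from
glycine-extended intermediates; an amidated peptide is *consistent* when the
precursor residue after its C-terminus is Gly (typically followed by the
K/R convertase site), and candidate scoring classifies the flank of an
amidated peptide at the post-glycine cut for the same reason. Cuts at the
annotated signal-peptide boundary are their own class and take precedence;
these motif rules encode standard processing biology rather than any single
dataset.

## Ladders and the minor-fragment filter

Ex vivo exoproteolysis shows up as ladders: series of identifications
differing by one or two terminal residues. Observations from one precursor
are single-linkage clustered, linking two peptides when they overlap and
either terminus differs by ≤2 residues; the cluster's canonical member is
its most abundant observation. Clusters are reported, never merged into a
longest variant — merging would discard genuine processing variants (e.g.
DPP4-truncated forms), which is precisely the information this analysis
wants. Separately, the minor-fragment filter removes peptides whose signal
is below 10% of the most abundant peptide *from the same propeptide*. The
filter compares each peptide's maximum area across samples (a per-sample
rule would let a peptide flicker in and out between samples); it is
idempotent, and it is applied before any differential statistics.

## Differential abundance and secretion

Within each gut region, peptides not matched in at least 70% of the samples
of at least one group are removed. The fold change is
$\log_2(\bar{x}_{\mathrm{lean}}/\bar{x}_{\mathrm{DIO}})$, so a decrease in
the DIO group is positive; means are arithmetic on the natural area scale
with missing values excluded (missing means *not matched*, not zero).
Group comparison uses a Mann–Whitney test by default — robust to the
log-normal skew of peak areas — with Welch's t on log areas as an option,
and Benjamini–Hochberg correction across peptides within a region. The test
and alpha are this package's choices; peptides with fewer than two finite
values in a group get no p-value, and a group that is entirely missing
yields a flagged `NA` fold change rather than an infinity.

Secretion is summarised as fold over basal, stimulated area divided by basal
area, defined only when the basal supernatant had a positive detection;
undetected basal gives `NA` (several real gut hormones behave exactly this
way). Fold > 2 in at least one region is the regulated-secretion criterion.

## Candidate scoring

Four booleans per mouse peptide: basic-residue (or signal-boundary or
precursor-end) flanks at both termini; abundance ≥ 1e5 peak area in mouse
*and* in a human observation overlapping the projected interval; sequence
identity ≥ 0.7 over the peptide span against the human homolog; and
fold-over-basal > 2 somewhere. The abundance cut mirrors the plotting
threshold used for the denser figures; the conservation and secretion cuts
are configurable defaults recorded here as engineering choices (the
secretion threshold is the one quantitative criterion stated by the study
design). A literature-prior criterion ("previously described as bioactive")
is out of scope; a manual boolean column can be joined onto the output if
desired. The composite is the count of satisfied criteria, so relaxing any
threshold can only raise it (tested); ranking breaks ties by peak area then
lexical id so that re-runs are reproducible.

## Pharmacokinetics

A one-compartment model with first-order absorption is used throughout:
i.v. bolus $C(t) = (D/V)e^{-k_e t}$ and s.c.
$C(t) = \frac{F D k_a}{V(k_a - k_e)}(e^{-k_e t} - e^{-k_a t})$, with the
limiting form $C(t) = \frac{F D k_a t}{V} e^{-k_a t}$ at $k_a = k_e$. One
compartment is appropriate for short-half-life peptides sampled sparsely
over ≤90 min; a two-compartment model is deliberately out of scope. For
extravascular data only $V/F$ and $CL/F$ are identifiable. Fitting minimises
squared residuals on log concentrations (equal weights, observations at or
below the LOQ excluded) over a multi-start grid of initial $(k_a, k_e)$
pairs; the flip-flop ambiguity is resolved by reporting the labelling with
$k_a > k_e$, with a warning when a genuinely different parameterisation fits
equally well. `t_half` is exactly $\ln 2 / k_e$, and the model AUC obeys
$CL/F = k_e \cdot V/F$.

Non-compartmental AUC uses the linear-up/log-down trapezoid with the
terminal slope $\lambda_z$ from a log-linear regression on the last three
positive points; fewer than three positive points leaves $AUC_{0-\infty}$
undefined rather than extrapolated. Bioavailability is the dose-normalised
AUC ratio of the s.c. and i.v. arms. The steady-state infusion rate is
$Css \times CL/F \times 1440$ min/day; when concentrations were fitted in nM
the dose-normalised clearance already carries the mass-per-mole factor, and
for mass-unit (ng/mL) data the molar target is first converted with the
molecular weight ($Css_{ng/mL} = Css_{nM} \cdot MW / 1000$), which is why the
molecular weight is mandatory in that case.

## The synthetic study

The generator's defaults are the shipped study conditions, fixed once:

* eight precursor genes with planted signal peptides, dibasic sites and
  amidation motifs; three candidate analogues (a gastrin-like p59-79, an
  amidated granin-like p435-462, a somatostatin-like p25-36 beginning at the
  signal boundary), three DIO-decreased L-cell precursors (Pyy/Gcg/Insl5-
  like), a cytosolic constitutive decoy with non-basic flanks, and a filler;
* mouse/human identity 0.85, point substitutions only (no indels), with
  structural positions (cut sites, amidation glycines) never mutated;
* log-normal peak areas around 1e6 (sdlog 0.5), exoprotease ladders up to 2
  residues at 3–60% of the canonical area, pyroglutamate probability 0.5;
* cohort: five regions × two groups × 8 animals, 15% missingness, a 4-fold
  decrease of the L-cell peptides in the DIO distal colon only;
* secretion: vesicular fold 4, constitutive fold 1, some peptides
  basal-undetected; 10% multiplicative noise;
* PK truth: terminal half-lives 18.1 and 36.0 min, absorption 5× faster
  than elimination, V = 0.1 L/kg, bioavailability 0.7 and 0.5, 8 sampling
  points over ≤90 min, 10% log-normal noise, concentrations in nM with the
  molar conversion taken from the planted peptide's monoisotopic mass.

Determinism: every artefact draws from its own RNG stream seeded by
`(master seed, artefact label)`, so adding artefacts never perturbs existing
ones and the same seed reproduces files byte-for-byte.

What the generator does *not* emulate — and hence what green tests do not
show about real data: spectrum-level effects (no mzML, no isotope envelopes,
no retention-time structure), realistic amino-acid composition bias,
correlated missingness (real dropout follows abundance), inter-animal
covariance, splice variants, and sulfation or other modifications that are
hard to detect upstream. Passing the pipeline on this generator shows the
statistics and bookkeeping are correct under the assumed data-generating
process, not that the biology of any particular tissue will match it.

## Problem sizes and numerical notes

The shipped configuration is deliberately desk-scale: ~600 observations,
a 14-peptide × 80-sample cohort, and 8-point PK series, so the full test
suite and the acceptance script each run in well under a minute of compute.
Parameter-recovery checks use three pooled replicates per analyte, pooled by
per-timepoint geometric mean (the natural pooling under multiplicative
log-normal noise on a shared sampling grid). One property worth recording:
with 8 points over 90 min, 10% noise and three replicates, the information
bound on the 36-min half-life corresponds to a coefficient of variation of
about 9% — the fitted estimator sits essentially on that bound, so
recovered values a little over 10% from truth are expected occasionally and
are a property of the sampling design, not the optimiser.

Other numerical choices: Nelder–Mead with tight relative tolerance and
multi-start for the PK fits (the 3-parameter log-scale objective has
flip-flop twins but is otherwise well behaved); ties in candidate ranking
broken deterministically; alignment plot shading is log10 of peak area;
degenerate inputs (empty observation sets, all-zero concentration vectors,
fully gapped intervals) return empty/`NA` results rather than errors
wherever the quantity is undefined but the input is legal.

## Known limitations

* Exact-match peptide mapping only: no de novo or tolerant matching, so
  polymorphic or misidentified peptides simply do not map.
* Very long processed forms (beyond the 65-residue identification limit)
  cannot be represented, so glicentin-length products are absent by
  construction rather than merged from ladders.
* The 10%-of-maximum ladder filter uses the global per-peptide maximum; a
  per-sample variant would behave differently on strongly heteroscedastic
  cohorts.
* The PK module fits single-subject (or pooled) curves; population
  mixed-effects modelling is out of scope.
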