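---
title: "Discovering methylation sites from peptide mass fingerprints"
author: "MethylPMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering methylation sites from peptide mass fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylPMF)
```

## The problem

Peptide mass fingerprinting (PMF) identifies a protein by matching the
masses of its tryptic peptides against an in-silico digest. When the
protein's identity is already known — as in large replicate MALDI-ToF
screens where each spectrum comes from a purified protein — the *extra*
peaks that do not match any unmodified peptide become informative: a
peak sitting exactly +14.01565 Da (one CH~2~) or +28.03130 Da above a
theoretical peptide that contains lysine or arginine is a candidate
mono- or di-methylation event. The difficulty is that a single mass
coincidence is weak evidence: at a realistic tolerance of a few
hundredths of a dalton, a proteome-scale screen produces thousands of
spurious delta matches. This package turns such matches into
high-confidence methylation sites by exploiting replicate spectra and
the sequence structure of tryptic digests, and provides the statistics
used to characterise the resulting site catalogue.

## The model and its assumptions

All masses are monoisotopic, singly protonated ([M+H]^+^), and derived
from elemental compositions (`residueMasses()` is a matrix product of
residue formulas with atomic masses, never a hand-typed table, so mass
sums agree with any composition-based computation to floating-point
precision). Digestion assumes trypsin specificity — cleavage C-terminal
to K/R — with at most one missed cleavage; every one-missed-cleavage
peptide is by construction the concatenation of two adjacent fully
cleaved peptides, and the fully cleaved peptides tile the mature chain.
Methionine and tryptophan may be oxidised; variants are enumerated from
zero up to a configurable cap (default 2) per peptide. One modification
instance per peptide is considered: multiply modified peptides are out
of scope, which biases against densely modified regions (e.g. histone
tails) but keeps the hypothesis space and false-positive load small.

Whether trypsin cleaves K/R followed by proline differs between
conventions; the digestion takes it as a flag, default on (the
conventional rule). The published analysis does not state which rule its
digestion engine used, which is why the packaged reference fixtures were
chosen to be insensitive to the flag, and tests exercise both settings.

### Tailor-made tolerances

Because the spectrum's protein is known, each spectrum carries its own
calibration estimate: the median absolute difference between observed
peaks and the nearest theoretical unmodified mass within a coarse 0.15
Da window. The median was chosen over the mean for robustness against
the occasional contaminant pairing (the two statistics agree on clean
spectra). Spectra with fewer than 3 supporting matches fall back to the
global default of 0.04 Da; spectra whose estimate exceeds 0.1 Da are
excluded from site discovery altogether. A floor (default 0.001 Da)
prevents a noise-free spectrum from estimating a zero tolerance that
would match nothing.

### The five filters

1. **Not unmodified** — a query mass that also matches an unmodified
   peptide (including oxidation variants) is most simply explained as
   unmodified and is vetoed.
2. **No D/E** — methyl esterification of Asp/Glu side chains during
   sample handling produces the same +CH~2~ shift as methylation, so
   D/E-containing peptides are categorically removed. (In-silico
   benchmarks disable this filter: no esterification artifact exists
   there.)
3. **Overlap** — methylation slows cleavage at the modified residue, so
   genuine sites occur both in a fully cleaved peptide ending at the
   site and in a read-through missed-cleavage peptide. Matches are
   grouped per protein and modification into connected components whose
   coordinates overlap *and* whose candidate position sets intersect;
   pure coordinate overlap without a shared assignable residue is not
   accepted. By default the two required members must be *distinct
   peptide sequences* (the same peptide observed in two spectra is not
   independent localisation evidence); a switch allows counting match
   instances instead.
4. **Unambiguous anchor** — at least one member of the group must be an
   unambiguous match, i.e. its query mass has exactly one (peptide
   sequence, modification) explanation. Oxidation variants of the same
   peptide and modification collapse to one identity; multiple candidate
   residues within one peptide do not by themselves create ambiguity
   (that is a localisation question, resolved by filter 5).
5. **Site consensus** — within a group, a residue becomes a site when it
   lies in the candidate sets of ≥ 2 overlapping members with identical
   modification *and degree*, at least one of them unambiguous. The
   unambiguous-anchor requirement is enforced per site, marginally
   stricter than the group-level filter 4, so that every emitted site
   individually satisfies the ≥ 1-unambiguous-supporter invariant.
   Mono- and di-methyl evidence never merge into one site: the
   published site catalogue lists mono and di entries at the same
   residue as separate sites, which forces the degree-strict reading.

The driver `runPipeline()` records an audit funnel of match counts after
every stage (at peptide-match granularity) and refuses a configuration
with `maxMissed = 0`, under which filter 3 is unreachable.

## Statistics over the site catalogue

**Discovery rates.** The identification unit is one replicate spectrum
assigned to a protein group; paralogs with identical mature sequences
are pooled because PMF cannot distinguish them. A peptide's discovery
rate is the fraction of the group's spectra in which its mass is matched
— deliberately at a wide tolerance (default 1.5 Da) so every available
spectrum contributes; a residue's rate is the sum over distinct covering
peptides. Methylated and unmodified rates are compared with a two-sided
rank-sum test, and paired residue rates with Kendall's rank correlation.
Residue rates are kept separate per modification degree, consistent with
degree-strict sites.

**Benchmarking.** `buildArtificialSet()` samples a fraction (default
6%) of K residues — independently for each of the four classes
mono/di-methyl-K/R — and emits the theoretical masses of the methylated
host peptides (≤ 1 missed cleavage, oxidation variants, modified mass
within 500–3000 Da). `evaluateTpRate()` then runs delta matching and
scores each match: a true positive must get residue, position and
methylation type right. The reported TP rate, 100·TP/(TP+FP), is a
*precision over matches*; the fraction of planted sites recovered at all
is a different quantity (a recall), reported separately and not
conflated with it. Classes with fewer than 10 tested sites are flagged
N.D. Tri-methyl-lysine is excluded throughout: at +42.04695 Da it lies
0.036 Da from acetyl-lysine (+42.01056), inside realistic tolerances.

**Motifs.** ±10-residue windows are clipped at the termini, never
padded, and the per-offset denominator counts only the windows that
cover the offset. Enrichment uses a one-sided *exact binomial* tail
against proteome-average residue frequencies, with Bonferroni correction
(default factor: 20 letters × 21 offsets). The chi-squared proportion
test with continuity correction is available as an option, but the
binomial is the default because observed counts at a single offset are
small (typically ≤ 8), where the normal approximation is poor. For this
reason the published motif p-values — computed with the proportion test
and an unstated correction factor — are not reproduced number-for-number
and are not used as reference values anywhere in the package; the motif
*memberships* (which sites match which motif) are.

**Functional statistics.** GO slim enrichment is a one-sided Fisher
exact test per term over the annotated universe, Bonferroni-corrected
within each ontology branch independently; with the branch-specific term
count unknown for the published tables, the printed corrected values are
treated as upper bounds for the recomputed raw p-values, never as exact
targets. Abundance and half-life comparisons are two-sided rank-sum
tests; interplay proportions round half-up to integer percentages.
Ubiquitination *prediction* is out of scope: the interplay function
accepts any precomputed binary flag table and reports the overlap
generically.

## The synthetic-data generator

The generator emulates the statistical structure that the pipeline
relies on, under one seeded configuration object:

* proteins as i.i.d. draws from average yeast residue frequencies with
  log-normal lengths (median ≈ 400 residues);
* replicate spectra per protein: Poisson with mean 11, floored at 3;
* peptide detection as a Bernoulli event (default probability 0.7;
  unmodified missed-cleavage peptides at 0.1);
* planted sites at sub-stoichiometric occupancy (default 0.3, in line
  with observed methylation stoichiometries well below one-third);
* partial cleavage at methylated residues (default 0.5), so the cleaved
  and read-through methylated forms both occur across replicates —
  exactly the overlapping evidence filters 3–5 require;
* Gaussian mass error (default σ = 0.02 Da, a typical average MALDI-ToF
  calibration error) and Poisson-many uniform contaminant peaks in
  500–3000 Da.

Filter-compatible planting restricts sites to cleavable K/R whose two
host peptides are D/E-free and whose methylated masses fall in the
detectable window; an adversarial mode plants exactly the complementary
sites to exercise the rejection paths. The generator does **not** model
ionisation efficiency, isotope envelopes, chemical noise structure, or
correlated calibration drift, so passing tests demonstrate the logic and
statistics of the pipeline under its stated assumptions — not
performance on real spectra, where peak detection and mass error are
less well behaved.

Two consequences of the defaults are worth knowing. First, with σ =
0.02 Da the tailor-made tolerance (median |error| ≈ 0.0135 Da)
deliberately rejects roughly half of the methylated peaks — precision is
bought with recall, and end-to-end recovery of planted sites at the
default conditions sits well below one (seed-pinned in the tests as a
regression value, not a performance claim). Second, a broad
modification screen can assemble a confident-looking non-methyl site
(e.g. acetyl) from chance coincidences in noisy data; headline precision
is therefore reported over methylation calls, the class the planted
ground truth defines.

## Numerical choices and degenerate inputs

Matching is inclusive (`|Δm| ≤ tol`); ties are never broken — every
peptide/modification within tolerance is enumerated and ambiguity is
dealt with by filters 4–5 rather than by ranking. Query masses are
keyed by value formatted to 12 significant digits when grouping per
spectrum. Empty peak lists after preprocessing drop the spectrum with a
warning; an empty spectrum set yields an empty site table and an
all-zero audit; a protein group with no identifications is skipped from
rate calculations with a warning rather than dividing by zero. A zero
background frequency with a nonzero observed count gets the smallest
representable p-value and a flag instead of `-Inf`. Seeds: the
simulation configuration requires one explicitly, and the three
generator stages draw from `seed`, `seed + 1`, `seed + 2` so that
regenerating any single stage is reproducible in isolation.

## Problem sizes

The test-suite and acceptance runs use desk-scale data — 20–60 proteins
with on average 11 replicate spectra each, artificial benchmarks of a
few hundred peptides — chosen so that a full run completes in about half
a minute while every property under test (funnel monotonicity,
precision at zero noise, tolerance monotonicity of the TP rate, rate
concentration) is already well exercised at that scale. All quantities
scale linearly with proteome size except the per-protein overlap
grouping, which is quadratic in the matches of one protein and
negligible at any realistic match density.

## Known limitations

* Single modification instance per peptide; densely modified peptides
  are invisible.
* No scoring or FDR machinery (decoy digests, localisation
  probabilities) — confidence comes entirely from the filter cascade.
* The default modification table is a minimal screen (methylation
  degrees, acetyl, oxidation); a fuller screen must be supplied as a
  TSV.
* Intensities are ignored; peaks are masses only.
* The known-site benchmark ingests a user TSV rather than querying
  annotation databases, and sequence-redundancy reduction of benchmark
  sets is out of scope.
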