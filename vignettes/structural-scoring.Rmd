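---
title: "Structural pathogenicity scoring: model, parameters and design notes"
author: "spscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural pathogenicity scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spscore)
```

## The scoring model

`spscore` is a structure-based binary classifier of missense-variant
pathogenicity, built for the cardiac hERG (KCNH2) potassium channel and
applicable to any ion channel with a resolved structure. Each variant is
described by five per-substitution metrics, all on a 0–1 scale:

* **Score A — size.** Median, over one or more size tables (residue
  volume, solvent-accessible surface area), of the normalized absolute
  difference between mutant and wild-type residue. Each table is
  normalized by its own maximum pairwise difference, computed at load time,
  so 1 means "the largest size change any substitution can produce under
  this table".
* **Score B — hydrophobicity.** The same construction over hydrophobicity
  scales, four by default.
* **Score C — charge.** Half the absolute formal-charge difference
  (D, E = −1; K, R = +1; H neutral at pH 7.4 by default, switchable to +1).
  Each charge gained or lost costs half a point, so a full inversion such
  as Glu→Lys scores 1 and the score only takes the values 0, 0.5, 1.
* **Score D — steric clash.** Every rotamer of the mutant side chain from a
  rotamer library is built on the wild-type backbone; a rotamer contributes
  0 if it produces no van der Waals clash, 0.5 if its clashes disappear
  under torsion-space relaxation, 1 if they persist. Contributions are
  weighted by rotamer probabilities renormalized to sum to 1.
* **Score E — pathogenic-hotspot contacts.** For each rotamer with library
  probability strictly above 10%, the fraction of its contact residues
  that sit at registry "hotspot" positions (positions with a known ACMG
  class 4/5 substitution), weighted by the raw (unrenormalized) rotamer
  probability and summed. Hotspot membership is decided at position level:
  a position with several pathogenic substitutions counts once.

Scores A–C need no structure; D and E do. Variants at positions missing
from the structural model — for hERG the intervals 132–398, 433–448,
511–519, 578–582, 598–602 and 864–1159 — are scored in *A–C mode* with
D = E = 0, through the same scaling.

The cumulative sum is mapped onto the ACMG-like 1–5 grid by

$$\mathrm{SPS} = 1 + \frac{\lfloor x + \tfrac12 \rfloor}{4},
\qquad x = \frac{A+B+C+D+E}{3.3}\times 16,$$

which sends 0 to 1, the observed study maximum 3.30 to 5, and rounds to
the nearest 0.25 (ties round up, by floor semantics). SPS ≥ 3.25 is called
**high pathogenic risk**; anything below is **uncertain risk** — never
"benign", because the score measures structural disruption, not its
absence. A lower advisory threshold of 2.5 for the conduction pore is
reported as a flag column (`in_pore`, `pore_call`) and does not change the
primary call.

```{r example}
score_variant("p.Gly903Arg")    # C-tail position: A-C mode
```

## Tunable parameters

All cutoffs live in one YAML-backed configuration (`sps_config()`), and
every value below is a config key:

| parameter | default | meaning |
|---|---|---|
| `scoring$scale_max_sum` | 3.3 | raw-sum value mapped to SPS 5; re-derive it when re-targeting another channel |
| `scoring$threshold` | 3.25 | high-risk decision boundary on the SPS grid |
| `scoring$pore_threshold` | 2.5 | advisory pore-domain flag only |
| `clash$overlap_cutoff` | 0.6 Å | VDW overlap \(r_a + r_b - d\) at or above which two atoms clash |
| `clash$hbond_allowance` | 0.4 Å | subtracted from the overlap when both atoms are polar (N/O) |
| `contact$overlap_cutoff` | −0.4 Å | near-touching criterion defining a "direct contact" |
| `score_d$w_relieved` | 0.5 | Score D weight of a clash that relaxes away |
| `score_e$min_prob` | 0.10 | strict lower bound on rotamer probability for Score E |
| `vdw_radii` | C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å | element-based radius set |

The clash and contact constants are the published defaults of the
molecular-graphics tooling this scoring scheme was originally built on;
they are exposed because other radius sets or stricter criteria shift
Scores D and E systematically.

## Property tables, rotamer library, numbering

The shipped size tables are Zamyatnin residue volumes and Tien et al.
theoretical maximum accessible surface areas; the four hydrophobicity
scales are Kyte–Doolittle, Hopp–Woods, the Eisenberg consensus and
Fauchère–Pliska. Any study that defines its own tables can pass them in
(`property_table()`, `read_property_table()`); the per-example reference
medians quoted in the literature (e.g. 0.3798 for a particular Cys→Phe
size change) are properties of the originating study's exact tables and
are reproduced here by table override, not by the defaults. A pleasing
consequence that does survive the change of tables: glycine↔arginine
substitutions — the substitution class the structure-independent screen
singles out — land exactly on the 3.25 threshold in A–C mode under the
shipped defaults too.

The embedded rotamer library is a minimal backbone-independent set of the
common chi modes with typical frequencies, shipped as TSV
(`residue, chi1..chi4, probability`); a backbone-dependent library in the
same format can be loaded for full fidelity. Mutant side chains inherit
the wild-type backbone (N, CA, C, O, CB; CB is rebuilt from the backbone
when the wild type is glycine) and are constructed from ideal internal
coordinates. Protein positions are 1-based; intervals are closed on both
ends; structure residue numbers are taken as authored, with a configurable
offset for structures whose numbering differs from the translation.

## Clash relief

Where the original workflow called an interactive energy minimizer, this
package uses a deterministic torsion-space relaxation: coordinate descent
over the chi angles of the mutant side chain and of every clashing
neighbour's side chain (backbone fixed), minimizing total squared
effective overlap with a fixed step schedule (30°, 15°, 5°) and sweep cap.
A clash counts as relieved only if no effective overlap of any moved atom
still reaches the clash cutoff. This keeps the Score D contract — clash
persists versus disappears — while being dependency-free and bit-for-bit
reproducible. It explores torsions only: rearrangements that would need
backbone movement are reported as unrelieved, which can make Score D
slightly conservative in tightly packed sites. For the same reason the
single published Score D value for the T421M example (0.64) is treated as
a soft reference: it depends on the original minimizer's internals and is
not asserted by this package's tests.

## What the synthetic fixtures emulate

The fixture generator builds ideal poly-alanine helices (phi −57°, psi
−47°; 1.5 Å rise, ~100°/residue) and extended strands, plus two engineered
situations: a *cavity* (a glycine cage around a site, verified at
generation time by exhaustive chi-grid search to deny every rotamer of a
designated mutation — generation fails rather than produce a fixture that
does not do what it claims) and exposed sites where no clash is possible.
Identical specs regenerate byte-identical files.

These fixtures make the geometric machinery fully checkable by brute
force, which is how the tests use them (all-pairs clash/contact scans,
exhaustive chi grids, literal re-enumeration of Score E). What they do not
emulate is real protein packing: native cores are neither ideal helices
nor glycine cages, real structures carry alternate conformations,
missing atoms and non-ideal geometry, and a cryo-EM model has its own
error structure. Passing tests therefore demonstrate correctness of the
scoring rules, not predictive accuracy on real channels — the latter rests
on the calibration workflow run against real variant tables.

Problem sizes used by the test-suite: fixtures of 6–20 residues, 100
seeded fixtures per brute-force oracle, dense scaling sweeps of a few
thousand points. These sizes make every oracle exact and the whole suite
fast while exercising all code paths.

## Calibration and concordance

`calibrate()` tallies ACMG classes per SPS bin (optionally stratified into
structured / non-structured / pore regions) and reports the pathogenic
fraction (class 4 + 5) per bin. `saturation_fit()` summarizes the curve
with a monotone piecewise-linear model with a single breakpoint — a
non-decreasing rise followed by a constant plateau, fit by weighted least
squares with the breakpoint chosen by grid search. The breakpoint is
reported as the *saturation* onset; the largest jump between consecutive
occupied bins is the *rupture* point. The two-segment form was chosen over
a continuous hinge because it reads a step-shaped calibration exactly and
degrades predictably: strictly increasing fractions push the breakpoint to
the top bin and raise a poor-fit flag, constant fractions are flagged
degenerate and not fit. Rows with missing or invalid ACMG labels are
counted and excluded rather than guessed; conflicting-interpretation
labels should be mapped to class 3 (VUS) upstream, mirroring standard VUS
accounting. `concordance()` cross-tabulates high-risk calls against an
external predictor's categorical calls joined on variant identity, and
reports the share of high-risk variants the external tool also calls
pathogenic.

## Degenerate inputs and tie-breaks

* Synonymous "variants" (wild-type = mutant) are rejected at parse time.
* A structure/sequence mismatch at a scored position is an error; the
  variant is never silently rescored against the wrong residue.
* Raw sums above `scale_max_sum` (possible only with non-default tables)
  clamp to SPS 5 with a warning.
* Median over an even number of tables is the mean of the two central
  values.
* Alternate locations resolve to the highest-occupancy conformer;
  remaining ties break alphabetically by altLoc for determinism.
* Batch scoring preserves input order and carries per-row error messages;
  rows are never dropped.

## Known limitations

Scoring is local: allosteric effects, backbone rearrangements and
interface partners are invisible. Heterozygous states are not modelled.
Unresolved regions are scored from sequence-derived properties only, which
systematically lowers their scores — by design, as these flexible regions
tolerate substitution far better, but a high A–C score there is evidence,
not proof, of disruption. The classifier is one-sided: SPS below threshold
means "uncertain", never "benign".
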