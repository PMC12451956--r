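---
title: "Methods: screening oral bacteria for functional kynureninases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening oral bacteria for functional kynureninases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kynuscreen)
library(dplyr)
```

## The problem

The kynurenine (KYN) pathway is the dominant route of tryptophan catabolism:
TDO (EC 1.13.11.11) or IDO (EC 1.13.11.52) opens the indole ring, and
kynureninase (KynU, EC 3.7.1.3), a PLP-dependent hydrolase, converts KYN to
anthranilic acid (AA). Whether members of the oral microbiome encode a
*functional* KynU matters for host–microbe interactions, because AA and its
downstream metabolites (kynurenic acid, quinolinic acid, picolinic acid) are
immunologically and neurologically active.

`kynuscreen` implements the in-silico half of such a study as a pipeline of
five stages, each independently usable:

1. **screen** — which taxa plausibly carry the pathway genes;
2. **align** — how similar candidate KynU sequences are to reference enzymes;
3. **struct** — whether the predicted structures share the reference fold;
4. **props** — what band size each His-tagged expression construct should
   show on an immunoblot;
5. **quant** — what metabolite concentrations the validation LC-MS runs imply.

## Gene-presence screening

The screen consumes *snapshots*: an ortholog-annotation table (taxon, gene,
EC number, source), an oral-taxon whitelist, and a BLAST tabular (outfmt 6)
hit file from probing genomes with a known bacterial *kynU*. Live database
queries are deliberately out of scope — ortholog databases move, so taxon
counts are properties of a snapshot, not of the method. BLAST hits are kept
at e-value ≤ 0.001 (inclusive), deduplicated per taxon by best e-value, and
kept distinct from annotation evidence in the output, since the two
evidence classes have different failure modes. A **candidate** is an oral
taxon carrying *kynU* together with at least one pathway entry gene (*tdo*
or *ido*). Taxon names are matched exactly after whitespace/underscore/case
normalisation; fuzzy genus matching was considered and rejected as a silent
source of false merges.

## Sequence identity

Pairs are aligned with Needleman–Wunsch global alignment under affine gap
penalties, defaulting to BLOSUM62 with gap opening 10 and extension 0.5 —
the parameter set most GUI alignment tools default to; all three are
configurable and recorded in the run log. Percent identity needs a
denominator convention, and published "% identity" figures rarely state
theirs. The default here is the full alignment length (gap columns
included), which is the most conservative of the three conventions exposed
(`alignment_length`, `shorter_seq`, `longer_seq`). Identity figures quoted
for the same pair can therefore differ by a few points between conventions;
consumers comparing against published matrices should expect agreement
within a band, not digit-for-digit.

## Structural comparison

Structures are reduced to one CA per residue (`read_pdb()`): highest
occupancy altloc wins (ties by altloc letter), HETATM and waters are
dropped, MSE reads as methionine, and unknown residues become `X`.
Consecutive CA–CA distances outside 2.5–4.5 Å raise a warning, not an
error, because synthetic decoys legitimately violate chain geometry.
Internally everything is in Å; nm values are a reporting conversion (1 nm =
10 Å).

**RMSD.** The rigid superposition minimising RMSD over the paired atoms is
computed with the Kabsch algorithm (SVD of the cross-covariance with a
determinant correction, so a reflection can never be returned), and

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n} d_i^2}$$

over the $n$ paired atoms. Near-collinear point sets are flagged with a
stability warning: the in-plane rotation is then poorly determined.

**TM-score.** Fold similarity uses

$$\mathrm{TM} = \max_{\text{superpositions}} \frac{1}{L}
  \sum_{i \in \text{aligned}} \frac{1}{1 + d_i^2 / d_0(L)^2},
\qquad d_0(L) = 1.24\,(L-15)^{1/3} - 1.8$$

with $d_0$ floored at 0.5 Å (the cube-root form is undefined below
$L = 15$ and unphysically small below ~21). The normalisation length $L$
defaults to the first-named (reference) structure; because "which protein is
the target" is ambiguous in any pairwise report, batch output always
tabulates both directions (`tm_ab`, `tm_ba`). The maximisation is a
deterministic heuristic: Kabsch seeds from contiguous aligned fragments of
lengths $n$, $n/2$, $n/4$ (minimum 4, slid at half-fragment stride), each
refined by iterating {superpose on current subset → recompute distances →
keep pairs under a cutoff} with the cutoff starting at $d_0$ and growing by
0.5 Å whenever fewer than 3 pairs survive, for at most 20 iterations. The
full-alignment Kabsch frame is always a seed, so the reported TM-score is
never below the TM-score of the RMSD-optimal frame. No randomness is
involved: identical inputs give identical scores.

**Pairing.** For non-identical proteins the residue correspondence comes
from the global sequence alignment; `mode = "residue_number"` (pair residues
sharing a residue number) is offered because some comparison servers use it.

**Calls.** TM-score strictly above 0.5 ⇒ shared overall fold; RMSD strictly
above 0.3 nm ⇒ structural difference. Boundary values land on the negative
side of both calls, and both thresholds are configurable rather than
hard-coded. The two calls are deliberately reported together — a pair can
share a fold (TM 0.78) while still showing a local structural difference
(RMSD 0.39 nm). Which RMSD a comparison server reports (Kabsch-minimal or
TM-frame) is often unstated, so both are computed and tabulated
side-by-side (`rmsd_kabsch_nm`, `rmsd_tm_frame_nm`); the classification uses
the Kabsch-minimal value. A candidate without a usable predicted model is
reported `not_applicable` and the batch continues.

## Construct masses

Expression constructs are translated with the standard genetic code
(trailing stop trimmed; an internal stop is an error) and weighed by summing
*average* residue masses plus one water — average, not monoisotopic, because
an SDS-PAGE band estimates the average mass. The expression-tag constant
defaults to 0.84 kDa (N-terminal His-tag). The reporting precision is
2 d.p.; the package's mass table agrees with independent implementations to
well under the ±0.2 kDa that matters at band resolution.

## Metabolite quantification

Per-analyte calibration curves are ordinary least-squares lines of peak area
against standard concentration (≥ 3 points, ≥ 2 distinct concentrations;
r² < 0.99 warns; optional 1/x weighting). Quantification inverts the line;
a value below the analyte's limit of detection is *censored at the LOD* —
never reported as zero and never as the sub-LOD estimate (LODs here: 0.1 µM
for KYN/KYNA-scale analytes, 0.001 µM for AA). Replicate summarisation
forms the per-replicate **total** (extracellular + intracellular, a censored
fraction contributing 0 with its censoring counted) and reports the
arithmetic mean and *sample* standard deviation (n − 1) — three biological
repeats are a sample, not a population. A single replicate reports `NA` SD.
How an undetected intracellular fraction should enter a printed total is a
genuine policy choice; contributing zero while counting the censoring keeps
the totals conservative and the information auditable.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage is testable without downloads:

- `make_trace()` builds CA traces on an ideal α-helix (rise 1.5 Å, 100° per
  residue, radius 2.3 Å ⇒ CA–CA ≈ 3.8 Å) or decoy topologies (zigzag,
  3.8 Å-step random walk). Decoys of matched length give the fold
  classifier its negative branch.
- `perturb_trace()` applies a uniform random proper rotation (unit
  quaternion sampling, so no axis bias), a translation, then i.i.d.
  Gaussian coordinate noise, returning the ground-truth transform. For
  noise σ per axis the expected superposition RMSD is σ√3, which the test
  suite checks within 10% at n = 200.
- `make_screen_fixture()` plants a chosen candidate set (default 7 oral
  *tdo*+*kynU* taxa among 71 *tdo* carriers, the scale of a realistic
  snapshot) among oral non-carriers, non-oral carriers and above-cutoff
  BLAST decoys.
- `make_quant_fixture()` encodes known concentrations through a known
  line (default 1000 area/µM, intercept 50) with multiplicative Gaussian
  area noise.

All generators are seed-deterministic. What they do *not* emulate: real
protein folds (no secondary-structure mixture, no domain architecture),
alignment ambiguity between remote homologues, matrix effects or
heteroscedastic LC-MS noise, and real database taxonomies. Passing tests
therefore demonstrate the *machinery* — score arithmetic, optimisation,
censoring, bookkeeping — on known ground truth; they cannot certify scores
on any particular predicted model, which inherit the model's own
uncertainty.

## Numerical and design notes

- The d0 floor (0.5 Å), the cutoff schedule start (d0) and step (0.5 Å) and
  the iteration cap (20) are fixed, documented constants; changing them
  changes scores reproducibly because the search is RNG-free.
- Ties in the fragment search resolve toward the earlier seed (strictly
  greater TM is required to replace the incumbent), making batch output
  stable across platforms.
- Problem sizes in the tests and acceptance script (traces of 60–200
  residues, 71-taxon screens, 6-point calibrations) were chosen as the
  smallest sizes at which each statistical check is well-conditioned.
- Degenerate inputs fail loudly with typed conditions
  (`kynu_error_*`/`kynu_warning_*`), so pipelines can branch on the class
  rather than matching message text.

## Limitations

- The TM-score search is a heuristic; it is guaranteed not to fall below
  the Kabsch-frame score and is exercised against exhaustive fragment-seed
  enumeration on small cases, but global optimality is not guaranteed.
- Identity percentages depend on the denominator convention (above); the
  default is stated in every run log but is still a convention.
- The screen is only as good as its snapshots: an ortholog table from a
  different database version will legitimately change candidate counts.
- Censored values enter replicate totals as zero; distribution-aware
  censored estimators (e.g. maximum-likelihood under left-censoring) are
  out of scope.
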