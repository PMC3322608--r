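---
title: "Decision algorithms for automated crystallographic re-refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision algorithms for automated crystallographic re-refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrefine)
library(dplyr)
```

## The problem

Automated re-refinement of deposited macromolecular crystal structures
replaces a crystallographer's judgement with a closed set of rules: is
the test set usable, which B-factor parameterization does the data
support, which restraint weight is optimal, which waters should go, and
when should the pipeline give up on an entry altogether. `xrefine`
implements that decision layer. It deliberately does *not* perform
reciprocal-space refinement: all refinement work is delegated to an
abstract engine interface (`refinement_engine()`), and a deterministic
simulated engine ships with the package so that every decision path is
exercisable, and testable against planted ground truth, without any
external program.

## Quality metrics

All decisions consume a small set of metrics. The R factor
$R = \sum |F_{obs} - m F_{calc}| / \sum F_{obs}$ measures reciprocal-space
agreement; $R_{free}$ is the same quantity on a held-out test set. Because
$R_{free}$ is a noisy statistic, decisions are taken relative to its
estimated spread $\sigma(R_{free}) = R_{free}/\sqrt{2 N_{test}}$ and to
the expectation $R_{free,unb} = R \times R_{ratio}$, where $R_{ratio}$ is
the $R_{free}/R$ ratio expected for a converged, unbiased refinement. The
standardized excess $Z(R_{free}) = (R_{free,unb} - R_{free})/\sigma(R_{free})$
is positive when a model is *better* than expectation — suspiciously so
above 10 (a biased test set), alarmingly the other way below $-3$
(overfitting).

Two numerical choices here were genuinely open:

* **The scale $m$** in the R factor is defined only as "chosen to
  minimize the residual". We minimize the absolute residual by
  golden-section search (the objective is convex in $m$) to a tolerance
  of $10^{-8}$, after normalizing the calculated amplitudes so the
  bracket is scale-free. This makes `r_factor()` invariant under
  rescaling of either input to well below $10^{-9}$, which the tests
  assert.
* **The $R_{ratio}$ estimator.** The published closed form for restrained
  refinement depends on an effective restraint count that no engine
  reports uniformly. `estimate_r_ratio()` therefore implements the
  classical unrestrained approximation
  $[(N_{obs}+N_{par})/(N_{obs}-N_{par})]^{1/2}$ and *every* consumer
  (picker, bias tests, B-model selection) accepts an externally supplied
  ratio instead. When neither is available, downstream code treats
  $Z(R_{free})$ as undefined and falls back to gap-based cutoffs; an
  undefined $Z$ never crashes a selection and always loses a $Z$
  comparison.

## Reflection sanitation and completeness

`sanitize_reflections()` applies the standardization rules: only the
first dataset of a multi-dataset file is used (file order; no other
ordering criterion exists); negative amplitudes are impossible and
rejected while negative intensities are legitimate background-subtracted
observations and kept; a σ column whose values are all identical
carries no information and is flagged unusable (exact equality — these
are file values, not arithmetic); individual σ = 0 entries are reset to
the dataset's maximum σ. If every σ is zero the "reset to the maximum"
rule has no positive maximum to use, so the column is declared unusable
instead. Sanitation is idempotent, which the suite asserts on generated
datasets with planted defects.

`completeness()` is the observed fraction of the symmetry-unique
reflections inside the resolution sphere, with Friedel pairs always
merged; the point group is supplied as a list of index rotations
(identity for P1). The enumeration is checked against a longhand
brute-force oracle on a toy cell.

## The free set

An existing test set is swapped with the work set if it is the larger of
the two, then rejected if it holds more than 25% of the data or fewer
than 500 reflections — both strict, so the boundary values 500 and 25%
are kept, and the tests recover those constants by probing consecutive
integers. A missing or rejected set is recreated at 5%, raised to reach
1000 reflections when 5% falls short (ceiling division: the target is
exactly 1000), capped at 10%. Selection is uniform without replacement
from the caller's seed; stratification by resolution shell is a noted
extension point, not implemented, since the decision layer never
consumes shell structure.

A recreated set is biased by construction. An inherited set is tested:
$R_{free,calc} < R_{calc}$, $Z(R_{free,calc}) > 10$, or a recalculated
free–work gap below a third of the header gap all flag bias (the header
test is skipped when the deposited header carries no R factors — absence
of annotation must not force bias). A biased baseline is replaced by the
expectation $R_{free,unb,calc}$ and the protocol switches to resetting B
factors to the Wilson B with an extended cycle count.

## Categories, cycles, strategy

`assign_category()` bins models into six categories from data resolution
(half-open bins at 1.20, 1.70, 2.80, 3.50, 5.00 Å) with the
reflections-per-atom rule taking precedence (< 1.0 forces `xlow`,
1.0–2.5 forces `vlow`): solvent content makes resolution alone a poor
proxy for data density. The two lowest categories get jelly-body
restraints. The restraint-weight search spaces per category are
engine-tuning constants that are not published; the defaults are
log-spaced grids shrinking from 7 weights (`atomic`/`high`) to 3
(`vlow`) and a single automatic weight (`xlow`), all overridable through
`category_config()` — the package treats the grid contents as
configuration and only the grid *structure* as a decision.

`assign_cycles()` encodes the empirical cycle-count rules. The printed
rules do not state their interaction order; the implemented precedence
is legacy > anisotropic > new-free-set > default, with the "+5 cycles
without TLS" applied to the 20- and 30-cycle bases only. This is the
unique ordering that reproduces every printed single-condition count;
whether the +5 also applies to the 40/50/60 bases is not derivable from
the text, and we chose not to extend it.

## B-factor model selection

`route_parameterization()` routes on reflections per atom: above 18 the
nine anisotropic parameters per atom are twofold overdetermined and used
outright; 13.5–18 contests anisotropic against isotropic; 3–13.5 uses
isotropic; below 3 TLS is optimized first and isotropic is contested
against a single overall B; if TLS is unusable there, plain isotropic is
the fallback.

Contests are decided by `bselect()`. Step (i) rejects the complex model
if its *weighted* free R factor is higher — the weighted free R is named
by the selection rule, so it (not the weighted working R) also feeds the
Hamilton ratio. Step (ii) runs Hamilton R-factor ratio tests over a grid
of restraint weights $w_1$ (shared restraints) and $w_2$ (extra
restraints of the complex model), because the effective restrained
degrees of freedom are unknown: each grid point contributes a test with
free degrees $f = N_{obs} - N_{par,complex} + w_1 N_{restr,base} +
w_2 N_{restr,extra}$ and hypothesis dimension
$b = \Delta N_{par} - w_2 N_{restr,extra}$, and the complex model is
acceptable at that point iff the weighted-R ratio exceeds
$[(b/f)\,F(\alpha; b, f) + 1]^{1/2}$. The grids default to 0–1 in steps
of 0.1 and $\alpha = 0.05$; the published description says only "all
possible values" over a range, so both are configurable. $b$ is floored
at 1 to keep the F quantile defined, and an under-determined grid point
($f \le 0$) counts as not acceptable — a model the data cannot determine
cannot be justified by it. Below 30% acceptable tests the simple model
wins, above 95% the complex model; the band between (both bounds
strict) falls to step (iii): overrefinement checks via
$Z(R_{free})_{complex} < -3$, or, when $Z$ is unavailable, a free–work
gap cutoff of 4 percentage points for anisotropic and 6 for isotropic
complex models, and finally the requirement that the complex gap not
exceed twice the simple gap.

## Picking among candidate refinements

`pick()` guards against overfitting relative to the *starting* model.
Cutoffs come from the stage being judged (TLS-stage R factors for
TLS-model optimization, baseline values otherwise; the unbiased
expectation when the free set is biased); geometry cutoffs are 1.0,
relaxed to the baseline r.m.s. Z when that was already worse. Per
candidate the allowed maximum
$R_{free,max} = R_i R_{ratio} + 3.5\,\sigma(R_{free})_i$, capped at
$R_i + 0.06$ and floored at $(R_{free,co}/R_{co}) R_i$ — in exactly that
order, which the tests pin down arithmetically. Candidates violating any
limit are rejected with recorded reasons; `vlow`/`xlow` models must also
keep their free–work gap under twice the baseline gap. Among survivors,
the lowest free likelihood and the lowest $R_{free}$ are located; when
they disagree the higher $Z(R_{free})$ wins. Exact ties resolve to the
lower $R_{free}$ and then to input order — the published rules are
silent and the pipeline must be deterministic. An empty survivor set is
a legitimate outcome: the orchestrator then rebuilds from the original
model and final-refines with automatic weighting.

`pick()` is verified against an independent exhaustive
filter-and-argmin implementation on 1000 randomized candidate sets.

## Real-space scoring and rebuilding selection

`density_fit()` scores a group of atoms as the weighted mean density
over the grid points within each atom's radius, with a linear taper
$t(x) = \max(0, 1 - |x - x_a|/r_{atom})$ and atom weight
$w_a = occ_a/(1 + U_a)$, $U_a = B_a/8\pi^2$. The published formula body
is typeset as an image in the source material, so the kernel follows the
verbal definition and is pluggable (`taper` argument); consequently the
0.37 water-pruning threshold is asserted against the decision rule with
injected scores, not against this particular kernel. Atom radii default
to a small per-element table (C 1.7, N 1.55, O 1.52, S 1.8 Å),
overridable. Scores are evaluated on grid points with no interpolation,
matching the definition's "at grid points".

`centrifuge()` removes waters scoring below 0.37 (strict) on the
normalized 2mFo−DFc scale, never touching waters involved in LINK
records. `rebuild_candidates()` starts from everything-eligible and
applies negative selection: peptide flips skip residues whose backbone N
or O is linked and residues in the middle of helices or strands
(`ss_middle()` defines "middle" as both flanking residues sharing the
state); side-chain rebuilding skips linked side chains and multiple
conformations. `validation_tasks()` adds the positively selected fix-ups
(His/Asn/Gln flips, Asp/Glu/Phe/Tyr χ-standardization, Arg Nε unswaps,
Thr/Ile/Val Cβ and Leu Cγ chirality fixes) with the negative selectors
still applying.

## The pipeline state machine

`reproduce_baseline()` first resolves the TLS ambiguity (total versus
residual B factors) by evaluating with and without the header TLS model
and keeping the lower $R_{calc}$, then runs the escalation ladder only
while the gap to the header R exceeds 5 percentage points: twin targets
(gated on an external twin-fraction estimate above 5%), rigid-body
refinement, then 5 cycles of TLS refinement against corrupted header
tensors — in exactly that printed order; a rung's result is adopted only
if it lowers $R_{calc}$ and an engine failure at a rung is recorded
while the ladder continues. A terminal gap above 10 points aborts the
entry as unreproducible; a missing header R factor aborts before
anything runs. The two gap thresholds are percentage points on the R
scale. The baseline twin rung uses only the external-fraction gate while
the strategy-stage `twin_policy()` additionally requires an engine twin
operator with $R_{merge} < 44\%$ and fraction $> 7\%$ — the two stages
state different tests and both are implemented as stated.

`run_pipeline()` sequences sanitation, free-set handling, baseline
reproduction, category and strategy assembly, weight-grid re-refinement
with `pick()`, rebuilding dispatch (water pruning always; the peptide
and side-chain stages only for `atomic`–`low`, since very-low-resolution
maps do not support unsupervised rebuilding), and a final refinement at
the chosen weight plus one grid step to either side ("slightly tighter,
slightly looser" is unprinted; one grid step is the resolution-consistent
reading). Every branch lands in a `decision_report` whose JSON
serialization is byte-identical across equally seeded runs.

## What the synthetic generators emulate — and what they do not

`gen_reflections()` enumerates real P1 lattices and draws Wilson-like
intensities with B-factor falloff, planting sanitation defects on
request; `simulated_engine()` responds with a convex quadratic
$R_{free}$ in log restraint weight around a planted optimum, linearly
loosening geometry, configurable TLS gains and baseline-ladder gains;
`gen_map_and_waters()` builds Gaussian-sum densities with waters planted
in peaks and in flat solvent. The default profile describes a routine
2.0 Å, 4-reflections-per-atom case with a converged R of 0.18 and a
0.04 free–work gap — unremarkable values for a mid-resolution protein
structure. These generators expose every decision branch, which is their
job; they are *not* physically realistic structure-factor simulations.
Passing tests therefore demonstrate that the decision rules fire exactly
at their published constants and compose deterministically — not that
the pipeline improves real deposited models, which requires a real
refinement engine behind the interface.

Problem sizes in the suite are kept small on purpose (hundreds of
reflections, 32³ grids, ≤ 7 candidates, 100-run sweeps): the decision
layer's behaviour does not depend on data volume, and the boundary
probes are exact at any size.

## A worked fragment

```{r example}
profile <- synthetic_profile(seed = 7)
inputs <- gen_pipeline_inputs(profile)
result <- run_pipeline(simulated_engine(profile), inputs, seed = 7)
glance(result$report)
tidy(result$report) |> select(decision, outcome) |> head(8)
result$chosen_weight
```

## Known limitations

* Reciprocal-space refinement, map coefficient calculation, σ~A~
  estimation, French–Wilson intensity conversion and external validation
  programs are all outside the interface: their outputs are inputs here.
* NCS handling, automatic chirality repair and water *addition* are not
  implemented.
* mmCIF coordinate input is not supported (PDB-format coordinates only);
  structure-factor mmCIF is.
* The Hamilton grid endpoints and α, the category weight grids, the
  atom-radius table and the density taper are package defaults standing
  in for unpublished constants; all are configurable at their call
  sites.
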