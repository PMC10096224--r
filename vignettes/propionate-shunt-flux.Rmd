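---
title: "Modelling B12-dependent propionate metabolism: methods and design"
author: "b12flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling B12-dependent propionate metabolism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b12flux)
```

## The biological problem

*C. elegans* degrades propionate by two routes. The canonical route runs
through propionyl-CoA carboxylase and the vitamin B12-dependent
methylmalonyl-CoA mutase into succinyl-CoA and the TCA cycle. When dietary
B12 is scarce, an alternative five-step "propionate shunt" is
transcriptionally activated: propionate is oxidised via
3-hydroxypropionate (3HP) and malonic semialdehyde (MSA) to acetyl-CoA.
The 3HP-oxidation step, catalysed by HPHD-1, is a coupled reaction: it
reduces alpha-ketoglutarate (aKG) to D-2-hydroxyglutarate (D-2HG) while
oxidising 3HP, yielding one equivalent each of MSA and D-2HG. DHGD-1
re-oxidises D-2HG back to aKG. This couple means shunt flux is only
sustainable while D-2HG is recycled: losing DHGD-1 starves HPHD-1 of aKG
and blocks the shunt, with downstream consequences for ketone-body and
energy production from propionate and from the ketogenic amino acids
lysine and leucine.

`b12flux` implements the computational machinery used to study this
system: flux balance analysis (FBA) on a constraint-based metabolic
network with a cumulative knockout protocol, stable-isotope tracer
arithmetic, coexpression-compendium ranking with preranked gene set
enrichment analysis (GSEA), and differential metabolomics. Each stage is
exercisable on bundled synthetic data with known ground truth.

## Flux balance analysis

FBA solves the linear program

$$\max_v \; v_{obj} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

where $S$ is the stoichiometric matrix. Models are read from
COBRA-compatible JSON (the format in which the genome-scale *C. elegans*
network iCEL1314 is distributed by WormFlux) or, best-effort, SBML Level 3
FBC. Non-finite or very large bounds are clamped to the COBRA convention
of ±1000 model flux units so the polytope is always bounded.

The LP engine is a bounded-variable primal simplex with Bland's
smallest-index rule, which guarantees finite termination without cycling.
This solver is implemented in the package because the LP routines
available in the supporting libraries proved unreliable on FBA-sized
problems; its correctness is established two independent ways in the test
suite: (a) on randomly generated networks of up to 8 reactions every
objective value is compared with exhaustive enumeration of basic feasible
solutions, to 1e-8 relative; (b) on the bundled toy network every
production potential is compared with a closed-form bottleneck
calculation. Solutions additionally pass a post-solve audit
($\lVert S v\rVert_\infty \le 10^{-6}$, bounds respected).

Because individual fluxes of a single FBA optimum are degenerate, the
package never interprets a non-objective flux from one solution. Where a
protocol needs "the flux of reaction X at the optimum", it uses a
flux-variability query (`maxFluxAtObjectiveFraction`): the maximum flux X
can carry while the objective is held at a fraction of its optimum. This
makes the quantity well defined and solver-independent. Tests compare
objective values, never full flux vectors, across reaction orderings.

## The simulation protocol

`runB12Protocol()` encodes the scenario grid:

1. **Base constraints.** The glyoxylate-shunt reaction is made
   irreversible (lower bound 0) and propionate secretion is blocked
   (upper bound 0), forcing ingested propionate through its degradation
   pathways. The model's own dietary-intake and maintenance constraints
   are left as shipped.
2. **Background activity.** Biomass is maximised; then the
   methionine-synthase (MS) reaction is capped at half its
   flux-variability maximum and biomass is re-maximised, giving the
   low-B12 biomass potential. For all subsequent simulations the biomass
   reaction carries this level as a lower bound (the background metabolic
   activity) while the MS cap is removed. The biomass floor applies to
   the replete-B12 runs as well — the protocol installs it once, before
   any scenario runs, which is the literal reading of the ordering; this
   choice is inconsequential for feasible scenarios but is recorded here
   because the alternative (low-B12 runs only) is defensible too.
3. **Scenarios.** For each B12 state — replete, and low (MS capped at
   half, methylmalonyl-CoA mutase fixed at zero) — four cumulative runs:
   wild type; DHGD-1 reaction knocked out; plus the lysine-degradation
   entry reaction (AASS-1); plus methylcrotonyl-CoA carboxylase (MCCC).
   Each run inherits all previous constraints.
4. **Objectives.** In every scenario the fluxes of the energy demand,
   acetoacetate export and 3-hydroxybutyrate export reactions are
   maximised, giving an 8 x 3 production-potential table. Infeasible
   cells are reported as infeasible, never as zero — conflating the two
   would corrupt the monotonicity semantics of cumulative knockouts.

Reaction identities are injected through a role -> id map
(`defaultIdMap()` carries the iCEL1314 ids, `toyIdMap()` the toy ids), so
the same protocol drives the genome-scale model, when the user supplies
it, and the bundled toy network.

"Half of its value" for the MS constraint is interpreted as half the
flux-variability maximum at the unconstrained biomass optimum, for the
degeneracy reason above. The MS fraction (default 0.5) and the solver
tolerance (default 1e-9) are configurable.

## The toy network

`makeToyNetwork()` builds a 19-metabolite, 31-reaction network that
reproduces the structural logic of the genome-scale system while staying
fully analysable by hand:

- bacterial food digestion yields nutrients (2 ATP each) but releases 0.5
  propionate per unit, which must be disposed of once secretion is
  blocked; an inefficient propionate-free digestion route (0.25 nutrient
  per food) exists as a fallback;
- the canonical (mutase) route and the shunt (3HP -> MSA -> acetyl-CoA,
  with the HPHD/DHGD aKG <-> D-2HG couple modelled stoichiometrically)
  are energy-equivalent per propionate, so losing either alone is
  neutral;
- lysine degrades via 2-aminoadipate and glutarate to acetoacetate;
  leucine yields acetyl-CoA plus acetoacetate; ketogenesis,
  ketone-body oxidation and a reversible acetoacetate <->
  3-hydroxybutyrate interconversion connect the pools;
- every ATP costs one unit of a capped oxygen budget, so under replete
  B12 the energy potential is respiration-limited and knockouts are
  neutral; under low B12 with the shunt lost, food digestion collapses to
  the inefficient route and substrate supply becomes limiting.

Every substrate converts to ATP or to acetoacetate at a fixed exchange
rate (0.5 acetoacetate per ATP foregone), which makes every cell of the
production-potential table a minimum of sums of uptake bounds — the
closed-form truth stored alongside the model and asserted by the tests.
Default uptake bounds (food 10, propionate 4, lysine 2, leucine 2, oxygen
25, biomass cap 5, maintenance 0) were chosen once so that all scenarios
of the default protocol are feasible, the replete rows are
oxygen-limited, and the low-B12 knockout rows are substrate-limited; they
are the reference study conditions of the test suite.

The `biomassRequiresMet = TRUE` variant couples biomass to methionine
produced by the MS analog, with a methionine-precursor uptake of 9.1.
Halving the MS flux-variability maximum (2 x 5 x 0.91) then lowers the
biomass potential from 5 to 4.55, i.e. by 9 percent — the documented
magnitude of the low-B12 biomass reduction in the genome-scale *C.
elegans* model. This variant lets the background-activity code path be
verified quantitatively without bundling the genome-scale model, which is
distributed externally.

What the toy network does not emulate: cofactor balancing beyond the
oxygen budget, compartments, biomass composition, and the thousands of
alternative routes of a genome-scale network. Passing the toy-network
tests therefore demonstrates that the protocol arithmetic and constraint
bookkeeping are correct, not that any particular genome-scale prediction
is.

```{r toy}
toy <- makeToyNetwork()
ppt <- runB12Protocol(toy$model, toyIdMap())
ppt
```

## Isotope tracer arithmetic

Two correction paths are exposed, matching how deuterium and 13C
experiments are analysed:

**Paired enrichment (no matrix).** For labeled/unlabeled sample pairs,
isotopologue abundances are normalised to M+0 and differenced:
$R_i = L_i/L_0 - U_i/U_0$, and the relative enrichment is
$R_i/(R_i+1)\times 100$ percent. Comparing against the paired unlabeled
sample subtracts the natural-abundance contribution (e.g. the M+1 from
13C at natural abundance) without a correction matrix. The statistic is
scale-invariant, zero for identical samples, and undefined — reported as
`NA`, never as 0 — when M+0 is zero or $R_i \le -1$.

**Matrix correction.** `correctionMatrix()` builds the standard
convolution matrix: column $j$ is the predicted measured distribution of
a species with exactly $j$ labeled atoms, from binomial convolution of
the natural isotope distributions (NIST standard atomic compositions,
pinned as package constants) of all non-label atoms plus the unlabeled
remainder of the label element, truncated at the measured length (columns
sum to at most 1). Tracer isotopic purity is assumed to be 1.
`correctNaturalAbundance()` inverts a measured vector by non-negative
least squares (Lawson-Hanson) and renormalises to fractions; with noisy
input the NNLS constraint clips negative components at zero and the
relative residual is reported. Derivatisation-added atoms (e.g. TMS
groups) are part of the fragment formula supplied by the caller — the
package does not infer instrument chemistry.

## Coexpression and preranked GSEA

`buildCompendium()` z-normalises each gene within each dataset (datasets
with fewer than 10 conditions are dropped; constant rows are dropped and
logged, since their z-score is undefined) and concatenates datasets over
the union of genes, with `NA` where a gene is missing. Z-normalisation
preserves within-dataset Pearson correlations exactly.
`rankByCorrelation()` ranks genes by pairwise-complete Pearson
correlation with a query gene, requiring at least 10 shared conditions
per pair (pairs below that are excluded rather than reported with an
unstable estimate); ties break lexicographically so rankings are
deterministic.

`prerankedGSEA()` implements the classic weighted running-sum enrichment
statistic (weight exponent 1 on |r|, configurable), with a gene-label
permutation null — the only null available for an externally ranked
list. The normalised score divides the observed ES by the mean |null ES|
of the same sign, and the false discovery rate follows the
positive/negative-tail convention (pooled null NES at least as extreme
over observed NES at least as extreme, clipped to [0, 1]). Results are
bit-for-bit reproducible for a fixed seed. Sets overlapping the universe
in fewer than 2 genes are skipped and logged. The running-sum statistic
is verified against a brute-force walk and against an independent
implementation from the fgsea package.

The synthetic compendium plants one latent-factor module (pairwise
correlation `moduleRho`, default 0.8, among 6 genes in a 500-gene
universe; 8 datasets of 15 conditions, plus 2 undersized datasets to
exercise the filter). These defaults give comfortable separation between
module and background correlations at the pooled compendium size; the
test suite requires the planted set at FDR <= 0.05 in at least 95 of 100
seeded compendia and near-uniform permutation p-values for random sets.
What this does not show: robustness to the heteroscedastic,
batch-confounded structure of real expression compendia.

## Differential metabolomics

`preprocessAbundance()` subtracts the mean blank per metabolite (flooring
negatives at zero and flagging them) and divides each sample by its own
total over the quantified panel, so normalised samples sum to 1 — the
"normalisation to total quantified metabolites" convention. The
denominator is the sum over the targeted panel present in the table.
`differentialAbundance()` reports per-metabolite log2 fold changes of
group means on normalised values, a two-sample t test, and
Benjamini-Hochberg adjustment. Welch (unequal variance) is the default
because group variances differ whenever abundances differ under
multiplicative noise; a pooled-variance option exists. Fold changes are
computed on normalised values — whether raw or normalised areas is a
genuinely open choice, and normalised was selected for consistency with
the rest of the stage.

The generator's default replicate noise (CV 0.2) models typical targeted
GC-MS biological replicates; at that noise, Welch with ~4 degrees of
freedom detects a planted 4-fold change after BH in about 94 percent of
runs with 5 replicates per group. The power check in the acceptance
suite runs the low-noise condition (CV 0.1), where detection is
essentially certain; the type-I checks (pooled raw rejections near the
nominal 5 percent; few runs with any BH discovery under the global null)
use the default noise.

## Numerical choices, degenerate inputs, limitations

- Solver feasibility tolerance 1e-9, reported in every `FluxSolution`;
  mass-balance audit at 1e-6.
- Bound sentinel ±1000 for "unbounded" reactions (COBRA convention).
- Zero-variance groups in the t test: identical constant groups give
  p = 1, differing constant groups p = 0, rather than an error.
- Zero M+0 intensities and R <= -1 give `NA` enrichments, never 0.
- Gene-reaction rules are parsed into boolean trees; gene-level knockout
  is deliberately not implemented — the protocol constrains reactions,
  and the only gene-level operation needed is restricting a gene to a
  subset of its reactions (`restrictGeneToReactions`, used for the
  HPHD-1 pre-simulation edit).
- Problem sizes in the test and acceptance suites — 50 random networks
  for the LP oracle, 100 compendia for GSEA recovery, 200 simulations
  for metabolomics calibration, 1000 GSEA permutations — were chosen as
  the smallest sizes at which the binomial assertions (e.g. ">= 95% of
  runs") are stable across seeds.
- Not implemented (out of scope): parsimonious FBA, flux sampling,
  MOMA/ROOM, thermodynamic constraints, model gap-filling, MATLAB model
  files, untargeted metabolomics feature detection, and leading-edge
  GSEA analysis.

## Reproduction driver

`runReproduction()` ties the pieces together: it applies the HPHD-1
restriction edit, runs the protocol, writes the production-potential
table, the ordered constraint log and a configuration echo, and — in toy
mode — verifies every cell against the planted closed-form truth,
failing loudly on any deviation. Two runs with the same configuration
produce byte-identical reports.
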