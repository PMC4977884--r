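---
title: "Core metabolic models of bacterial energy metabolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core metabolic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

Automatically reconstructed genome-scale metabolic models are
notoriously unreliable at the one thing central metabolism is mostly
about: making ATP. Interweaving pathways create thermodynamically
absurd energy loops, electron transport chains (ETCs) are flattened
into single lumped reactions, and aggressive gapfilling pastes in
pathways the organism never had. `coremetab` takes the opposite
approach: a small, manually curated *core model template* (CMT)
restricted to central carbon metabolism, fermentation, and explicit
ETC variants, from which a *core metabolic model* (CMM) is instantiated
for any genome directly from its functional-role annotations — with no
gapfilling in the energy analyses, so that predictions reflect the
annotation evidence and nothing else.

The pipeline is: **template → per-genome model (GPR evaluation) → flux
balance analysis (ATP yield, biomass-precursor producibility) →
Boolean pathway and respiration classification → corpus-level
co-occurrence and phylogenetic visualisation**, with an optional
gapfilling diagnosis of models that cannot grow.

# The stoichiometric model

A model is a set of reactions with signed stoichiometries over ~100
compounds in two compartments (cytosol `_c`, extracellular `_e`).
Flux balance analysis solves

$$\max_v \; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

where the steady-state constraint covers *every* compound, including
both proton species. Two objectives are supported: the ATP hydrolysis
reaction `ATP + H2O -> ADP + Pi + H+` (`ATPM`), whose optimum divided
by the carbon uptake flux is the ATP yield in mmol/mmol; and a biomass
objective over the 12 canonical central-carbon precursors (G6P, F6P,
R5P, E4P, GAP, 3PG, PEP, PYR, AcCoA, OAA, AKG, SucCoA) with the
classical early *E. coli* coefficients (41.257 ATP, 18.225 NADPH
consumed, 3.547 NADH produced per gDW). The two CoA thioester
precursors return free CoA wherever they are drained — the core
network rightly cannot synthesise the carrier de novo.

Exchange reactions are written `x_e <=>` with positive flux =
secretion; a medium is a table of (max uptake, max secretion) bounds
that overrides template bounds on exchange reactions *only*. The seven
packaged media are {glucose, glycerol} × {O₂, nitrate, TMAO} plus
glucose without any acceptor; carbon uptake is capped at
10 mmol·gDW⁻¹·h⁻¹. Yields are per-mol, so this cap is immaterial — a
scale-invariance test asserts exactly that. All internal reactions are
bounded at ±1000, which structurally rules out unbounded flux loops.

# Electron transport and the proton balance

The proton-motive force is modelled by distinct cytosolic and
extracellular proton species; every translocation appears explicitly
in a reaction's stoichiometry, so element/charge balance and the
"protons pumped" bookkeeping are one and the same. The calibrated
translocation parameters are:

| reaction | H⁺ moved out per unit flux |
|---|---|
| NADH dehydrogenase I (`NADH16`) | 4 (plus 1 scalar H⁺ consumed) |
| NADH dehydrogenase II (`NADH5`) | 0 |
| cytochrome *bo* oxidase (`CYTBO3`) | 4 per ½ O₂ |
| cytochrome *bd* oxidase (`CYTBD`) | 2 per ½ O₂ |
| nitrate reductase (`NAR`) | 2 |
| TMAO reductase (`TMAOR`) | 0 |
| fumarate reductase (`FRD7`) | 0 |
| ATP synthase (`ATPS4r`) | −4 per ATP (reversible) |
| formate exporter (`FORt`) | +1 (symport) |
| CO₂ efflux (`CO2t`) | +1/3 (partial bicarbonate-coupled) |

These values were fixed once, by the documented calibration: with the
textbook 4/4/4 stoichiometry the aerobic glucose optimum of the
*E. coli*-like fixture is 26 ATP/glucose (10 NADH × 8 H⁺ + 2 QH₂ ×
4 H⁺ = 88 H⁺ → 22 ATP, plus 4 by substrate-level phosphorylation);
the fractional CO₂ proton coupling adds the remaining ½ ATP (6 CO₂ ×
1/3 H⁺ / 4 H⁺·ATP⁻¹), and the formate symport with a partially
reversed ATP synthase sets the fermentative optimum to 3 − ¼ = 2.75.
Both packaged anchor values (26.5 aerobic, 2.75 fermentative) are
recomputed from scratch by `scripts/acceptance.R` and the test suite;
they are never read from a table. The same parameters then *predict*
(rather than fit) the remaining grid — e.g. nitrate respiration at
20.5, TMAO at 14.5, glycerol aerobic at 14.25 per mol — and the
fermentation-only fixture's yield is identical under every acceptor.

Sulphate/iron/chromium-reducing ETC variants are excluded (their
annotations are not consistently propagated); a single quinone pool
stands in for the ubiquinone/menaquinone distinction; there is no
periplasm. These simplifications bound what the model can say about
organisms whose bioenergetics hinge on those features.

# Reconstruction and evidence

A template reaction enters a genome's model iff its gene–protein–
reaction (GPR) Boolean rule — `and`/`or` over quoted functional-role
strings — evaluates true over the genome's roles, or it is marked
`spontaneous` (e.g. neutral-species diffusion) or `universal`
(exchanges, ATP hydrolysis, water/mineral transport; always included
so FBA is well-posed on any genome, including an empty one). Role
matching is exact string equality after case folding and whitespace
squeezing; unknown roles are recorded and ignored, never fatal.
Reconstruction is therefore deterministic, monotone in the role set,
and idempotent — each a tested property.

# Pathway rules, respiration classes, capability

Each of the 12 pathways (4 glucose-oxidation: glycolysis,
Entner–Doudoroff, TCA, pentose phosphate; 8 fermentation: lactate,
acetate, formate, ethanol, 2,3-butanediol, butyrate, butanol, acetone)
is an ordered list of steps, each step a set of alternative reactions;
a pathway is present iff every step has at least one member in the
model. The rules ship as data (`pathway_rules.json`), so curation is
editable without touching code. Product transporters are rule steps —
a fermentation pathway without its exporter is called absent, which is
exactly how missing formate-transporter annotations surface — but a
configurable exemption list (`exempt_transporters`) can treat the
diffusion-plausible ones as satisfied. The gluconolactonase step is
deliberately kept mandatory in the ED rule: its frequent absence in
otherwise ED-complete genomes is a finding we want the rule to expose,
not to paper over.

Respiration: an aerobic chain needs (≥1 aerobic terminal oxidase) ∧
(≥1 respiratory dehydrogenase) ∧ ATP synthase; anaerobic analogously;
both → facultative; neither → none (fermentation-only). Note that a
single spurious oxidase annotation flips an anaerobe to "aerobic" —
by design, because the phylogenetic outlier screen is the mechanism
meant to catch it.

FBA-based fermentation *capability* (maximal product secretion > ε
under an acceptor-free medium) is deliberately distinct from Boolean
*presence*: a pathway can be annotation-present yet redox-blocked
(for instance 2,3-butanediol without any electron sink — the pathway
consumes one NADH per two pyruvate while glycolysis produces one per
pyruvate). The test suite asserts that such discrepancies are surfaced
rather than silently reconciled.

# Gapfilling

Gapfilling asks for a cardinality-minimal set of template reactions
whose addition lets the model carry biomass flux ≥ ε on a medium.
Candidates are pruned by a sound reduction — a reaction that cannot
carry flux even when *every* candidate is open can never help any
subset — and the minimal set is then found by exhaustive iterative
deepening over lexicographically ordered subsets, which makes the
result eps-exact, provably minimal, and deterministic (ties broken by
reaction id). A branch-and-bound search on the 0/1 indicator MILP is
kept as a fallback for solutions too large to enumerate; its growth
forcing is scaled to 1% of the fully augmented optimum because forcing
only ε makes the big-M relaxation degenerate (the indicator variables
sit below any integrality tolerance). "Added or modified" is
simplified to additions, with uniform costs; an unusable carbon source
returns a structured "unfillable" result. The plain-enumeration oracle
(`gapfill_bruteforce`) is a separate code path used to verify
minimality on small instances.

Models that fail on glucose can be probed with
`alternate_carbon_rescue()` (glycerol, lactate, succinate, ribose,
without gapfilling) — the packaged strict-aerobe fixture, whose ED
pathway is broken only by a missing gluconolactonase annotation, grows
on glycerol and succinate but not glucose, which is precisely the
diagnostic pattern this function exists to reveal.

# Co-occurrence statistics

Profiles are deduplicated by 16S key (best quality wins, ties by
genome id), stratified by model size (small < 93 reactions, medium
93–133, large > 133), and every pathway pair is scored with the
Pearson correlation of the 0/1 vectors — identical to the phi
coefficient of the 2×2 table — with the p-value from
\(t = r\sqrt{(n-2)/(1-r^2)}\) on \(n-2\) df. Raw p < 0.05 defines
significance (matching the original reporting); Holm correction is an
opt-in flag. Zero-variance columns give flagged "undefined" entries,
never NaN. Type-I error control is asserted by simulation: on 1000
independent Bernoulli profiles the significant-pair rate must sit
within three binomial standard errors of 5%. A pair is "consistent"
when sign and significance agree across all three size classes.

# Tree collapse and annotation export

A consumed newick tree (midpoint-rooted if unrooted) is collapsed at
an evolutionary distance threshold (default 0.01): every maximal
rooted clade whose leaf-pairwise patristic diameter is strictly below
the threshold is replaced by its highest-quality leaf (missing scores
fall back to lexicographic labels, with a message). One such pass is
not idempotent — representatives of adjacent collapsed clades can
themselves fall within the threshold — so the pass is iterated to a
fixed point; every individual merge still satisfies the strict
diameter guarantee against the original distance matrix, and both
properties are tested on random trees. Leaf annotations (Boolean
pathway vector, respiration class, one colour per distinct vector,
explicit "missing" states) export as a TSV dataset for circular tree
viewers, and `flag_profile_outliers()` implements the annotation-error
screen: a leaf is flagged when its vector differs from *all* leaves
within a patristic radius of five times the collapse threshold.

# The synthetic generator and the packaged fixtures

`generate_annotation_set()` inverts the pipeline: for each requested
pathway it takes the first alternative of every rule step and emits
all roles of that reaction's GPR, plus the roles of the requested ETC
variant(s), minus independent per-role Bernoulli dropout, plus decoy
roles that match no template leaf. At zero dropout the requested
presence vector round-trips exactly through reconstruction and rule
evaluation (tested on 100 random specifications); the dropout default
is 0 because the annotation-inconsistency literature motivates the
noise model but supplies no rate. What the generator does *not*
emulate: correlated annotation errors within subsystems, paralog
confusion, contamination, or any sequence-level process — so passing
tests demonstrate the pipeline's internal consistency, not robustness
to real RAST error modes.

The seven packaged fixtures are synthetic organism-style role lists
(`*_like`) curated from the template: a facultative enterobacterium
(the calibration anchor), a Gram-positive nitrate respirer missing its
pyruvate carboxylase annotation (the canonical one-reaction gapfill),
a strictly fermentative butyrate/butanol/acetone producer whose yield
ignores acceptors, an ED-only pseudomonad without phosphofructokinase,
a genome-reduced parasite that cannot make nine of twelve precursors,
a strict aerobe with the gluconolactonase gap, and an anaerobe
carrying a spurious bd-oxidase annotation (misclassified "aerobic" on
purpose; at its aerobic optimum it runs the oxidase *and* secretes
acetate, the mixed respiration–fermentation mode). Each ships with a
frozen manifest of its reaction set, pathway vector, respiration
class, per-medium yields and fermentation capabilities, computed by
the pipeline at curation time; the two paper-anchored yields are
asserted against their published values, not the manifest.

# Numerical choices

* LP solver: a dense bounded-variable two-phase revised simplex
  written for this package (no LP package of adequate scale is
  available in the target environment); Dantzig pricing with a Bland
  fallback against cycling, product-form basis updates with periodic
  refactorisation, feasibility/optimality tolerance 1e-9. Small
  instances are cross-checked in the tests against brute-force vertex
  enumeration and an independent simplex implementation.
* Producibility/growth/capability threshold ε = 1e-6 flux units.
* Degenerate optima: yields are unique even when flux vectors are not;
  reported flux vectors are one optimal basic solution, and no
  flux-variability analysis is attempted.
* Problem sizes used in the shipped checks — 50 synthetic models for
  the conservation/monotonicity properties, 7 seeded deletions for
  gapfill minimality, 1000 profiles for the alpha-level simulation,
  100 specifications for closed-loop recovery, 100 random trees for
  collapse — were chosen as the smallest sizes at which each property
  is sharply distinguishable from noise.

# Known limitations

The template is a curated re-derivation, not the original supplement:
reaction identity, the seven media, and the Boolean rule content were
reconstructed from standard biochemistry and the published pathway
scope, so corpus-scale counts from the original 8,179-genome study are
out of reach by construction. Yields for organisms using bifurcating
electron transfer, sodium-motive chains, or menaquinone-specific
couplings will be approximations at best. The biomass objective stops
at precursor stoichiometry — no growth-associated maintenance beyond
the ATP term, no macromolecule composition. Gapfilling searches the
template universe only.
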