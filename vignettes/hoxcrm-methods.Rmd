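---
title: "Methods: affinity models, site engineering and segment-level expression logic"
author: "hoxcrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: affinity models, site engineering and segment-level expression logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxcrm)
```

# The problem

Drosophila has eight Hox transcription factors (Lab, Pb, Dfd, Scr, Antp,
Ubx, Abd-A, Abd-B) with nearly indistinguishable monomer DNA-binding
preferences: a short, 6-bp AT-rich footprint around a TAAT core (Abd-B,
with a divergent homeodomain, prefers TTAT or TTAG). In vivo, however, each
factor regulates its own targets. A large part of the resolution lies in
cofactor complexes: bound together with the TALE proteins Extradenticle and
Homothorax (Exd/Hth), the recognition site widens to about 12 bp and a
*latent specificity* appears, splitting the family into three classes by
preferred 8-bp core:

| class | core | members |
|-------|------|---------|
| 1 | `TGATTGAT` | Lab, Pb |
| 2 | `TGATTAAT` | Dfd, Scr |
| 3 | `TGATTTAT` | Antp, Ubx, Abd-A, Abd-B |

The three cores differ *only at core position 5* (0-based; G/A/T), so a
single base substitution converts a site from one class to another. Flanking
bases on either side of the core further grade the affinity of each complex
without changing its class.

hoxcrm provides the in-silico layer for studying how such sites control a
segmentally expressed enhancer: affinity scanning, site classification,
rational site engineering, and a segment-level activation model that
combines Hox input with a positive collaborator (JAK/STAT) and a negative
one (WNT).

# Binding-affinity models

An `EnergyModel` is a position-specific free-energy matrix: for a footprint
of $L$ bases it stores non-negative penalties $\epsilon_{i,b}$ (dimensionless,
$RT = 1$) for each position $i$ and base $b$. A window
$w = w_1 \dots w_L$ scores

$$\mathrm{aff}(w) \;=\; \frac{1}{Z}\exp\Big(-\sum_{i=1}^{L}\epsilon_{i,w_i}\Big),$$

where $Z$ (`normMax`) is a normalization constant. Models are *anchored*:
$\min_b \epsilon_{i,b} = 0$ at every position, so the optimal window scores
exactly 1 at $Z = 1$. Log affinity is exactly additive over positions; this
additivity is what makes per-position flank optimization exact (see below).

Two consequences are enforced at the API level:

* **Relative only.** $Z$ corresponds to a different, unknown dissociation
  constant for every factor, so affinities are comparable only *within* one
  model. No hoxcrm operation arithmetically combines affinities from two
  models; cross-model results are only reported side by side.
* **Explicit normalization.** `normalizeToReference()` rescales a model so
  that the best window over both strands of a user-supplied reference set
  scores 1. The reference universe is an explicit argument because the
  appropriate choice (genome, scaffold, construct family) is a scientific
  decision, not a default. After renormalization, windows better than the
  reference optimum can legitimately score above 1.

Unanchored or negative penalty matrices are rejected at construction and at
file load (the JSON schema names the offending position) rather than being
silently re-anchored: a silently shifted matrix would change every score in
a round trip.

Fitted matrices for the Hox-Exd complexes are not distributed with this
package. `modelFromCore()` therefore synthesizes *class-anchored* models
that encode the qualitative structure: the registered core is the unique
zero-penalty core (any other base at a core position costs `corePenalty`),
and each flank position has one optimal base (any other costs the smaller
`flankPenalty`). `defaultHoxModels()` builds one dimer and one monomer
model per factor this way.

## Default model parameters

The defaults in `defaultHoxModels()` are calibration constants, not
measured quantities:

* **Core mismatch penalty $\ln 50$** — a single core mismatch scores
  $0.02$, below the default site threshold of $0.05$. This encodes the view
  that exact core identity decides the class while flanks grade affinity,
  and it keeps near-core background windows out of site lists. (The
  `modelFromCore()` default of $\ln 10$ is gentler and suits exploratory
  scanning.)
* **Flank mismatch penalty $\ln 3$** — four dimer flank positions span a
  $3^4 = 81$-fold affinity range, enough to separate "weak",
  "intermediate" and "optimal-flank" sites cleanly.
* **Class-specific flank optima** — dimer and monomer flank preferences
  differ between the cephalic (class 1/2) and trunk (class 3) model sets.
  For monomers this is a deliberate simplification: real Hox monomer
  preferences differ only modestly, but distinct optima let the synthetic
  fixtures carry monomer sites that feed trunk factors without feeding
  cephalic ones, which is the configuration the modelled enhancer family
  displays.
* **Abd-B monomer degeneracy** — the Abd-B monomer model zero-penalties
  both TTAT and TTAG at the variable core position.

# Scanning conventions

`scanSites()` scores every window on both strands. Coordinates are 0-based
half-open plus-strand intervals throughout the package (BED export inherits
this); a minus-strand site's `window` field holds the reverse complement of
the plus-strand substring — the string that was actually scored. Sites are
ranked by descending affinity, then ascending start, then strand (+ before
−), which makes outputs byte-deterministic. Windows containing non-ACGT
characters score 0, are excluded from site lists, and are counted in a
logged notice; sequences shorter than the footprint scan to an empty list
with a notice rather than an error. `class_label` is assigned only when the
core positions of the scored window *exactly* match a registered class
core; near-cores keep their graded affinity but are labelled `none`.

The scanner is validated against an exhaustive oracle (every window on both
strands scored independently) on random sequences and models, along with
two properties: strand symmetry (scanning the reverse complement mirrors
the site list exactly) and threshold monotonicity (raising the threshold
only removes sites).

# Site engineering

`convertClass()` rewrites the core positions of a called site into a target
class core. Minimality is trivial to certify: the edit count equals the
Hamming distance of the two cores, which is 1 for every class pair. Edits
on minus-strand sites are mapped back to plus-strand coordinates with
complemented alternate bases.

`optimizeFlanks()` locks the core and picks, at every flank position, the
base with the lowest penalty. Because the energy model is additive,
independent per-position choice attains the model's maximum affinity
achievable with the core fixed — no search is needed. Ties keep the current
base when it is already optimal, otherwise the first optimal base in
A,C,G,T order. Conversion and flank optimization are deliberately separate
operations; a "class-x with optimal flanks" construct is their explicit
composition, mirroring how such variants are built and tested separately in
practice.

`knockoutSites()` finds a small substitution set after which no Hox site
survives. Two modes exist because "remove Hox input" means two different
things:

* **core mode** (default): destroy every exact occurrence of the forbidden
  cores (default: the three class cores) on both strands without creating a
  new one — the logic of mutagenesis designed against predicted cores.
* **affinity mode**: push every window of every supplied model below a
  ceiling — the model-quantitative version.

For sequences up to 60 bp and up to 3 edits the search is exhaustive over
ascending edit counts, so the result is *certified minimal*; single-edit
searches enumerate every position, and multi-edit searches restrict
candidates to bases covered by a current site (an edit elsewhere can only
create sites, never destroy one). Beyond those limits an iterative greedy
search is used: each step applies the substitution that best reduces the
residual site count, and the provenance records that the result is not
certified. Among equal plans the lexicographically smallest (position, then
alternate base in A,C,G,T order) is returned. Property tests check that
greedy results never beat, and on small instances match, the certified
minimum.

`restoreRegions()` splices original sequence back into selected intervals,
supporting knockout-then-restore designs whose round trip is exact.

`sideEffectAudit()` diffs the complete site content of two sequences:
exact-core occurrences (always) and per-model scan results (gained / lost /
affinity-changed, matched by start and strand). The canonical use case is
the overlap artifact: on the template `CCTGATTAATTTATCC`, converting the
class 2 core to class 1 (a single A→G at core position 5) simultaneously
creates a brand-new class 3 core `TGATTTAT` two bases downstream — an edit
whose collateral effect is invisible unless the whole sequence is re-scanned.
Every designed plan carries a `predictedEffects` audit that equals an
independent audit of its application (a tested invariant).

# The synthetic fixture suite

The enhancer this package's validation emulates is segmentally active,
about 680 bp, dissectable into three fragments (here 300 + 250 + 130 bp,
within the documented 200-680 bp fragment range), and carries a pair of
*overlapping* Hox-Exd sites — a conserved class 2 "main" site and a class 3
"overlapping" site sharing sequence — inside a 55-bp element that converts
an otherwise inert fragment into an active construct. Its true sequence is
not available as text, so `makeFixtureSuite()` builds a synthetic family
with that documented structure:

* the 55-bp cassette is `18 bp pad | C | TGATTAATGATTTAT | TGT | 18 bp pad`:
  a class 2 core at cassette offset 19 and a class 3 core at offset 26
  sharing exactly one base (offset 26), so one substitution at the shared
  base destroys both cores — the single-edit dual knockout the design
  space permits;
* the fixed flank bases give the main class 2 site affinity $1/9$ under the
  class 2 model (one matching flank of four), the overlapping class 3 site
  $1/81$ (no matching flank), a converted class 3 main site $1/9$, and a
  converted class 1 main site $1/3$ — a graded ladder that makes "weak but
  sufficient", "below threshold" and "optimal" behaviours separable;
* backgrounds are rejection-sampled to carry no class or monomer core on
  either strand, and every planted element is verified after assembly (the
  generator retries until the k-mer content equals the designed manifest
  exactly), so fixtures regenerate byte-identically from (version, seed);
* planted monomer sites are class-targeted: three Abd-B-type TTAT sites with
  optimal flanks in the S2-like fragment, three generic TAAT sites with
  trunk-optimal flanks in the S3-like fragment;
* the seven variant constructs (cl1 / cl2 / cl3, their optimal-flank
  versions, and the dual-core knockout `mut`) are produced by actually
  running the variant-designer operations, not by string editing.

What the fixtures do *not* emulate: the real enhancer's sequence and its
~18 monomer-site positions; the real (unpublished) overlap geometry of the
main/overlapping pair — in the real element the class 1 conversion
*strengthens* the overlapping class 3 site, whereas in this geometry it
leaves it intact (the artifact itself is reproduced on a dedicated crafted
template); chromatin context, accessibility, and binding cooperativity.
Passing tests therefore demonstrate correctness of the algorithms under the
documented site architecture, not sequence-level fidelity to the real
enhancer.

`noisyMeasurements()` adds unit-mean multiplicative lognormal noise with a
given coefficient of variation, standing in for quantified band
intensities. `recoverModelPenalties()` inverts the model by linear
regression of $-\log(\text{measurement})$ on per-position base indicators;
with $n = 500$ windows at $cv = 0.1$ all 18 penalty contrasts of a random
6-bp model are recovered within 3 standard errors (a check that, by
construction, a few percent of random seeds will narrowly fail — the fixed
validation seed is part of the frozen configuration).

# Segment-level expression logic

`predictExpression()` scores each (segment, intra-segment position) cell as

$$\mathrm{score} = \big[\, w_\mathrm{hox}\, H + w_\mathrm{stat}\, S -
w_\mathrm{wnt}\, W \,\big]_+ ,$$

with ternary calls off / weak / strong at two ordered thresholds. The Hox
drive $H$ sums, over factors occupying the segment (registry occupancy,
minus removed, plus ectopic factors), the best dimer-site affinity (zero
when cofactors are unavailable, emulating strong *hth* loss) plus the
factor's monomer competence times its monomer aggregate — the sum of
monomer-site affinities at or above 0.5, capped at 1. The cap reflects that
many weak monomer sites act cumulatively but cannot drive unbounded output;
the 0.5 monomer threshold means only moderately strong monomer sites
contribute, which keeps incidental AT-rich background out of the drive.
$S$ is a per-segment STAT level (site-level STAT scanning is out of scope);
$W$ is a positional mask with two intra-segment positions (WNT-on /
WNT-off), the minimal structure that distinguishes segmental patches from a
continuous stripe.

## Calibration of the default configuration

The biology constrains *signs and orderings*, not magnitudes: Hox input
alone is too weak to activate, STAT alone is insufficient, their sum
activates, and WNT vetoes. The shipped defaults
($w_\mathrm{hox}=1$, $w_\mathrm{stat}=0.2$, $w_\mathrm{wnt}=2$, thresholds
$0.3/0.7$) were calibrated once so that the full qualitative truth table
holds, then frozen. The key constraint is
$w_\mathrm{stat} \cdot S < 0.3 \le w_\mathrm{stat} \cdot S +
w_\mathrm{hox} \cdot H_\mathrm{weak}$: STAT must not activate on its own
(an inert fragment with a STAT site stays off; removing all Hox factors
silences every segment) yet must tip a weak Hox site over the threshold —
this is what forces $w_\mathrm{stat}$ well below the weak threshold. A
larger STAT weight with the same thresholds would call every segment
active regardless of Hox input, contradicting the modelled genotypes.
$w_\mathrm{wnt}=2$ exceeds the maximum attainable score of the default
fixture family ($\approx 1.8$ in the Abd-B domain), so WNT-on positions are
fully vetoed, as the patch-versus-stripe phenotype requires.

Registry expression domains are Lab: ic; Pb: none (not specified in this
system); Dfd: md, mx; Scr: lb, T1; Antp: T1-T3; Ubx: T3-A7; Abd-A: A2-A8;
Abd-B: A8-A9 — the per-factor granularity needed for the genotype
behaviours (stripe retained in A2-A9 without Scr/Antp/Ubx; retained in
A8-A9 without Abd-A as well; cofactor-independent activity confined to the
Abd-B domain). Monomer competence is 1.0 for Abd-B and 0.3 for all other
factors: the ordering (Abd-B functions markedly better as a monomer) is the
supported claim; the magnitudes are tunable defaults.

The model's granularity is deliberately coarse: it predicts md activity
wherever Dfd acts (the real pattern starts at mx), treats A9 like A8
(both are Abd-B domain), and does not model the residual abdominal patches
seen in some multiple-mutant genotypes. These are documented limitations,
not targets of the truth-table validation.

# Concordance

`rankConcordance()` computes Kendall's tau (tau-b under ties, via
`stats::cor`) between predicted affinities and measured relative binding
across construct variants — rank-based because gel-band quantification is
at best monotone in affinity. `expressionAgreement()` scores the fraction
of (variant, segment) cells where the predicted ternary call matches an
observed call and attaches the confusion table. No significance test is
attached to tau: with a handful of variants the interesting quantity is the
ordering itself.

# Numerical and validation choices

* Anchoring is checked to $10^{-9}$; additivity is asserted to $10^{-12}$
  in tests; audit "affinity-changed" uses a $10^{-12}$ tolerance.
* All randomness flows through explicit seeds; generators preserve the
  caller's RNG state.
* Validation problem sizes: the scanner oracle runs 100 random sequences
  (up to 200 bp) against 5 random models; knockout certification is
  exercised on sequences up to 60 bp with up to 3 edits; parameter recovery
  uses 500 windows; the rank-stability check uses 200 noise replicates over
  a 64-fold, 7-step affinity ladder. These sizes make the full suite run in
  well under a minute while keeping every certification exhaustive where
  claimed.

# Known limitations

* Models are mononucleotide and additive: no dinucleotide, shape, or
  cooperativity terms, and no model fitting from selection data — models
  are inputs here.
* The expression model is a two-position-per-segment caricature of
  intra-segmental patterning and treats STAT as a scalar.
* Synthetic models and fixtures encode qualitative class structure;
  absolute affinities and real flank preferences are not claimed.
* BED/bedGraph export uses the package's 0-based convention and a
  1000-scaled score; re-import with standard genomics tooling is covered by
  tests, but scores above 1 (possible after reference renormalization) are
  clamped at 1000 in BED output only.
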