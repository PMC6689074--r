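# hoxcrm

Affinity scanning and rational design of Hox-regulated *cis*-regulatory
modules (CRMs).

## The problem

All eight *Drosophila* Hox transcription factors bind nearly the same short
AT-rich DNA as monomers (a 6-bp footprint around a TAAT core; Abd-B prefers
TTAT/TTAG), yet each controls its own target genes in vivo. When a Hox
protein binds together with the Exd/Hth (Pbx/Meis) cofactors, the
recognition site widens to ~12 bp and a latent specificity appears:

* class 1 (Lab, Pb) prefer the core `TGATTGAT`
* class 2 (Dfd, Scr) prefer `TGATTAAT`
* class 3 (Antp, Ubx, Abd-A, Abd-B) prefer `TGATTTAT`

The cores differ only at core position 5, so a **single base substitution
re-addresses a site from one Hox class to another**, and the flanking bases
grade each complex's affinity without changing the class. hoxcrm is an R
package for working quantitatively with this logic. It provides:

* **Energy models** — anchored position-specific free-energy matrices
  (PSAM-style). A window `w` scores
  `aff(w) = exp(-Σ_i ε[i, w_i]) / normMax`, in (0, 1] within one model;
  affinities are never compared across models (each model's normalization
  corresponds to a different, unknown K_d).
* **Site scanning** — both-strand window scoring, ranked site calls with
  class labels, per-position affinity profiles, overlap detection between
  sites; BED6/bedGraph/FASTA I/O.
* **Rational site engineering** — single-base class conversion, exact
  optimal-flank design (valid because the model is additive), minimal-edit
  knockout of Hox input with exhaustive certification on small instances,
  site restoration, and side-effect audits that catch collateral core
  creation (e.g. a class 1 conversion that silently creates an overlapping
  class 3 core).
* **Expression logic** — a segment-level activation model,
  `score = w_hox·Hox + w_stat·STAT − w_wnt·WNT` (floored at 0, quantized
  to off/weak/strong), over the anterior-posterior segment registry, with
  genotype emulation: factor removal, cofactor loss (*hth/exd*), WNT or
  JAK/STAT silencing, ectopic expression.
* **Synthetic fixtures** — a reproducible enhancer-like construct family
  with a 55-bp cassette carrying overlapping class 2 + class 3 cores that
  share exactly one base pair, planted monomer sites, and the seven
  engineered construct variants, all generated by running the design
  operations themselves.
* **Concordance** — Kendall rank agreement between predicted affinity and
  measured relative binding, and ternary-call agreement with observed
  expression.

## Worked example

```r
library(hoxcrm)

suite  <- makeFixtureSuite(seed = 1)      # enhancer-like fixture family
models <- defaultHoxModels()              # per-factor dimer + monomer models
construct <- suite$sequences[["S1p55"]]   # inert fragment + 55-bp cassette

# 1. Where can Dfd-Exd (class 2) bind?
scanSites(construct, models$Dfd$dimer, threshold = 0.05)
#>     model start end strand       window  affinity  type class_label core_offset
#> 1 Dfd-Exd   318 330      + CTGATTAATGAT 0.1111111 dimer      class2           1

# 2. Re-address the site to the trunk class with a single base edit
site <- scanSites(construct, models$Dfd$dimer, threshold = 0.05)[1, ]
plan <- convertClass(construct, site, "class3")
plan
#> EditPlan (convert_class): 1 substitution(s)
#>   324 A>T
cl3 <- applyEditPlan(construct, plan)
scanSites(cl3, models$Ubx$dimer, threshold = 0.05)
#>     model start end strand       window  affinity  type class_label core_offset
#> 1 Ubx-Exd   318 330      + CTGATTTATGAT 0.1111111 dimer      class3           1

# 3. Predict the construct's segmental activity (wild-type genotype)
p <- predictExpression(cl3, models)
subset(p, call != "off")
#>    segment position       hox stat wnt     score call
#> 10      T1  wnt_off 0.1111111    1   0 0.3111111 weak
#> 14      T3  wnt_off 0.2222222    1   0 0.4222222 weak
#> ...                                   (all trunk segments, WNT-off positions)
```

The single core edit moved the construct's output from the head segments
(where the class 2 factors Dfd/Scr act) into the trunk (class 3 factors),
at WNT-off positions only — the patch pattern. The affinity 1/9 reflects
the cassette's deliberately suboptimal flanks; `optimizeFlanks()` lifts the
same site to affinity 1.

Because the cassette's class 2 and class 3 cores overlap by exactly one
base pair, one substitution can destroy both — and the search certifies
minimality exhaustively:

```r
ko <- knockoutSites(suite$sequences[["cassette"]], mode = "core")
ko
#> EditPlan (knockout): 1 substitution(s)
#>   26 T>A
planProvenance(ko)$params$certified
#> [1] TRUE
```

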