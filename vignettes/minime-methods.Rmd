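---
title: "Models of metabolism and gene expression at desk scale: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of metabolism and gene expression at desk scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A conventional genome-scale metabolic model (an "M-model") fixes a biomass
recipe and asks for a flux vector $v$ with $S\,v = 0$ and
$lb \le v \le ub$ that maximises growth. A model of metabolism *and* gene
expression (an "ME model") additionally represents the machinery that makes
the catalysts: transcription, translation, tRNA charging, complex formation
and protein translocation become reactions, and every catalysed flux incurs
a synthesis cost for its catalyst. The price of this realism is that
stoichiometric coefficients become functions of the growth rate $\mu$
(1/h): the faster the cell grows, the more of each machine it must maintain
per unit of flux.

`minime` restricts every $\mu$-dependent coefficient to the linear form
$a + b\mu$, which covers all the coupling conventions used here:

* **enzyme usage** $\mu/k_{\mathrm{eff}}$ per unit catalysed flux, where
  $k_{\mathrm{eff}}$ (1/h) is the effective turnover rate of the complex;
* **polymerase and ribosome usage** $\mu L / r$, i.e. $\mu/k_{\mathrm{eff}}$
  with an effective rate $r/L$ set by the processivity $r$ (nt/h or
  residues/h) and the template length $L$;
* **mRNA usage** $(\mu + k_{\mathrm{deg}})/k_{\mathrm{rate}}$ per
  translation event, combining dilution and first-order decay
  ($k_{\mathrm{deg}}$, 1/h) against a per-transcript translation capacity
  ($k_{\mathrm{rate}}$, events per mRNA per hour). The degraded share
  $k_{\mathrm{deg}}/k_{\mathrm{rate}}$ is emitted as a degraded-mRNA
  species whose processing is coupled to the RNA degradosome, so mRNA
  turnover genuinely costs degradosome capacity;
* **biomass dilution** $f_c\,\mu$ for each biomass component $c$ (protein,
  RNA, other), consumed by a dilution pseudo-reaction whose flux is pinned
  at 1.

Substituting a numeric $\mu$ therefore yields an ordinary linear
feasibility problem, and the maximum growth rate is the largest feasible
$\mu$ — found by bisection, exactly as ME solvers do.

## Solving: minimum-norm feasibility and a presolve

At fixed $\mu$ the solver must (a) decide feasibility reliably and (b)
return a reproducible flux vector. Both are obtained from a single
primitive: the minimum-norm feasible point
$\min \|v\|_2^2$ s.t. $S(\mu)v = b$, $lb \le v \le ub$, a strictly convex
quadratic program solved with the Goldfarb–Idnani active-set method
(`quadprog`). Infeasibility is reported by the solver itself and confirmed
by a structural presolve; feasible solutions are checked against the
steady-state residual (`feas_tol`, default $10^{-9}$) after solving, never
assumed. The min-norm point is unique, which makes every reported flux
vector deterministic — this is the package's "secondary objective" that
stabilises fluxes across platforms.

The presolve iterates a simple fixpoint: a species with no remaining
producer (or consumer) forces all of its sign-capable participants to zero
flux. This prunes the whole expression cascade downstream of a knocked-out
translation reaction *structurally*, which has two benefits. First, a
knockout of (say) a ribosomal protein is detected as infeasible by exact
integer bookkeeping rather than by asking the floating-point solver to
notice a $10^{-10}$-scale coefficient — the well-known reason genome-scale
ME solvers resort to quad precision. Second, it removes the degenerate
block of exactly-zero bounds that active-set QP codes handle poorly.
Structural signs in the presolve are exact (any nonzero coefficient makes
a row live); tolerances appear only in the residual check.

Two search loops sit on top of the feasibility oracle:

* `maximize_growth()` — bisection on $\mu$ over a default bracket
  $[0, 2]$ h$^{-1}$ to a bracket half-width `tol` of $10^{-6}$ h$^{-1}$;
* `grid_search_growth()` — a staged dense grid scan (step shrinking
  20-fold per stage down to `tol`/2) used as an independent cross-check of
  the bisection path in the tests;
* `maximize_flux()` — flux-variability-style maximisation of a single
  reaction, again by bisection on that reaction's bound. This avoids ever
  needing a linear-objective solver and keeps the entire numerical core in
  one well-tested primitive.

Bisection presumes feasibility is monotone in $\mu$; this is asserted
empirically on every fixture rather than proved.

## The mini-cell: what it emulates and how ground truth is built

`generate_minicell()` produces a complete organism specification — about
20 protein-coding genes, 5 explicit amino acids (Ala, Gly, Lys, Trp, Cys;
the rest of the proteome is lumped into them), ~37 core reactions — whose
purpose is to exercise every analysis the package offers with *known
answers built in by construction*, not inferred from the solver:

* **Carbon core.** Glucose enters through a single transporter (`ptsG`),
  is split to a three-carbon precursor (`enzA`), and respired for energy
  (`atpA`, the sole ATP source). Every element of this chain is therefore
  essential by construction. Carbon (the only tracked element) balances
  exactly in every fully annotated reaction.
* **Expression layer.** RNA polymerase, ribosome (protein subunits plus an
  rRNA incorporated as a formation modification), one lumped
  aminoacyl-tRNA synthetase serving all amino acids, and an RNA
  degradosome. All of their genes are essential by construction because
  biomass requires protein, protein requires translation, translation
  requires charged tRNA and mRNA, and mRNA turnover requires the
  degradosome (the degraded share of every translated transcript must be
  processed).
* **Bulk proteome.** The protein fraction of biomass is supplied by a
  dedicated 200-residue bulk-proteome pseudo-gene (`bulkP`), rather than
  by summing enzyme masses. This keeps enzyme expression demand-driven —
  an enzyme is translated exactly as much as its catalytic duty requires —
  so stress-induced expression changes are clean increments instead of
  being buried in a proteome-filling term. Enzyme mass is consequently
  excluded from the biomass constraint; at desk scale it is a small
  fraction of the total and the simplification is documented here.
* **Ethanol-stress motif.** Ethanol diffuses in (uncatalysed transport),
  is oxidised by `adhA`/`aldX` to acetate, and exported by a
  tryptophan-rich exporter (`ywcA`, 8 Trp by default, against a
  deliberately Trp-poor background proteome of ~3%). Forcing ethanol
  influx therefore raises tryptophan synthesis monotonically — through
  demand for the processing enzymes, with no regulatory rules — while the
  decoupled (M-like) variant shows no change at all.
* **Folate motif.** Tryptophan synthesis passes through a chorismate
  analog; a branch (`folE`) converts chorismate to a folate analog.
  Imposing a folate-damage drain raises flux demand on the shared branch
  and hence transcription of the `trpB`–`folE` operon even as tryptophan
  itself does not benefit.
* **Salt motif.** Sodium influx is uncoupled (a leak reaction); export
  costs 2 ATP per ion through a coupled exporter (`natE`). The exported
  pool is tracked as a separate extracellular species so that a forced
  net-uptake exchange and coupled export can coexist at steady state.
  The ATP drain propagates to a global, monotone decrease in amino-acid
  synthesis — the downregulation-without-regulation result.
* **Secretion motif.** With glucose closed and starch open, growth
  requires starch hydrolysis by either the secreted reporter amylase
  (`amyE`, translocated through the Sec pathway with translocase coupling
  and a per-residue energy cost) or a membrane-bound amylase (`amyC`)
  whose mature sequence is pure cysteine (5 residues by default). The
  reporter's mature composition is set *exactly* by configuration
  (default Ala 8, Gly 4, Lys 4, Trp 2, Cys 0).

The last point is what makes the sensitivity analysis self-validating.
At fixed $\mu$, forcing reporter secretion $r$ forces reporter translation
$r$ (amino-acid demand $+c_{aa} r$ for each planted count $c_{aa}$) and
forces hydrolysis capacity $r\,k_{\mathrm{eff}}/\mu$, displacing the
membrane amylase one-for-one in hydrolysis duty and hence *removing*
$c_{\mathrm{Cys}}^{\mathrm{amyC}}$ of cysteine demand per unit secretion.
The slope of each amino acid's synthesis flux against secretion is
therefore the planted count — positive for reporter residues, $-5$ for
cysteine — up to corrections of order $\mu\cdot(\text{synthesis
cost})/k_{\mathrm{eff}} \sim 10^{-3}$, well inside the 10% recovery the
tests demand.

Membrane proteins insert co-translationally (SRP-style, energy cost only);
only genuinely secreted proteins couple the translocase complex. This both
reflects the biology of co-translational insertion and keeps the
translocase out of the constructively essential set, so the essential /
non-essential partition recorded by the generator is exact:

```{r}
library(minime)
spec <- generate_minicell(minicell_config(), seed = 7)
spec$ground_truth$essential_genes
```

## Key parameters

All rates are configuration values with, in the package's judgment,
realistic defaults for a fast-growing bacterium; none is fit to data.

| parameter | default | units | rationale |
|---|---|---|---|
| `glucose_uptake` | 5 | mmol/gDW/h | moderate carbon limitation; puts $\mu^\ast \approx 0.55$ h$^{-1}$ inside the $[0,2]$ bracket |
| `keff_primary` | 36000 | 1/h | 10 s$^{-1}$, a typical central-metabolism turnover |
| `keff_secondary` | 3600 | 1/h | 1 s$^{-1}$ for transporters, amino-acid synthesis and stress enzymes |
| `mrna_degradation_rate` | 8 | 1/h | ~5 min mRNA half-life |
| `translation_rate_per_residue` | 43200 | residues/h | 12 aa/s per ribosome |
| `transcription_rate_per_nt` | 36000 | nt/h | 10 nt/s per polymerase |
| `mrna_translation_capacity` | 40 | events/mRNA/h | ~5 translations per transcript lifetime |
| `biomass_composition` | 0.55 / 0.20 / 0.25 | g/gDW | protein / RNA / other |
| `translation_atp_per_residue` | 2 | mmol/residue | GTP-equivalent polymerisation cost |

The machinery turnover numbers are deliberately on the slow side of the
literature. This is a numerical-integrity choice as much as a biological
one: the growth ceiling that a knocked-out machinery gene can reach
through double-precision equality slack scales like
$\sqrt{\varepsilon\,k_{\mathrm{eff}}}$, and with these defaults it stays
one to two orders of magnitude below the zero-growth threshold
($10^{-5}$ h$^{-1}$, ten times the bisection tolerance), so the
essentiality screen is unambiguous without quad-precision arithmetic.

## Stress conventions

Ethanol is forced by pinning its exchange to the influx rate (diffusion
carries it in; no transporter expression is triggered). Sodium is forced
the same way at its own exchange, with the uncatalysed leak delivering it
to the cytosol and export remaining enzyme-coupled. Expression profiles
(per-gene transcription and translation fluxes) are normalised per gene to
the maximum across a sweep; all-zero series map to zero by convention.
Differential-expression calls use a configurable relative-change threshold
(default 5%; the underlying studies state no threshold), and accuracy is
scored over reference-changed genes, overall, by direction and by
subsystem.

Attribution of an amino acid's synthesis change divides each protein's
$\Delta(\text{translation flux} \times \text{count})$ by the total change
in synthesis flux. Because charging is the amino acid's only sink in the
mini-cell, the fractions sum to one exactly — machinery proteins included
as their own rows, and negative rows (proteins whose expression fell)
permitted. A baseline term can shrink as growth slows under stress, so a
dominant contributor's share may exceed 100% of the *net* increment; the
conservation property is the invariant, not the sign of individual rows.

## Secretion analytics

Batch kinetics follow the standard mass balances
$dX/dt = \mu X$ and $dC/dt = \nu X$: growth is the least-squares slope of
$\ln X$ against time over the exponential window (natural logarithm, so
$\mu$ is in 1/h), and the secretion rate is
$\nu = (C_f - C_0) / \int_{t_0}^{t_f} X\,dt$ with trapezoidal quadrature
on the reported grid. Activity converts to concentration through a
specific-activity range (defaults 153.7–245 U/mg, a typical span for a
bacterial amylase), and to molar units through the molecular weight of the
mature, post-excision sequence.

Near-optimal sampling draws, per sample, a growth rate uniform in
$[0.9\,\mu^\ast, \mu^\ast]$ and exchange bounds uniform within the
envelopes spanned by the optimal and 90%-optimal solutions, retrying
infeasible draws against a budget; overexpression sampling fixes $\mu$ and
forces the secretion flux to uniform draws in a stated range. Defaults
(100 samples, 90% growth fraction) follow the sampling protocol the
analyses are built around. Flux matrices are z-scored per reaction
(constant reactions dropped) before PCA; subsystem loadings are means of
absolute loadings.

Outlier handling: sensitivity distributions are trimmed once at
mean $\pm\,1.96$ SD (the 95% level; the exact procedure is not pinned down
by the protocols this follows and is configurable); the
composition-versus-sensitivity regression flags points by externally
studentised residuals at the 95% critical value and refits without them.

## Problem sizes and determinism

The default mini-cell assembles to ~130 species and ~180 reactions; one
feasibility solve takes ~20 ms, a growth maximisation ~0.5 s, the full
knockout screen a few seconds, and 100-sample overexpression sets a few
seconds each. These sizes were chosen so that every stage of the pipeline,
including its tests, runs in seconds on one CPU.

Generation is byte-deterministic: identical (configuration, seed) pairs
serialise to identical directories, model assembly is a pure function of
the spec (hash-stamped), and all sampling takes explicit seeds while
restoring the caller's RNG state.

## What passing tests do and do not show

The mini-cell is a designed organism: its ground truth is constructed, its
stress responses are planted, and its parameters are chosen for numerical
clarity. Tests passing on it demonstrate that the *machinery* — coupling
assembly, feasibility search, screening, attribution, sampling, estimation
— computes what it claims to compute. They do not validate biological
predictions on a real organism: real reconstructions bring isozyme
ambiguity, incomplete annotation, uncertain $k_{\mathrm{eff}}$ values
spanning orders of magnitude, thermodynamic constraints, and regulation
that a growth-optimal ME model cannot see (the known weakness for storage
compounds and sub-optimal growth states). The essentiality screen also
inherits the structural bias of ME models: every subunit of a fixed
machinery complex is essential in the model even where biology tolerates
its loss.

## Known limitations

* No rRNA modification enzymology, excision machinery or rho-dependent
  termination; protein folding costs are collapsed into complex-formation
  stoichiometry.
* Elemental balance is checked only for reactions whose participants all
  carry formulas; the energy token and biomass components are exempt.
* The decoupled variant is a diagnostic contrast, not a curated M-model.
* The COBRAme-style JSON dialect stores the network only; organism specs
  travel separately as table directories. Constructs outside the dialect
  are rejected loudly (coefficients) or collected as warnings (fields),
  never silently dropped.
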