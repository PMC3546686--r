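---
title: "Modelling translation initiation under sRNA influence"
author: "sRNAtim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling translation initiation under sRNA influence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAtim)
```

## The question the model answers

Trans-acting small RNAs (sRNAs) regulate bacterial gene expression mostly at
the level of translation initiation. Binding-site prediction by
hybridisation energy alone produces long candidate lists with many
non-functional sites, because almost any two sufficiently long RNAs pair
somewhere. `sRNAtim` post-evaluates candidate sites by asking a mechanistic
question: *would a bound sRNA at this site actually change the amount of
translation-initiation complex?* A site only matters if it either competes
with the 30S subunit for the docking site, or changes how accessible the
docking site is.

## Model

Initiation is treated as an equilibrium in the system mRNA (`M`), sRNA
(`S`) and initiation-competent 30S ribosome (`R`).

**Ribosome--mRNA interaction.** The ribosome recognition site (RRS), a
generalisation of the Shine--Dalgarno sequence, is the energetically best
duplex of the anti-RRS (the 3' terminal 10 nt of the 16S rRNA,
`UCACCUCCUU` in *E. coli*) in the window $-30\ldots+3$ around the start
codon. The hybridisation energy $\Delta G_R$ gains a start-codon bonus of
$-1.19$ kcal/mol for AUG and $-0.075$ for GUG. The ribosome docking site
(RDS) is the 30-nt stretch starting at the RRS start.

**Accessibility.** The initiating subunit cannot melt mRNA structure, so
the probability $P_{EF}$ that the *entire* RDS is unpaired is the central
thermodynamic barrier; equivalently the opening energy
$\Delta E_F = -RT\ln P_{EF}$. With an sRNA bound, the same probability is
recomputed with the site's bases barred from intramolecular pairing,
giving $P_{ES}$. Probabilities come from the ratio of constrained
partition functions over all nested secondary structures.

**sRNA--mRNA interaction.** Candidate sites are sub-optimal intermolecular
duplexes whose accessibility-corrected energy
$\Delta G_S = \Delta G_{hybrid} + \Delta E_{open}(\text{mRNA site}) +
\Delta E_{open}(\text{sRNA site})$ passes the standard filters: at most
$-7$ kcal/mol, at least 10 nt on the mRNA (interior bulges included),
fully inside $-150\ldots+20$ relative to the start codon.

**Equilibrium.** Energies become dimensionless constants
$K = e^{-\Delta G/RT}$ and copy numbers per cell are used directly as
activities against them — a deliberate simplification inherited from the
model this package implements; no volume or standard-state conversion is
applied, so all $K$ and concentrations should be interpreted jointly, not
separately. Two topologies arise:

* **Overlap** (site shares $\ge 1$ nt with the RDS): ribosome and sRNA
  binding are mutually exclusive; the active species is `M_R` alone.
  Eliminating the five-equation system produces a cubic in $m_R$.
* **Non-overlap**: the ternary complex `M_SR` exists and is active;
  $m_{TA} = m_R + m_{SR}$ solves a quintic.

Each initiation event removes $n$ ribosomes from the free pool
(occupancy, default 20, from the average loading of a translated
transcript). The readout per site is the signed fold change
$\alpha = m_{TA}(s_T)/m_{TA}(0)$, with the convention
$\alpha = -m_{TA}(0)/m_{TA}(s_T)$ when activity decreases, so
$|\alpha|\ge 1$ and the sign is the direction. Sites with $|\alpha| > 2$
are called putatively regulatory; a gene is flagged when *any* of its
sites passes, because the energetically best site is often not the
effective one.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| site window | $-150\ldots+20$ | search region relative to the start codon (full containment) |
| energy cutoff | $-7$ kcal/mol | max accessibility-corrected $\Delta G_S$ |
| min site length | 10 nt | mRNA span incl. interior unpaired bases |
| RRS window | $-30\ldots+3$ | anti-RRS search region |
| RDS length | 30 nt | footprint of the initiating 30S subunit |
| accessibility flank | 250 nt | folding context on each side of the RDS |
| temperature | 310.15 K | $RT = 0.61633$ kcal/mol |
| $n$ | 20 | ribosomes removed per initiation event |
| `[sRNA]/[mRNA]` | 2/3 | default sRNA copy ratio when unmeasured |
| total 16S | 57,000 | ribosome copies per cell |
| busy fraction | 0.80 | ribosomes engaged in elongation, leaving $r_T = 11{,}400$ |
| $\|\alpha\|$ threshold | 2 | classification boundary (inclusive) |

Copy numbers come from read counts via RPKM, rescaled so that the summed
16S rRNA signal corresponds to 57,000 copies per cell; fractional counts
are accepted so `1/n` multi-mapper weighting applied at mapping time is
representable. Genes with zero expression are skipped ($\alpha$ is
undefined at $m_T=0$).

## Coordinate convention

Relative positions use the biologist convention with no position 0: `+1`
is the first base of the start codon, `-1` the base immediately upstream,
so `(-12)..(+18)` spans exactly 30 nt. Internally, absolute positions are
1-based R indices; the external annotation format carries 0-based start
offsets (`id <TAB> offset`), converted on load.

## The bundled energy model

All thermodynamics run through an exchangeable backend
(`EnergyBackend`). The bundled `NearestNeighborBackend` is a deliberately
simple, fully documented model so that every number it produces can be
re-derived by explicit enumeration:

* stacking energies: a published-style Watson--Crick + GU 6×6 table
  (kcal/mol, 37 °C), symmetric under reading the helix from the other
  strand;
* hairpin loops: $5.4 + 1.08\,\ln(L/3)$, minimum loop 3;
* interior loops/bulges: $3.2 + 1.08\,\ln(s)$ for $s$ total unpaired
  bases, prohibited above $s = 20$;
* multiloops: $3.4 + 0.4\times$(number of branches including the closing
  pair), unpaired bases free;
* duplexes: stacks plus an initiation penalty of $4.1$ and affine
  inter-molecular loop penalties $2.6 + 0.4(g_1+g_2)$, per-strand gaps
  capped at 10;
* no dangling ends, no terminal-AU penalty, no coaxial stacking.

This is not a full Turner-parameter model and is not meant to reproduce
literature energies; it is self-contained and oracle-checkable. The
duplex dynamic program is verified against exhaustive alignment
enumeration, and the constrained McCaskill-type partition function
against explicit enumeration of all secondary structures with
per-structure loop-decomposition scoring (`bruteForceDuplexEnergy()`,
`bruteForceUnpairedProbability()`). Accessibility profiles for site
search use a windowed context (±100 nt around the site) with the pair
span capped at 150 nt, mirroring common local-folding practice; the RDS
exposure uses the full ±250 nt context with no span cap. Partition
functions accumulate in extended precision, which keeps deep opening
energies (tens of kcal/mol, probabilities down to $10^{-40}$ and below)
free of underflow for windows up to ~1000 nt.

Sub-optimal duplex candidates are taken per mRNA end position; two
candidates are the same site when their mRNA spans overlap by more than
50% and they share the sRNA region, keeping the lower-energy one. The
published description of the workflow does not fix a deduplication rule;
this one is our choice and is configurable only in code.

## Numerical choices in the equilibrium solvers

The eliminations to the cubic and the quintic are exact, but solving the
polynomial directly is numerically fragile: binding constants reach
$e^{40/RT}\sim 10^{28}$, and the physical root can sit within machine
epsilon of the box boundary $\min(m_T, r_T/n)$ where species
reconstruction divides by a vanishing free-ribosome concentration.
The production path therefore eliminates onto the *free* species, where
every other species is a cancellation-free closed form: for the overlap
topology a strictly increasing scalar equation in $m_F$ solved by
bisection in log space; for the non-overlap topology a nested pair of
monotone scalar solves in $(m_F, r_F)$. The eliminated polynomial is kept
as a guard: the solution must be one of its roots (in the backward-error
sense) and no other clearly interior root may reconstruct to a physical
species set — the equilibrium of this closed system is unique, so a
second feasible root would indicate a defect. `P_{ES} = P_{EF}` is
detected and reduced analytically to the no-sRNA baseline, which makes
the identity $\alpha = +1$ exact rather than approximate. Convergence is
driven to near machine precision (160 log-space bisection steps);
conservation residuals are checked post hoc at $10^{-9}$ relative to the
totals.

`oracleSolve()` is the independent verification path: a damped Newton
iteration in log-species space on the un-eliminated system, with
physics-informed multistart and, as a last resort, geometric continuation
in the binding constants. It never touches the eliminated polynomials and
agrees with the production solvers to better than $10^{-8}$ relative
across the full working range ($K$ up to $e^{40/RT}$, totals $1..10^5$,
$n$ 1..100).

Well-conditioned domains of the scalar conversions: $K \leftrightarrow
P = K/(1+K)$ inverts to machine precision for $K \lesssim 10^3$ (beyond
that $P$ saturates at 1 in doubles); $\Delta E \leftrightarrow
e^{-\Delta E/RT}$ inverts for $\Delta E \gtrsim 0.01$ kcal/mol and is
exact at 0.

## The synthetic scenarios

`fixtureSet()` builds four deterministic scenarios per seed, each
self-verified at construction by running the real pipeline and
cross-checking the fold change against `oracleSolve()`:

* **repression** — an sRNA perfectly complementary to a 20-nt stretch
  overlapping the RDS; the RDS is kept accessible ($P_{EF}\ge 0.1$), so
  binding sequesters mRNA from the ribosome. With the default 2/3 copy
  ratio the expected $\alpha$ is close to $-3$: the sRNA removes two
  thirds of the target pool. The duplex is long enough that its binding
  constant beats ribosome docking across the whole sensitivity grid.
* **activation** — an inhibitory hairpin whose 5' arm sits near $-95$
  and whose 3' arm covers the RDS; the sRNA pairs with the 5' arm *plus
  8 nt of flank on each side*, so its duplex beats the stem by more than
  the $-7$ kcal/mol filter margin (opening a stem to form an equally
  long duplex gains almost nothing — real activators out-pair the
  inhibitory structure). Blocking the arm raises $P_{ES}$ by many orders
  of magnitude: strong activation through a non-overlapping site.
* **null** — a random sRNA with no complementarity above the filters:
  no sites, no records.
* **upstream_weak** — a strong perfect duplex at $-149\ldots-130$ with
  negligible effect ($\alpha\approx\pm 1$; it neither overlaps nor refolds
  the RDS) next to a weaker site at $+4\ldots+18$ that overlaps the RDS
  and represses. The weak site sits in the transcript-specific coding
  sequence rather than on the shared RRS/AUG block, so each scenario's
  sRNA stays specific to its own transcript. The gene is flagged through
  the *weaker* site, the pattern that motivates evaluating every site
  rather than the energy-best one.

Backgrounds are drawn A-rich and GC-poor (65/8/12/15% A/C/G/U): bacterial
5' UTRs are AU-rich, and a purine-rich docking site in a pyrimidine-poor
background keeps spurious structure over the RDS rare so the repression
scenario's $P_{EF}\ge 0.1$ requirement is met within a few draws.
Transcripts are 220 nt (160 nt 5' leader + 60 nt of coding sequence) with
$m_T = 60$ copies per cell — small enough that the baseline is never
ribosome-limited across occupancies 1..100, which is what makes the
verdicts invariant over the sensitivity grid. Construction retries
derived sub-seeds until all checks pass, so regeneration from the same
seed is bit-identical.

What passing these scenarios does *not* show: performance on real
transcripts with Turner-accurate energies, Hfq-mediated kinetics,
competition among many mRNAs for one sRNA, or co-transcriptional folding
— all outside the model.

## Problem sizes used in validation

The test suite and the acceptance script size their checks to run
comfortably on one CPU: 200 random parameter sets per topology for
solver/oracle agreement, 50 (tests) or 15 (acceptance script) random
sequences of 15–25 nt for partition-function/enumeration agreement, a
3×3 grid over $n\in\{1,20,100\}$ and ratio $\in\{2/3,1,2\}$ for verdict
invariance, and whole-pipeline screens of the four scenarios. These sizes
are the package's validation choices; all of them can be scaled up by
editing one constant in the corresponding test.

## Known limitations

* The bundled energy model is qualitative; absolute energies differ from
  Turner-parameter engines, so published interaction energies are not
  reproduced numerically — only the model's *behaviour* is.
* One site at a time: cumulative effects of simultaneously bound sRNAs
  and titration across the transcriptome are not modelled.
* Equilibrium only: co-transcriptional kinetics, bursting and RNase
  recruitment are out of scope, as is Hfq.
* $\alpha$ is a qualitative classifier, not a quantitative prediction of
  fold change; treat its magnitude with caution.
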