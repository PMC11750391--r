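---
title: "Modelling LC-PUFA biosynthesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling LC-PUFA biosynthesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufapath)
library(dplyr)
```

pufapath models how a marine invertebrate builds its long-chain
polyunsaturated fatty acids (LC-PUFA) from dietary C18 precursors, using the
sea urchin *Hemicentrotus pulcherrimus* enzyme complement as the packaged
reference dataset: 8 S/MUFA-subfamily elongases (Elovl6-like A–H), 5
PUFA-subfamily elongases (Elovl2/5-like, Elovl-like, Elovl1/7-like,
Elovl4-like, Elovl8-like) and 3 front-end desaturases (FadsA, FadsC1,
FadsC2), each functionally characterised by heterologous expression in
yeast. This vignette explains the models behind each module, the tunable
parameters and their defaults, what the simulators do and do not emulate,
and the design decisions taken where more than one reasonable choice
existed.

## The fatty-acid model and its nomenclature algebra

A fatty acid is a chain length $C$ (carbons, carboxyl carbon = C1) plus a
strictly increasing set of double-bond positions $\Delta = \{d_1 < d_2 <
\dots\}$, where $\Delta d$ denotes a C=C between carbons $d$ and $d+1$.
Geometry (cis/trans) is not modelled — every bond is treated as cis, which
is the only configuration relevant to these biosynthetic products. The
structural invariants are $C \ge 2$, $2 \le d \le C-1$, and adjacent
positions differing by at least 2 (cumulated dienes are chemically
excluded; *conjugated* spacing of 2 is structurally allowed and classifies
as non-methylene-interrupted, although no enzyme operator here produces
it).

Two shorthand dialects interconvert:

* **omega** (`20:4n-6`): $x$ counts the terminal double bond from the
  methyl end. It implies methylene interruption, so the positions expand to
  $C - x - 3k$ for $k = 0, \dots, D-1$. Expansion below C2 is a parse
  error.
* **delta** (`20:2^Δ5,11^`): positions listed explicitly. This is the only
  faithful name for non-methylene-interrupted (NMI) structures, so
  `fa_to_omega()` *refuses* NMI inputs rather than inventing a name — the
  omega dialect simply cannot encode their spacing. Both the GREEK CAPITAL
  DELTA and the INCREMENT glyph are accepted on input (they are visually
  identical in most fonts and both occur in the wild); output always uses
  U+0394.

Unsaturation classes: `saturated` (no bonds), `monounsaturated` (one),
`methylene_interrupted` (≥ 2 bonds, every adjacent spacing exactly 3) and
`nmi` (≥ 2 bonds, any spacing ≠ 3). The spacing-3 rule is what makes the
omega dialect well defined, and it is the axis along which the unusual
NMI-FAs of echinoderms (such as 20:2^Δ5,11^ and 20:2^Δ5,13^) depart from
ordinary PUFA.

## Reaction operators and the activity dataset

Two operators generate everything:

* `elongate()` — Elovl condensation adds a C2 unit **at the carboxyl end**,
  so the chain grows by 2 and every delta position shifts by +2; the omega
  class is invariant. This is the only mechanism consistent with every
  substrate/product pair in the packaged panels (e.g. 18:3n-3 = Δ9,12,15 →
  20:3n-3 = Δ11,14,17). The chain cap defaults to 24 because C24 products
  are the longest the reference enzymes make.
* `desaturate(x, d)` — front-end desaturation inserts one bond at a named
  position (here Δ5, Δ6 or Δ8 depending on the enzyme), rejecting
  duplicates and cumulated placements.

The packaged activity table (`load_activity_panels()`) transcribes the
measured conversions of all 16 enzymes. Three statuses are distinguished
deliberately: `quantified` (a percentage), `not_detected` (below the
detection limit — *not* a measured zero, so it is stored as `NA` with a
flag rather than `0`), and `qualitative` (activities documented on
chromatograms whose percentages are only in supplementary material: the
Elovl6-like C elongation cascade on the yeast endogenous MUFA 16:1n-7 and
18:1n-9, and the FadsA Δ5 product 18:1n-13 from 18:0). Every row is
machine-validated on load: the product must equal the operator applied to
the substrate, which catches transcription errors in the fixture and in any
user-supplied panel CSV.

## The pathway graph

`build_pathway()` closes a precursor set under all panel records that
qualify as edges. A record qualifies when its conversion is at least the
threshold, or when it is qualitative. Two parameters matter:

* **threshold, default 5%.** The reference study treats sub-5% conversions
  as "overall low" and treats FadsC2's 0.5%/0.1% Δ6 activities as absence
  of a Δ6 desaturase. Five percent cleanly separates every
  claimed-functional activity from every claimed-absent one in the panels;
  raising it can only remove edges (monotonicity is property-tested).
* **precursors, default `{16:1n-7, 18:1n-9, 18:2n-6, 18:3n-3}`.** The two
  yeast endogenous MUFA plus the two dietary C18 PUFA. 18:3n-6 and 18:4n-3
  are *reachable products*, not assumptions; 18:0 can be added to obtain
  the 18:1n-13 branch.

Because both operators strictly increase the pair (chain length, bond
count), the graph is a DAG; this is asserted via a topological-sort check
on every build. With the default settings the graph reproduces the
published biosynthetic map: ARA (20:4n-6) and EPA (20:5n-3) are reached
from 18:2n-6 and 18:3n-3 exclusively through the "Δ8 pathway" (elongation
→ Δ8 → Δ5 — there is no Δ6 edge above threshold, so the vertebrate "Δ6
pathway" cannot operate), exactly four C20 NMI-FAs are produced
(20:2^Δ5,11^, 20:2^Δ5,13^, 20:3^Δ5,11,14^, 20:4^Δ5,11,14,17^), all six C20
methylene-interrupted PUFA are reachable, and DHA (22:6n-3) is unreachable:
24:5n-3 exists (Elovl1/7-like) but no enzyme desaturates it at Δ6, so the
Sprecher route is closed at that step and no β-oxidation operator is
needed.

Route enumeration (`routes_to()`) is an exhaustive simple-path search —
the graph has ~20 nodes, so DFS cost is irrelevant — with deterministic
ordering: fewest steps first, then lexicographic enzyme names.

## The conversion statistic

For one fed substrate in one culture,
$$\mathrm{conversion} = 100 \times
  \frac{\sum \text{product areas}}
       {\text{substrate area} + \sum \text{product areas}}.$$
Areas are unitless FID responses; no response-factor correction is applied
because none is applied in the reference workflow. Peak identification
(retention-time matching) is upstream of this package: the input is an
already-identified area table. Two numerical decisions: an all-zero
denominator is an explicit error (a failed assay must not read as 0%
conversion), and *iterated* elongation products all count in the numerator
(`multi_step_products()` chases the cascade, e.g. 16:1n-7 → 18:1n-7 →
20:1n-7), because the elongases act processively in the yeast assay. No
minimum-area threshold is applied to the sums — none is stated for the
reference data — so trace intermediate peaks count as products.

## DMOX fragment series and double-bond inference

Electron-ionization spectra of 4,4-dimethyloxazoline (DMOX) derivatives
show a fragment series retaining 2, 3, ..., $C-1$ acyl carbons. The model
is unit-mass and intensity-free (peak presence only), because unit-mass
positions are what carry the structural information. Anchors are
$m/z(2) = 113$ and $m/z(3) = 126$; each later fragment adds +14, or +12
across a carbon that starts a double bond. A 12-a.m.u. gap between the
$n{-}1$- and $n$-carbon fragments therefore localises $\Delta n$; the
molecular ion is the last member +15. These anchors are the unique integer
solution consistent with the four landmark fragments of the dienoic
NMI-FAs (222/234 for 20:2^Δ5,11^, 250/262 for 20:2^Δ5,13^), and they give
the exact unit mass of the palmitic-acid derivative's molecular ion
(C20H39NO, $m/z$ 309). Δ5 is special-cased: it is read from the m/z 153
diagnostic ion rather than from the low-mass gap region, which is
unreliable in practice below about six carbons; the rule table ships with
this single entry and is extensible as further diagnostics are
established.

Inference inverts prediction by enumeration: every candidate position set
in the detectable window $[4, C-2]$ with up to 6 bonds and spacing ≥ 2
(a few thousand candidates for $C = 22$) is scored by the fraction of its
predicted peaks — series, diagnostics, molecular ion — present in the
observed spectrum at exact unit mass. Ties break toward fewer bonds, then
the lexicographically smallest set, so a saturated reading is always
preferred when the data do not demand a bond. A best score below the
`floor` (default 0.5, i.e. less than half the predicted evidence present)
is reported as an uninterpretable spectrum rather than a guess. Structures
with bonds outside the detectable window are out of model by declaration,
not silently mis-assigned.

## Motif screening

The subfamily motifs are applied as PROSITE-like patterns: `H-[WT]-X-H-H`
for S/MUFA Elovl, `[QH]-X-[TS]-X-L-H-X-X-H-H` for PUFA Elovl, and the
three desaturase histidine boxes `H-X-X-X-H`, `H-X-X-H-H`, `Q-X-X-H-H`,
which must occur in N→C order (first occurrences compared; no spacing
constraint, since none is established). Three decisions worth stating:
a sequence matching both Elovl motifs is labelled `pufa_elovl` — the
longer pattern is the more specific claim — with an `ambiguous` flag
rather than a silent tie-break; an unknown residue `X` in the *input*
matches only wildcard pattern positions (the conservative reading:
an unknown residue is not evidence for a histidine); and no positional or
transmembrane-context restriction is imposed on where a motif may sit.
Scanning uses a lookahead regex so overlapping hits are all reported, and
is property-tested against a brute-force window oracle.

## What the simulators emulate — and what they do not

The `sim_*()` generators produce inputs with exactly the statistical
structure each stage assumes, so the whole pipeline is testable offline:

* `sim_protein()` / `sim_protein_panel()`: uniform-random 20-letter
  background with concrete motif instances embedded at random positions,
  rejection-sampled until the classifier returns exactly the requested
  label unambiguously. By construction, generator and classifier agree —
  which is the point: these panels test the machinery, not homology. Real
  enzyme sequences have composition bias, transmembrane architecture and
  family-wide similarity that uniform backgrounds do not emulate, so
  passing on synthetic panels does not demonstrate classification accuracy
  on diverged natural sequences. All synthetic ids are prefixed
  `synthetic_`.
* `sim_peak_table()`: the substrate receives $(100-p)$ area units and the
  products split $p$, each multiplied by independent log-normal noise of
  the requested CV (areas are positive; detector noise is multiplicative —
  the reference data state no noise model, so log-normal is our choice).
  The expected product share equals $p$, and the ratio estimator is
  unbiased within Monte-Carlo error at realistic CVs (property-tested at
  CV = 0.1 over 150–200 replicates). Endogenous background FAMEs (16:0,
  16:1n-7, 18:0, 18:1n-9) are added as in real yeast chromatograms.
  Retention times, co-elution and baseline artefacts are not simulated.
* `sim_dmox_spectrum()`: predicted peaks with decreasing intensities,
  seeded dropout and uniform noise peaks. The diagnostic region — the
  molecular ion, diagnostic ions, and both flanks of every 12-gap — is
  protected from dropout, so the simulator never erases the structural
  evidence itself; noise peaks keep ≥ 2 m/z away from true peaks so ground
  truth stays unambiguous at unit resolution. Recovery is ≥ 95% at the
  default 10 noise peaks / 10% dropout (seeded property test). Real
  spectra additionally contain fragment-intensity structure and isotope
  peaks that the unit-mass, presence-only model ignores.

Every generator takes an integer seed, restores the caller's RNG state,
and is bit-reproducible (golden-tested).

## Problem sizes used by the test suite

The property suites run at sizes chosen to exercise the full modelled
space while remaining desk-scale: the omega-expansion oracle enumerates
*all* methylene-interrupted structures up to C24/D6 (exhaustive, a few
hundred cases); nomenclature and operator properties use 100–200 random
structures; DMOX inversion checks all published exemplars exactly plus
seeded random samples of 30–60 structures across $C \le 22$, $D \le 4$
(the candidate enumeration makes full exhaustion over every structure
unnecessary — each inversion already scores every candidate set for its
chain length); noisy-recovery rates use 30–60 seeded spectra.

## Known limitations

* The activity dataset is a transcription of published summary tables;
  replicate-level variance is not available, so the pathway threshold acts
  on point estimates.
* Qualitative activities participate in pathway building without a
  percentage; if supplementary quantitation becomes available, replacing
  the `qual` sentinels in the fixture upgrades them transparently.
* The DMOX rule table carries only the Δ5/153 diagnostic; Δ4 diagnostics
  (relevant to vertebrate-style pathways, absent here) would need new rule
  rows and validation spectra.
* Classifying the deposited GenBank accessions requires downloading them;
  `read_proteins()` accepts any such FASTA directly, and the packaged
  synthetic panels exist precisely so the screen is exercised without
  network access.
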