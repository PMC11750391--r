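# pufapath

Sea urchins accumulate arachidonic acid (ARA, 20:4n-6), eicosapentaenoic
acid (EPA, 20:5n-3) and a family of unusual **non-methylene-interrupted
fatty acids** (NMI-FAs, e.g. 20:2^Δ5,11^) even on diets that barely contain
them. pufapath is an R package for working out *how*: it models long-chain
polyunsaturated fatty acid (LC-PUFA) biosynthesis from the measured
substrate specificities of the enzymes involved — elongases (Elovl) and
front-end desaturases (Fads) characterised by heterologous expression in
yeast — with the *Hemicentrotus pulcherrimus* enzyme complement (8 S/MUFA
Elovl, 5 PUFA Elovl, 3 Fads) shipped as the reference dataset.

It is aimed at lipid biochemists and comparative physiologists who need to
turn enzyme assay tables into pathway statements, and at analysts
interpreting GC-FID/GC-MS data from such assays.

## What it computes

* **Nomenclature algebra** — parsing and interconversion of the two
  fatty-acid shorthand dialects: omega (`20:4n-6`, positions
  `C − x − 3k`) and delta (`20:2^Δ5,11^`); classification into
  saturated / monounsaturated / methylene-interrupted / NMI. NMI
  structures have no omega name and are refused, not guessed.
* **Reaction operators** — elongation (+C2 at the carboxyl end; Δ
  positions shift +2) and front-end desaturation (insert Δd), with the
  packaged, machine-validated enzyme activity panels.
* **Pathway graphs** — closure of precursor sets under all activities
  above a conversion threshold (default 5%), route enumeration, DOT/CSV
  export. Reproduces the reference biosynthesis map: ARA and EPA arise via
  the **Δ8 pathway** (elongation → Δ8 → Δ5; no functional Δ6), exactly
  four C20 NMI-FAs are produced, and DHA is unreachable (no Δ6 activity on
  24:5n-3, closing the Sprecher route).
* **GC conversion statistic** —
  `100 × Σ product areas / (substrate area + Σ product areas)`,
  with iterated elongation products counted in the numerator.
* **DMOX mass spectrometry** — prediction of the
  4,4-dimethyloxazoline-derivative EI fragment series (+14 per carbon, +12
  across a double bond, anchors 113/126; Δ5 diagnostic ion at m/z 153) and
  inference of double-bond positions from observed spectra by exhaustive
  candidate scoring.
* **Motif screening** — Elovl subfamily classification
  (`H-[WT]-X-H-H` vs `[QH]-X-[TS]-X-L-H-X-X-H-H`) and the
  three-histidine-box Fads screen, with FASTA I/O.
* **Seeded simulators** for every input type (motif-bearing proteins, peak
  tables with known true conversion, noisy DMOX spectra), so the whole
  pipeline is testable offline.

## Worked example

```r
library(pufapath)

g <- build_pathway()   # packaged panels, default precursors, threshold 5%
g
#> <fa_pathway> 21 nodes, 17 edges (threshold 5%, precursors: 16:1n-7, 18:1n-9, 18:2n-6, 18:3n-3)

reachable_products(g, chain = 20, class = "nmi")$id
#> [1] "20:2^Δ5,11^"       "20:3^Δ5,11,14^"    "20:4^Δ5,11,14,17^" "20:2^Δ5,13^"
```

Four C20 NMI-FAs — the dienoic pair made by Δ5-desaturating elongated
MUFA, and the trienoic/tetraenoic pair made by Δ5-desaturating 20:2n-6 and
20:3n-3. The route to EPA shows the Δ8 pathway with each step's measured
conversion:

```r
routes_to(g, "20:5n-3")[, c("substrate", "product", "enzyme", "activity_label", "conversion")]
#>   substrate         product             enzyme        activity_label conversion
#> 1 18:3^Δ9,12,15^    20:3^Δ11,14,17^     Elovl6-like C  C18->C20            58.5
#> 2 20:3^Δ11,14,17^   20:4^Δ8,11,14,17^   FadsC2         Δ8                  11.7
#> 3 20:4^Δ8,11,14,17^ 20:5^Δ5,8,11,14,17^ FadsA          Δ5                  34.7
```

Structure determination from a DMOX spectrum: the fragment series of
20:2^Δ5,13^ steps by 14 except across the Δ13 bond (250 → 262, a
12-a.m.u. gap), and Δ5 announces itself at m/z 153:

```r
s <- predict_dmox("20:2^Δ5,13^")
s[s$n_carbons %in% c(12, 13), ]
#>   n_carbons    mz
#> 1        12   250
#> 2        13   262
diagnostic_ions("20:2^Δ5,13^")
#>   position    mz
#> 1        5   153

sp <- sim_dmox_spectrum("20:2^Δ5,13^", n_noise_peaks = 10, dropout_rate = 0.1, seed = 7)
infer_double_bonds(sp, 20)
#> <dmox_inference> 20:2^Δ5,13^  score 0.900 (chain 20)
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "fapath", package = "pufapath")` with subcommands
`convert`, `classify`, `screen`, `gcquant`, `pathway`, `dmox`, `simulate`
and `reproduce-map`.

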