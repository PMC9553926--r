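---
title: "Mapping C-to-Ψ tRNA editing by mass spectrometry: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping C-to-Psi tRNA editing by mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudomap)
```

## The measurement problem

Pseudouridine (Ψ) is a C-glycoside isomer of uridine: same elemental
formula, same mass. A cytidine that has been edited to Ψ therefore cannot
be distinguished from one edited only to U by mass alone, and neither U
nor Ψ can be distinguished from a genomically encoded U by sequencing
(both template a T in the cDNA). The readout chain this package models
resolves the ambiguity with chemistry:

1. **Oligo protection** trims the tRNA to a window (positions 10–46 by
   default) so the fragment of interest dominates the spectrum.
2. **Cyanoethylation** (acrylonitrile) attaches a cyanoethyl group
   (C3H3N, +53.0266 Da) specifically to Ψ, converting the mass-silent
   isomerization into a diagnostic mass shift.
3. **RNase A digestion** releases short 3′-phosphate fragments; the
   tetramer ending at the editable C (AGACp in the tRNA-Tyr-like
   substrate) carries the full information: unedited C at m/z 1325.197
   ([M−H]⁻), deaminated U at +0.98402 Da, cyanoethylated Ψ at
   +0.98402 + 53.0266 Da.
4. **¹⁸O tracing**: deamination takes its new base oxygen from water, so
   running the reaction in heavy water marks the product +2.00425 Da.
   This distinguishes enzymatically installed U/Ψ from pre-existing
   uridines at the nucleoside level (the U+2 channel).
5. **Nucleoside MRM** quantifies modified nucleosides after complete
   digestion, normalized to m⁵U (one copy per tRNA, untouched by the
   editing chemistry).

Two orthogonal readouts round out the toolkit: the edited fraction from
sequencing-trace peak heights, `T / (T + C)`, and the dual-luciferase
Rt/Rs statistic for codon decoding efficiency.

## Mass bookkeeping

Residues are internal-chain units (nucleoside monophosphate minus water);
a chain of n residues plus one water is the neutral 5′-OH /
3′-linear-phosphate oligonucleotide. Terminal variants adjust from there
(5′-p: +HPO3; 3′-OH: −HPO3; 2′,3′-cyclic phosphate: −H2O). The default
3′ chemistry is the linear phosphate because the observed MALDI values of
the diagnostic tetramers match the linear-phosphate masses; the cyclic
intermediate is available as an option. The default ion is singly
deprotonated [M−H]⁻ on the monoisotopic scale — the only convention
consistent with the observed 1325.1 / 1344 / 1379.1 values.

¹⁸O is a first-class element symbol in formulas (written `[18O]`), not a
mass correction, so labeled and unlabeled species coexist in one species
table. The label is placed on the deamination-installed base oxygen (O4),
which is why nucleoside product ions retain it: the default MRM product
rule is neutral loss of the ribose (C5H8O4, 132.0423 Da), which leaves
the base — and its heavy oxygen — intact. Ψ is the exception: its C–C
glycosidic bond does not break, so its product-ion rule is overridden in
the modification table (double water loss).

```{r}
mz_fragment(c("A", "G", "A", "C"))                 # AGACp
mz_fragment(c("A", "G", "A", "Y"), ce_count = 1)   # AGA-Psi-p + CE
mrm_transitions(c("U", "m5U"))
```

## Digestion model

RNase A cleaves 3′ of pyrimidine-derived residues (C, U, Ψ, D, m⁵U);
RNase T1 cleaves 3′ of guanosine. Queuosine, though guanosine-derived, is
non-cleavable by default, and 2′-O-methylated residues block cleavage at
their position. Digestion is modeled as complete (the readout assumes
limit digests); partial digestion is expressed only through
`missed_cleavages`, which adds longer variants without removing the limit
products. Whether RNase A cleaves 3′ of Ψ and D at full efficiency is not
a settled point; the observed release of the GAGDp and AGACp tetramers
implies cleavage after D16 and C32, which the defaults encode.

## The species ensemble

One editing condition is summarized by three probabilities: the edited
fraction `f`, the cyanoethylation efficiency `ce`, and the ¹⁸O water
fraction `w`. The species mixture follows from independence: the unedited
residue keeps weight `1 − f`; edited molecules split across the ¹⁸O
channel with probability `w` and (for Ψ) the CE channel with probability
`ce`. A Ψ that escaped cyanoethylation is mass-identical to U, so the
assignment table reports the +0.984-no-CE species as U — which is also
why `ce` defaults to 1: the labeling reaction is treated as complete,
consistent with the near-complete conversion the readout shows in
practice, and a documented assumption rather than a measured value.
Enzymes that deaminate but cannot isomerize are represented simply as
`edit_state = "U"` — no special code path.

Editing-state inference mirrors the chemistry: a CE-shifted species
demonstrates Ψ; a +0.984 species without the CE shift, after CE
treatment, demonstrates U; only the unedited species means C. The edited
fraction is the intensity ratio of edited to total diagnostic species,
which assumes equal desorption/ionization efficiency across species —
reasonable for isomers and small adducts of one tetramer, but an
assumption the instrument does not enforce.

## Peak matching

Matching is greedy nearest-mass within a tolerance (default 0.3 Da,
linear-MALDI scale; ties broken by intensity), with each peak assigned to
at most one species and vice versa. The C and U species sit 0.984 Da
apart, so the default tolerance resolves them as long as mass error stays
well under half that spacing; the synthetic generator's 0.1 Da error
s.d. represents that regime.

## What the synthetic generator does and does not emulate

`make_trna_like()` produces an 85-nt substrate with the anticodon-arm
modification set (D16, editable C32, Q34, ms²io⁶A37, m⁵U54), the
structural anchors that make the diagnostic digest work (a pyrimidine
before each diagnostic tetramer, U33, the Tyr anticodon, a 3′-CCA end),
and otherwise random residues. Random positions inside the protection
window are re-drawn until no non-diagnostic fragment falls within 2 Da of
a diagnostic species m/z — emulating the clean spectral neighbourhood the
real substrate happens to have. The generator does **not** reproduce the
actual tRNA-Tyr primary sequence (it is emulated, not copied), nor
secondary structure, hybridization thermodynamics of the protection
oligos, MALDI matrix effects, chromatographic retention, or ¹⁸O
back-exchange. Passing closed-loop tests therefore demonstrates the
correctness of the computational chain under its stated noise model, not
the behaviour of any particular instrument.

Noise is Gaussian on m/z (s.d. 0.1 Da, typical of linear-mode MALDI-TOF)
and multiplicative Gaussian on intensity (CV 5%, floored at zero).
A single root seed fans out to per-generator streams, so adding a
generator never perturbs existing outputs, and identical seeds give
identical outputs everywhere.

```{r}
cfg <- sim_config(seed = 1, f = 0.5, ce = 1, w = 0.5)
make_trna_like(cfg)
head(simulate_maldi(cfg))
```

## Numerical and design choices

* **Coordinates** are 1-based, inclusive, linear. The field's Sprinzl
  numbering is deliberately not implemented: every positional statement
  the pipeline consumes is a linear index at desk scale.
* **Unknown codes are errors**, never silently skipped; the modification
  vocabulary is a versioned TSV keyed by short codes with MODOMICS-style
  names.
* **Degenerate inputs**: an ensemble parameter at 0 or 1 collapses its
  branch exactly (no near-zero species rows); zero diagnostic intensity
  is an error rather than a 0/0 fraction; an all-purine sequence digests
  to a single fragment.
* **Ties** in peak matching break by smaller absolute error, then higher
  intensity; assignments are exclusive both ways.
* **Rt/Rs** is implemented literally as stated for the assay: Rt is the
  mean firefly/renilla ratio of in-frame (frame-0) reporter replicates,
  Rs of +1-frameshift replicates, and scores are normalized per codon to
  the WT mean (so WT ≡ 1 by construction). The frame-to-symbol mapping
  reads unusually but is taken at face value and documented rather than
  second-guessed. Group inference (ANOVA/Tukey) is out of scope; the
  module emits scores for any external test.
* **Problem sizes**: the property suites use 1,000 random sequences for
  the digestion oracle and 9 × 200 replicates for fraction-estimator
  recovery — large enough for stable means, small enough to run
  comfortably on one CPU.
* The parameter-recovery suite runs with `w = 0` (no heavy water), the
  condition of the partial-conversion titrations it emulates; the ¹⁸O
  default of 0.5 applies to the labeling experiments.

## Known limitations

* Fraction estimates inherit the equal-ionization assumption; real
  desorption efficiencies differ slightly between CE-shifted and
  unshifted species.
* No raw-spectrum processing: inputs are peak lists, and isotopic
  envelopes beyond the explicit ¹⁸O channel are not deconvolved.
* MRM transition values are first-principles (protonated nucleoside,
  ribose loss) rather than instrument-tuned; per-modification overrides
  live in the modification table for exactly that reason.
* The digestion model is kinetic-free; enzymes either cleave a site or
  do not.
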