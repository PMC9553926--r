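# pseudomap

Detection and quantification of **C-to-Ψ tRNA editing** by mass
spectrometry, as a tested, reusable R pipeline. The package is aimed at
RNA-modification labs that read out editing states with the classic
cyanoethylation / MALDI-TOF workflow and nucleoside LC-MS/MS, and at
anyone who needs in-silico RNase digests of modified RNA with correct
terminal-phosphate chemistry.

## The science in brief

Pseudouridine (Ψ) is a mass-silent isomer of uridine, so a cytidine edited
to Ψ (a two-step C→U→Ψ conversion at position 32 of bacterial tRNA-Tyr)
cannot be called from mass or sequence alone. The pipeline models the
chemistry that makes it visible:

* **Cyanoethylation** adds C3H3N (+53.0266 Da) specifically to Ψ.
* **Oligo protection + RNase A** digestion releases the diagnostic
  tetramer covering the edit site, with 5′-OH / 3′-phosphate chemistry.
  Singly deprotonated monoisotopic masses of the three key species:

  | fragment | species | theoretical m/z [M−H]⁻ |
  |---|---|---|
  | AGACp | unedited C32 | 1325.197 |
  | AGAΨp + CE | edited, cyanoethylated | 1379.208 |
  | GAGDp | positions 13–16 (D16 control) | 1344.192 |

* **¹⁸O tracing**: deamination draws its oxygen from water, so reactions
  in heavy water mark the product +2.00425 Da (the U+2 / Ψ+2 channels).
* **Nucleoside MRM** transitions (protonated nucleoside → base after
  ribose loss, with per-modification overrides) quantify modification
  levels normalized to m⁵U.
* The edited fraction is estimated from relative species intensities;
  sequencing-trace `T/(T+C)` ratios and the dual-luciferase **Rt/Rs**
  decoding statistic provide orthogonal readouts.

Seeded generators simulate every input the pipeline consumes from an
85-nt tRNA-Tyr-like substrate carrying D16, C32, Q34, ms²io⁶A37 and m⁵U54.

## Worked example

```r
library(pseudomap)

# Simulate a half-edited substrate read out with full cyanoethylation
cfg <- sim_config(seed = 1, f = 0.5, ce = 1, w = 0.5)
peaks <- simulate_maldi(cfg)

# Protect positions 10..46, digest, enumerate species, match, call
substrate <- make_trna_like(cfg)
protected <- protect_window(substrate, 10, 46)
theo <- diagnostic_species(protected, 32)
theo[, c("species", "mz")]
#>   species       mz
#> 1       C 1325.197
#> 2       U 1326.181
#> 3     U+2 1328.185
#> 4    Y+CE 1379.208
#> 5  Y+CE+2 1381.212

call <- infer_editing_state(match_peaks(theo, peaks, 0.3), 32)
call
#> <editing_call> position 32: Ψ (pseudouridine), edited fraction 0.500
```

The species table is the theoretical spectrum of the diagnostic tetramer:
unedited C, the +0.984 deamination product (U), its heavy-oxygen
isotopologue, and the cyanoethylated Ψ in both oxygen channels. The call
reports Ψ because CE-shifted species were observed, with the edited
fraction estimated from relative intensities (0.500 here, matching the
simulated `f`).

The same chain is scriptable from a shell:

```sh
Rscript inst/scripts/pseudomap.R simulate --seed 1 --f 0.5 --out-dir sim/
Rscript inst/scripts/pseudomap.R maldi --seq sim/seq.fasta \
    --mods sim/mods.tsv --peaks sim/peaks.tsv --out-dir out/
```

## Package layout

* `R/formula.R`, `R/modifications.R` — element masses, formula algebra,
  the modification vocabulary (shipped as `inst/extdata/modifications.tsv`)
* `R/sequence.R`, `R/digestion.R` — modified-sequence model, oligo
  protection, RNase A / T1 digestion
* `R/chemistry.R`, `R/maldi.R` — editing states, cyanoethylation, ¹⁸O
  labeling, species enumeration, peak matching, state inference
* `R/mrm.R`, `R/reporter.R` — nucleoside inventory, dynamic-MRM
  transitions, m⁵U-normalized quantification, trace and Rt/Rs statistics
* `R/simulate.R`, `R/pipeline.R` — seeded generators and orchestration
* `vignettes/pseudouridine-mapping.Rmd` — models, assumptions, design
  choices, and limitations
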