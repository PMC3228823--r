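---
title: "Enrichment calling for RIP-chip experiments: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment calling for RIP-chip experiments: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripchip)
```

## The experiment and the statistical problem

A RIP-chip experiment immunoprecipitates an epitope-tagged bait protein from
a cell extract and asks which mRNAs came down with it. The co-purified RNA is
labelled and hybridised on a two-channel microarray against total RNA from
the same extract, so every spot yields an IP intensity and a reference
intensity. Most of the IP channel is unspecific carryover — a roughly
constant fraction of each transcript's abundance — so the signature of a
genuine protein–mRNA association is a spot ratio that stands out from the
bulk of the distribution, not a large absolute intensity.

The package implements the complete analysis from quantified spot tables to
called target sets:

1. **Spot QC** — keep a spot when enough of its foreground pixels exceed the
   local background (median + 2 SD): at least 55% in the IP channel *and*
   90% in the reference, *or* 90% in the IP channel alone, on PCR-spotted
   arrays; 70% / 98% / 98% on oligonucleotide (Agilent) arrays. Comparisons
   are inclusive, and scanner-flagged spots are dropped first.
2. **Enrichment ratios** — per gene, `R = median(log10(IP / reference))`
   over surviving probes of coding sequences. Spots with a nonpositive
   signal are excluded, never clamped.
3. **Scores** — `z = (R - mean) / sd` (mean 0, SD 1; the plotting scale) and
   `s = (R - median) / sd` (SD above the *median* enrichment of all mRNAs;
   the selection scale). Both use the sample SD about the mean, so the two
   scales differ by one constant per profile.
4. **Calling** — a gene is enriched in one replicate when `s >= tau`
   (default `tau = 2`), and called only when enriched in *every* independent
   biological replicate; known unspecific contaminants are subtracted.
   Under a normal background with per-replicate false-positive fraction
   `p ~ 0.05`, the intersection leaves `p^k`: 2.5e-3 for two replicates
   down to 6.25e-6 for four.
5. **Classification** — a bait is `empty` (no mRNA), `bait_only` (its own
   transcript, pulled down via the nascent chain), or `targets` (non-cognate
   mRNAs).
6. **Perturbations** — the same scoring applied to −ATG (start-codon
   mutant), puromycin and EDTA experiments, with the cell codes `P`
   (present in the IP, but too few mRNAs survive QC to form the background)
   and `ND` (not detectable in the IP), and unanimous lost / retained /
   inconclusive verdicts per condition pair.

## Choices the interfaces leave open

**One- vs two-sided tails.** The printed per-replicate false-positive rate
of ~0.05 corresponds to a two-sided normal tail at 2 SD (0.0455), while the
selection rule is one-sided ("above the median", tail ≈ 0.023). We implement
the rule exactly as stated — one-sided and inclusive — and keep `p = 0.05`
as the default *stated* constant in `expected_false_positive_fraction()`,
so the classical `p^k` arithmetic is reproduced while the empirical tail the
simulator realises (~0.022–0.024) is reported by the calibration checks.
`call_enriched()` selects on `s` (the median-centred scale), matching the
wording of the selection rule; `z` is emitted alongside for plotting.

**Dye swaps.** Half of the hybridisations in a typical design have the
fluorophores exchanged. The scan dialect stores physical channels; the
orientation is declared in metadata, never guessed from the file, and
`read_spot_table()` exchanges both the signal and the pixel-fraction columns
exactly once, so the channel-specific QC thresholds always apply to the
correct sample. `gene_log_ratios(dye_swapped = TRUE)` additionally supports
plain ratio inversion for callers working on unresolved spots.

**Detectability and the P/ND codes.** The sources define neither code
numerically. We operationalise "not detectable in the immunoprecipitate" as
*no* spot of the gene reaching the stand-alone IP threshold (90% / 98% —
the same quantity the QC rescue clause uses), and "background not
computable" as fewer than `min_background = 200` genes surviving QC. Both
cutoffs are configuration, and the detectability definition is a
reconstruction, flagged as such here.

**Numeric conventions.** Median of an even count = mean of the middle two.
Box-plot quartiles use linear interpolation between order statistics
(`quantile()` type 7); whiskers are the most extreme data values within
1.5 × IQR of the quartiles and outliers are reported individually. Profiles
with `sd(R) = 0` raise a classed error (`ripchip_degenerate_profile`);
undersized backgrounds raise `ripchip_background_too_small`, which
`score_or_code()` converts into `P`. `standardize_profile()` itself is
permissive (`min_background = 0`) so that small worked examples standardize;
the pipeline layer applies the 200-gene default.

**Blacklist derivation.** The contaminant list is described in the sources
only as "compiled". `derive_contaminant_blacklist()` reconstructs it with
two explicit knobs: a gene is blacklisted when called for at least half
(`min_fraction = 0.5`) of the baits unrelated to it, over a panel of at
least `min_baits = 4` baits, with each bait's cognate mRNA exempt from its
own experiments.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates spot-level two-channel data with known
ground truth so every stage is testable offline:

* a fixed array design (default 5,000 genes — the order of the fission-yeast
  coding set — with 2–5 independent probes per gene, drawn once from a
  dedicated design seed, like a physical array print run);
* log-normal per-gene abundances (log10 mean 2.0, SD 0.6) shared by both
  channels; the IP channel carries a 1% carryover of each transcript plus
  the spiked enrichments;
* per-spot, per-channel multiplicative log-normal noise (log10 SD 0.1);
* a logistic pixel-quality link from the spot's log10 signal *level* to the
  fraction of above-background pixels (midpoint −1.5, slope 4 in log10
  units): detectability is treated as a property of how much material sits
  on a spot, consistent across replicates, rather than of the multiplicative
  noise on the quantified intensity. This keeps detection-limit selection
  from feeding back into the measured ratios, so null genes enter a
  k-replicate consensus at the expected (per-replicate tail)^k rate;
* 1% scanner-flagged spots, a dye swap on the last replicate, and the
  condition semantics: −ATG removes exactly the designated mRNA's
  enrichment while leaving its reference abundance unchanged (the mutant is
  expressed but untranslatable); puromycin and EDTA remove every
  translation-dependent enrichment; contaminant binding persists under both
  (it is not ribosome-mediated), which is why only the blacklist removes it.

Spiked effects are specified in **SD units of the resulting profile**, not
raw multipliers (defaults: bait 6, targets 3 and 5, contaminants 4). Each
replicate is calibrated against its own no-effect profile: the generator
computes what every gene's median log-ratio would have been without
effects, then multiplies the spiked gene's IP signals so its median lands
exactly the requested number of profile SDs above the profile median. This
makes recovery tests robust to the noise settings. Spike-in genes default
to genes of median abundance, mirroring that the probed baits were
expressed proteins.

The simulator does **not** model spatial artifacts, image-level pixel data,
dye-specific intensity bias, between-array batch effects, or expression
programs; noise magnitudes are stated defaults, not estimates from any
deposited dataset. Consequently, passing tests demonstrate the *analytic*
correctness and calibration of the pipeline, not its behaviour on real
scanner output.

A quantitative caveat worth knowing: with 5,000 genes, a one-sided 2-SD
rule and three replicates, about 0.06–0.09 truly null genes are *expected*
per consensus (5,000 × tail³, slightly inflated because 2-probe genes have
noisier medians than 5-probe genes). A three-replicate consensus is
therefore clean in most but not all runs; the `p^k` law describes the rate,
not a guarantee of zero.

## Problem sizes used by the checks

The bundled checks standardize on: 1,000 random spots per platform for the
QC oracle comparison; null calibration on the full 5,000-gene design with
two replicates; end-to-end recovery on the default configuration over 20
seeded runs (sensitivity and consensus cleanliness) plus five runs each for
the −ATG and puromycin/EDTA condition logic; and smaller designs (200–400
genes, with `min_background` lowered accordingly) where only mechanics are
exercised.

## Worked example

```{r example}
cfg <- ripchip_config(n_genes = 1000, k = 3, seed = 1)
sim <- simulate_experiment(cfg)
ann <- simulated_annotation(cfg)

cs <- call_targets(sim$scans, ann,
                   blacklist = sim$truth$contaminant_genes,
                   min_background = 200)
glance(cs)
tidy(cs)

# the truth the generator planted
sim$truth$target_genes
```

```{r plot, fig.width = 4, fig.height = 4}
std <- standardize_profile(enrichment_profile(sim$scans[[1]], ann))
autoplot(std, highlight = consensus_genes(cs))
```

## Known limitations

* The pipeline consumes pre-quantified spot tables in a simplified
  tab-separated dialect; it does not parse native GenePix ATF/GPR or Agilent
  Feature Extraction files, and performs no gridding or segmentation.
* No between-array normalisation (loess, quantile) is applied — the
  within-array ratio standardization is the entire normalisation model.
* No multiple-testing machinery beyond the replicate-intersection argument;
  there are no q-values.
* "Gained" interactions under perturbation are reported as inconclusive;
  the verdict vocabulary covers only loss and retention.
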