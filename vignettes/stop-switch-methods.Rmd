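---
title: "Designing and quantifying base-editor-switchable stop codons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying base-editor-switchable stop codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopswitch)
```

## The problem

A fluorescence-off reporter allele is built by using a cytosine base
editor (CBE) to install a premature termination codon (PTC) in an EGFP
transgene; the allele is switched back on when an adenine base editor
(ABE) reverts the PTC to the original codon. The package implements the
computational side of that workflow:

1. **switch design** -- which codons of an ORF can a CBE convert into a
   stop, and can an ABE revert that stop with minimal collateral
   ("bystander") editing?
2. **editing quantification** -- given single-end amplicon sequencing of
   the locus, what fraction of reads carries the conversion?
3. **copy number** -- how many transgene copies per diploid genome does
   droplet digital PCR (ddPCR) imply?
4. **activation model** -- with several reporter copies per cell, how do
   per-copy edited-allele fractions map to reporter-positive cell
   fractions?

## Coordinates and conventions

Protospacer positions are 1-based from the PAM-distal (5') end of the
spacer, the field's "A7" nomenclature. Sequence-interval starts
(`protospacer_start`) are 0-based half-open on the input plus strand, so
the two systems round-trip without ambiguity; CDS coordinates
(`edit_cds_position`, `apply_edit()`) are 1-based from the A of the start
codon. Guide inputs may be RNA; U is normalized to T on ingest.

"d bases upstream of the PAM" is read as d bases strictly between the
target base and the first PAM base, i.e. d = spacer_length − target
position. For a 20-mer this makes "12--16 bases upstream" equivalent to
protospacer positions 4--8, which is the window that reproduces the
printed installation guide (target at position 5, fifteen intervening
bases). The inclusive alternative was considered and rejected because it
cannot reproduce that guide; a custom `editor_profile()` can still encode
it.

## Editor profiles

```{r profiles}
editor_profiles()
```

The install screen defaults to the NG-PAM CBE profile, because the editor
used to build such alleles in practice is an SpCas9-NG fusion and because
the printed installation guide's PAM is not NGG; the canonical NGG
profile ships alongside and reports state which profile produced each
candidate. The SaCas9 and S. auricularis ABE windows are not
experimentally established here; they default to positions 4--12 of a
21-mer, are configurable via `editor_profile()` or a YAML config
(`load_editor_profiles()`), and carry a `window_default` flag that
propagates into reports. An N in a candidate PAM window never matches
(conservative: N is unknown, not a wildcard). The genetic code is the
standard table; stops are TAA, TAG, TGA.

## The design screen

Four sense codons are one C->T edit away from a stop: CGA (R), CAA and
CAG (Q) on the coding strand, and TGG (W) through the antisense cytosine
(two distinct edits, giving TAG or TGA). `enumerate_stop_switch_sites()`
tries every such edit and retains a candidate when at least one install
guide places the edited base inside the CBE window with a matching PAM.
5'-proximity is deliberately not a hard filter -- candidates carry their
codon index and a `max_codon` cap is available -- because a screen should
report everything it finds and let the investigator choose.

Bystander counting includes every in-window editable base other than the
target, regardless of predicted consequence; consequence annotations
(synonymous/missense/nonsense/stop-loss, recomputed by translation) are
reported but do not change the count, since deaminases do not read codon
tables. A candidate's `min_reversion_bystanders` is the minimum over its
reversion guides under the default ABE profile: a candidate is as good as
its best guide. Ranking is ascending by that number, ties broken by
orthologue coverage (more Cas9 orthologues with a valid reversion guide
first) and then by smaller codon index; candidates with no reversion
guide at all are retained, flagged, and ranked last so install-only
screens remain possible.

```{r screen}
fx <- egfp_fixtures()
ranked <- rank_candidates(enumerate_stop_switch_sites(
  fx$wt_cds, editor_profiles("be4max_sp_ng"),
  list(editor_profiles("abe8e_sp"))))
candidates_table(ranked)[1:3, c("codon_index", "wt_codon", "installed_codon",
                                "install_spacer", "min_reversion_bystanders")]
```

The packaged fixture is the canonical 720-nt EGFP CDS; the PTC mutant is
never stored but rebuilt at call time by locating the installation spacer
and applying C->T at protospacer position 5 (CDS position 241, codon 81).
The edit is stored strand-explicitly and reported in both
representations, coding-strand c.241C>T and antisense G>A numbering,
since published descriptions of such alleles use either.

## Amplicon quantification

The quantifier mirrors standard batch analyses of base-editing amplicon
data: reads are dropped unless their arithmetic-mean Phred score is
strictly greater than 30 (a plain reading of "average Phred score";
error-probability averaging would weight low-quality bases more
heavily), aligned to the amplicon in whichever orientation scores
higher, and tallied per position inside a quantification window. The
window is protospacer positions center ± halfwidth (defaults 10 and 20)
mapped to amplicon coordinates and clipped -- the defaults always cover a
20-mer protospacer. The window is defined here independently of any
external tool's sign convention for its window-center parameter, and is
recorded in the result object. Reads with an insertion or deletion
overlapping the window are excluded from substitution tallies by default
(`indel_policy = "count_all"` keeps them); reads that do not fully cover
the window are excluded and counted separately, so the accounting
identity n_pass_quality = n_quantified + unalignable + window-indel +
window-incomplete always holds. The headline `editing_percent` is the
percentage of quantified reads carrying the converted base at the
guide's target position; with zero quantified reads it is reported as
missing, never as 0.

Alignment is semi-global -- the read aligned end to end, free end gaps on
the amplicon -- under match +2, mismatch −3, gap open −5, gap extend −2
per gap base (a length-k gap costs 5 + 2k). These values are not derived
from any publication; they are fixed, echoed in result metadata, and
exercised against an independent dynamic-programming oracle in the test
suite. A read whose best score falls below 0.4 × 2 × read length is
flagged unalignable. Orientation ties resolve to the plus strand and
tracebacks prefer matches over gaps, so results are deterministic. For
speed, reads that match the amplicon ungapped at an exactly-indexed
anchor are accepted without dynamic programming when a short proof shows
no gapped alignment can score higher (at most one mismatch always; two
mismatches when unique, agreeing anchors near both read ends bracket
them); everything else runs through a compiled affine-gap
(Gotoh) aligner.

## ddPCR copy number

With p the fraction of positive partitions, the mean occupancy is
λ = −ln(1 − p); the target:reference concentration ratio λ_t/λ_r is
volume-free, and copies per diploid genome are that ratio times the
reference gene's diploid copy number (default 2, configurable). A
saturated channel (p = 1) is an error, not an estimate. The 95% CI uses
the Wilson score interval on each channel's positive fraction -- stable
at low and high occupancy where the Wald interval degenerates -- carried
exactly through the monotone map to λ and combined on the log-ratio
scale by the delta method.

## The activation model

With n reporter copies per cell, each edited independently with
probability q, a cell fluoresces when at least one copy is edited:

f = 1 − (1 − q)^n,  q = 1 − (1 − f)^(1/n).

So the edited-allele fraction is generally *lower* than the
reporter-positive cell fraction, with equality only at n = 1 or q ∈
{0, 1} -- the reason a six-copy reporter is unusually sensitive to rare
editing events. Both maps are implemented with `expm1`/`log1p` to avoid
cancellation near the boundaries; `allele_fraction_from_cells(1, n)`
returns exactly 1. **The independence assumption is the model's main
idealization**: in vivo, copies of one cell share exposure to the
delivery vehicle, so editing is positively correlated across copies and
the true f lies between q (perfect correlation) and the independent
prediction. Inverted allele fractions are therefore lower bounds in the
correlated case.

## What the simulators emulate -- and what they do not

`simulate_amplicon_reads()` draws plus-strand substrings of the amplicon
(220--280 nt by default, matching single-end sequencing of that cycle
range), labels a Bernoulli(q) subset edited, installs the conversion,
applies optional bystander co-edits and a uniform per-base substitution
error, and assigns per-base qualities from a Normal(37, 3) model
truncated to [2, 41]; a configurable fraction of reads (default 5%) is
drawn at mean quality 25 to exercise the Q>30 filter. Bystander co-edits
are independent of the target edit by default; `bystander_linked = TRUE`
confines them to edited reads, reflecting processive deaminase action on
a single molecule. Read starts are uniform subject to covering the
quantification window, as amplicon sequencing covers its locus by
design. Every generator is byte-reproducible under its seed and writes
the seed into its truth manifest.

Deliberately not modelled: quality-by-cycle decay, context-dependent
errors, PCR duplicates and jackpots, indel sequencing errors, and
correlated editing across copies. Passing recovery tests therefore shows
the estimators are correct for substitution-dominated, duplicate-free
data -- the regime of short amplicon sequencing -- not that they are
robust to every real-world artefact.

`simulate_ddpcr()` gives each partition a Poisson occupancy per channel,
independently; `simulate_cell_population()` gives each cell n independent
Bernoulli(q) copies.

## Problem sizes and numerical choices

The recovery analyses use 10,000 reads per sample at per-base error
0.001 across editing fractions 0.03--0.98 (the transduced-fibroblast,
electroporated-fibroblast and bone-marrow regimes), 20,000 ddPCR
partitions at occupancies around 0.2--0.6, and 100,000-cell populations;
these sizes put Monte-Carlo error well below the effects being checked
while keeping each analysis in seconds. Degenerate inputs are errors,
not silent defaults: frame violations, empty sequences, saturated ddPCR
channels, out-of-range fractions, and a guide whose protospacer is
absent from (or repeated in) the amplicon all raise immediately.

## Known limitations

The screen designs guides but does not predict editing efficiency or
genome-wide off-targets (the wet-lab workflow uses empirical off-target
nomination for that). Quantification handles single-base substitutions
only -- no paired-end merging, UMIs, or large rearrangements. The
activation model ignores silencing, mosaicism and partial fluorescence;
it maps fractions, not intensities.
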