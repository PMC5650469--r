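---
title: "Detecting Ire1-dependent mRNA cleavage and no-go decay from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Ire1-dependent mRNA cleavage and no-go decay from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riddseq)
library(dplyr)
```

## The biology and the measurement

In fission yeast the unfolded protein response acts through a single
output: the ER-resident endoribonuclease Ire1 cleaves ER-associated mRNAs
between the G and C of a UG/C consensus, committing them to degradation
(RIDD). A cut inside a coding sequence leaves a truncated mRNA on which an
elongating ribosome runs out of template and stalls with an empty A site.
In cells lacking the rescue factor Dom34 and the 3'->5' decay adaptor Ski2,
these stalled ribosomes and the mRNA fragments they protect accumulate, and
ribosome profiling sees them directly:

* a stalled ribosome on a truncated 3' end protects a **short (15-18 nt)**
  footprint whose 3' end marks the cleavage position at single-nucleotide
  resolution;
* elongating ribosomes protect canonical **long (25-34 nt, mode 28-31)**
  footprints;
* a trailing ribosome that collides with the stalled one (a **disome**)
  protects a long fragment ending ~16 nt upstream of the stall;
* the stalled ribosome recruits an endonuclease ("NGDase") that cleaves the
  mRNA just upstream, stalling the next ribosome ~14 nt further 5', so the
  ribosome acts as a ruler that templates an upstream ladder of cleavages.

`riddseq` implements the computational side of this experiment: density
tracks from aligned reads, single-nucleotide site calling, motif and frame
diagnostics, metagene and periodicity analysis, and a colony-size screen
scorer. A generative simulator of the same mechanism provides ground truth,
so every stage is testable without the original sequencing libraries.

## Density tracks and normalization

Reads aligned to a spliced transcriptome (one reference per transcript,
0-based half-open coordinates internally) are assigned one count at the 3'
end (footprints) or 5' end (mRNA-Seq). Site-level analyses use *unshifted*
3'-end tracks; gene quantitation uses P-site-aligned tracks (shift -2 for
short, -14 for long footprints). Multi-mapping reads are discarded. rpm
divides by the library size in millions, where a library is all
uniquely-mapped 15-34 nt reads of a footprint sample (mRNA-Seq libraries
are counted separately). Gene rpkm sums CDS counts excluding the first and
last five codons, which guards against initiation/termination artifacts.
Transcripts overlapping another transcript on the same strand, flagged
dubious by the user, or with a CDS length not divisible by three are masked
and skipped, never dropped.

## Site calling

For every transcript position the short-footprint density ratio between
stress (+DTT) and control (-DTT) is computed in rpm. Control positions with
no reads are floored at the rpm equivalent of one read *in that library*
(the printed constant 0.244 rpm corresponds to one specific library size,
so the floor is recomputed per dataset). The raw ratio is divided by the
gene-level mRNA-Seq ratio, removing abundance-driven fold changes; the
correction is gene-level because mRNA-Seq coverage is too sparse for
position-level correction, and its direction (footprint ratio divided by
mRNA ratio) is chosen so that a transcript being degraded by RIDD
*increases* the corrected positional enrichment. Genes with an undefined
mRNA ratio keep a factor of 1 with a warning.

A site is called when the corrected ratio exceeds 10 and the position's
pause score (density over the trimmed-CDS mean of its gene, zeros included)
exceeds 2. Sites are annotated with their UG/C motif class (`UGC`, one
mismatch = `near_UGC`, else `other`), reading frame, and membership of
three reporting tiers: a visualization tier (>1.5 rpm in both conditions),
a strong tier (pause > 100) and a metagene tier (pause > 200 and >= 10 rpm).
Calling is restricted to CDS positions: the method detects cleavage through
stalled ribosomes, so UTR cuts are invisible to it by construction.
Thresholds are deliberately hard cutoffs rather than a statistical error
model; filter monotonicity (tightening never adds sites) is tested as an
invariant.

## Metagene, disome and periodicity analysis

Metagene profiles average rpm in a fixed window (default -200..+50) around
anchor sites with equal weight per anchor and no per-anchor rescaling;
frame-0 anchors are analyzed by default because footprint length varies
with frame and mixing frames blurs the peaks. The upstream segment
(-200..-1) is mean-subtracted and autocorrelated with the unbiased
(1/(n-k)) estimator; the power spectrum is the Blackman-Tukey correlogram —
the cosine transform of the even-extended lag series, zero-padded to 1024
points. We use the cosine transform rather than the magnitude of an FFT of
the one-sided lag series because the latter displaces comb-like peaks by a
measurable fraction of a nucleotide. Peaks are local maxima over periods
3-100 nt, refined by parabolic interpolation and reported to the nearest
integer; the secondary peak is the next-ranked local maximum outside 20% of
the dominant period (excluding the dominant peak's shoulder).

One estimator property is worth recording: with a 200-nt window, the
secondary component of an alternating 14-nt comb — two interleaved 28-nt
lattices in antiphase — has its spectral apex displaced upward by up to
~0.6 nt through interference between the two sub-combs, so a true 28-nt
disome component is typically reported as 28-29 nt. We report the value as
computed rather than snapping it to the lattice.

The disome offset is the argmax of the long-footprint metagene over
-40..-1, reported as nucleotides upstream; the expected value is 16 nt for
frame-0 anchors (the lead ribosome's 16-nt protected stub).

## The simulator

`sim_params()` fixes the study conditions; `generate_transcriptome()` and
`simulate_reads()` implement the mechanism generatively.

**Transcriptome.** Random-sequence transcripts (default CDS 1200-1800 nt in
frame, 30-nt UTRs) each carry one planted `TGC` whose terminal-G position
and frame are recorded as truth. Planted sites keep >= 256 nt of CDS
upstream and 60 nt downstream so metagene windows and cleavage ladders fit.
ER flags are drawn at 0.9 for planted-site transcripts and 0.1 otherwise,
matching the strong ER enrichment expected of genuine substrates.

**Activation and depth.** Each planted site activates with probability 0.9
under stress and 0.02 without (the basal leak reproduces the small
stress-independent stall signal seen in rescue-deficient cells). Stall-read
depth is Poisson with mean `stall_depth` x genotype multiplier (x6 for
*dom34*, x3 for *ski2*, multiplicative in the double knockout — scalar
emission/stability multipliers, not kinetic models) and an `anchor_boost`
(x5) at the primary site, where ribosomes accumulate longest.

**The cleavage ladder.** Ribosome positions are set by stacking against the
queue, so rungs live on a rigid lattice at multiples of 14 nt upstream of
the primary site. Each round is a monosome round (cleavage behind the
stalled ribosome; next stall one rung up) or a disome round (a trailing
ribosome stacks first: it emits a long read ending 16 + frame nt upstream
of the lead's 3' end, the intervening rung is protected and never yields
stall reads, and the next stall forms two rungs up). Disome formation is
*persistent* — probability 0.85 at the primary stall, 0.9 after a disome
round, 0.5 after a monosome round. Persistence matters: if disome formation
were an independent coin flip per round, the even/odd parity of protected
rungs would decohere after a single round (alternation contrast decays by
|2p-1| per rung, i.e. to zero at p = 0.5) and no 28-nt spectral component
could exist; sustained stacking keeps the 28-nt register phase-locked to
the primary site, which is exactly the persistent alternating intensity the
disome signature consists of. Chains continue with probability 0.9 per
round, so the marginal depth envelope decays geometrically and ladders
extend a couple of hundred nucleotides; chains terminate silently at the
CDS start (recorded in the truth table).

**Cleavage-position scatter.** The endonuclease cuts inside the mRNA
channel with 1-2 nt of positional freedom. We decompose this into a
per-site ladder registration offset (-3..+3, triangular) plus an
independent per-rung scatter (-2..+2, triangular), both non-accumulating
because the ribosome queue, not the previous cut, sets each rung. Without
this scatter the read comb is delta-sharp and its 7-nt harmonic outranks
the genuine 28-nt disome component; with it, simulated metagene peaks have
realistic few-nucleotide widths. The primary site itself is exact — the
initiating cut defines the coordinate origin.

**Read lengths.** A stall whose terminal base is in frame f yields a
16 + f nt footprint; frame-2 stalls translocate once more with probability
1/3, shortening the footprint to 15 nt with the 3' end unchanged (the
mRNA's physical end cannot move). Long footprints (background and disome)
draw from a 25-34 nt distribution with ~73% of mass at 28-31 nt. Poisson
backgrounds cover every CDS (0.2 long and 0.02 short reads per nt), and
mRNA-Seq reads fall uniformly with abundance multiplied by 0.4 on cleaved
transcripts under stress.

Truth tables record planted sites with activation flags, every round's
lattice rung, disome flag and realized read position, and per-transcript
abundance factors; the exact-lattice spacing invariant (14 or 28 nt between
consecutive stalls) is asserted on the rung positions.

**What the simulator does not emulate.** Real libraries carry sequence-
dependent ligation and RNase biases, rRNA/tRNA contamination, mismatches
and multi-mapping ambiguity, nascent-peptide and translocon effects, and
UTR cleavage — none are modeled. Passing recovery tests therefore
demonstrates that the estimators are correct for the stated mechanism, not
that the thresholds are optimal for any particular real library. The
simulator also exaggerates stall occupancy relative to a real library
(short reads are a much larger fraction than the ~10% observed in vivo) so
that desk-scale runs have usable depth per site.

## Problem sizes and numerical choices

Recovery analyses use 220 transcripts (~200 activated anchors) for
periodicity/disome targets and 120 per frame for length diagnostics —
enough that modal lengths are unambiguous and the frame-2 translocation
fraction is estimated to within ~0.01, while a full simulate-and-analyze
cycle stays in the tens of seconds. Detection performance is scored on the
*primary* site per transcript: the predicted primary is the most-downstream
UG/C call, compared at exact position against the planted activated site;
upstream no-go rungs that land on a UG/C trinucleotide by chance (~1/64 of
rungs) are thereby excluded from the primary comparison, mirroring how the
most-downstream-site analysis separates initiating cuts from secondary
ones. Zero-background pause scores return `Inf` rather than dropping the
position; zero control densities are pseudocounted as described; tied
most-downstream positions cannot occur because sites are keyed by unique
positions. The screen scorer floors zero colony sizes at half the smallest
nonzero size in that condition and averages duplicate spots on the log
scale (log2; z-scores are base-invariant).

## Worked example

```{r example, eval = FALSE}
params <- sim_params(seed = 7, n_transcripts = 60)
ex <- simulate_experiment(params, genotype = "dom34_ski2")

short_plus <- to_rpm(build_density(ex$plus$footprints, ex$transcripts,
                                   "short", "three_prime", 0))
short_minus <- to_rpm(build_density(ex$minus$footprints, ex$transcripts,
                                    "short", "three_prime", 0))
mrna_plus <- gene_rpkm(build_density(ex$plus$mrna, ex$transcripts,
                                     "all", "five_prime", 0), ex$transcripts)
mrna_minus <- gene_rpkm(build_density(ex$minus$mrna, ex$transcripts,
                                      "all", "five_prime", 0), ex$transcripts)

sites <- detect_sites(short_plus, short_minus, mrna_plus, mrna_minus,
                      ex$transcripts)
glance(sites)
most_downstream_analysis(sites)$fraction_ugc

anchors <- subset(ex$plus$truth$sites, activated & frame == 0,
                  c(transcript_id, pos))
prof <- metagene_average(short_plus, anchors, ex$transcripts)
spec <- power_spectrum(profile_autocorrelation(prof))
glance(spec)
autoplot(prof)
```

## Known limitations

* Site calling uses the hard-threshold scheme of the original analysis; no
  FDR is attached to a call.
* The mRNA correction is gene-level; a position-level correction would need
  far deeper mRNA-Seq than the design assumes.
* The spectral secondary-peak estimate carries the ~1-nt interference
  displacement described above; distinguishing, say, 27 from 28 nt reliably
  would need longer windows than 200 nt.
* The simulator's disome persistence parameters are plausible but not
  measured quantities; they are exposed in `sim_params()` and the
  directional consequence (removing disomes removes the 28-nt component) is
  what the tests assert.
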