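---
title: "Modelling bidirectional 43S scanning and its footprint signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bidirectional 43S scanning and its footprint signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanpic)
```

## The question and the model

How a capped mRNA is accommodated by the 43S pre-initiation complex (PIC)
determines which start codons are visible to it. Under *threading*, the cap
is fed base-by-base into the mRNA channel, so every position from the 5'
end can be inspected. Under *slot-in*, the mRNA attaches laterally with
eIF4E still on the cap near the exit side of the channel, which places the
P-site about 12 nt downstream of the cap and leaves a cap-proximal *blind
spot*. Slot-in plus *bidirectional scanning* — backward (3'→5') excursions
superimposed on net forward migration — reconciles lateral loading with the
observed translatability of ultra-short 5'UTRs: the PIC can slide back into
the blind spot once eIF4E lets go.

`scanpic` turns this verbal model into a discrete-time Markov walk of the
P-site on `0 … length−3`. Each step, in order:

1. **Commitment.** If an AUG occupies the P-site, commit with probability
   `recognition_base × context`. Context strength is an abstract number in
   [0, 1]; it is *not* computed from sequence, because no sequence-based
   score is part of the model. A per-step (rather than per-visit) check
   means a pausing PIC accumulates recognition chances, which is the
   mechanism by which increased dwell raises upstream-start usage.
2. **Dropoff** with probability `dropoff_rate`.
3. **eIF4E release** with probability `eif4e_release_rate` while cap-bound
   (geometric kinetics — the release mechanism is not characterized
   experimentally, so the memoryless choice is the least-structured one;
   it is exposed in the configuration).
4. **Move** −1/0/+1 with probabilities `(p_back, p_stay, p_fwd)`. While
   eIF4E is bound under slot-in, backsliding reflects at `cap_offset`
   (the cap blocks entry into the blind spot) and both move probabilities
   are scaled by `bound_mobility` — the tether restrains displacement until
   dissociation frees bidirectional scanning. An absorbing *runoff* state
   sits `runoff_margin` nt past the CDS end.

The same chain is used twice: simulated trajectory-by-trajectory (Monte
Carlo, snapshot libraries) and solved exactly. `absorption_oracle()` builds
the sparse transition matrix over states (position × eIF4E flag), treats
commitment at each AUG, dropoff and runoff as absorbing, and solves the
linear absorption system directly. That makes the claim "a downstream AUG
competes with an upstream one only if scanning is bidirectional"
falsifiable to numerical precision rather than by sampling, and it is the
route all selection-probability results take (spacer sweeps, blind-spot
profiles, internal-entry selection).

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `cap_offset` | 12 nt | the cap-proximal blind spot of the slot-in geometry; also why a 12-nt core 5'UTR needs essentially no scanning |
| `p_fwd, p_back, p_stay` | 0.42 / 0.35 / 0.23 | near-balanced walk with net drift +0.07 nt/step; the excursion-depth law P(depth ≥ k) ≈ (p_back/p_fwd)^k = 0.83^k makes ~12-nt excursions common (the observed oscillation scale) while ~30-nt retrograde reaches stay rare but real |
| `recognition_base` | 0.5 | near-certain commitment at a strong AUG over a visit cluster, yet measurable leakiness at weak contexts |
| `eif4e_release_rate` | 0.002/step | cap engagement persists through a substantial fraction of a typical 200-nt 5'UTR scan, consistent with reports of cap-tethered scanning |
| `bound_mobility` | 0.2 | displacement restraint while tethered; the origin of the cap-proximal dwell that shows up as the TSS 3'-end bump |
| `dropoff_rate` | 2e-4/step | sets overall initiation efficiency without dominating outcomes on reporter-length transcripts |
| `pic_len_open` / `pic_len_closed` | N(30, 5) / N(60, 10) nt | open (eIF4A-engaged) versus closed conformation protected-fragment lengths; the closed tail reproduces the broad upper length range seen in mixed PIC libraries |
| `p_open` | 0.7 | fraction of snapshots catching the open conformation; lowered by the eIF4A1-knockdown and hippuristanol presets |
| `cap_complex_len` | N(35, 2) nt | the cap-anchored fragment of an eIF4E-engaged complex; tight, so its 3'-end peak is sharp ("parallel" 5'/3' distribution) |
| `ribo80s_len`, `ribo80s_p_offset` | N(29, 2), 12 nt | canonical elongating-ribosome footprint geometry |
| `osc_reach`, `osc_reach_sd` | 12, 2 nt | excursion amplitude of a start-codon-engaged PIC; the quantity the flanking-peak analysis recovers |
| `engage_dwell`, `ribo80s_dwell` | 300 steps each | start-codon residence before/after subunit joining; sets the start-codon occupancy peak that dominates metagene plots |
| `boundary_noise_sd` | 1 nt | RNase boundary raggedness, both ends |

Condition presets are pure overrides of this configuration: `eif4a1_kd`
and `hippu` lower `p_open` and damp oscillation (`p_back` 0.05, `p_stay`
0.53); `pata` raises `p_open`, `p_back` and `p_stay` (0.9/0.36/0.24) so
dwell per position grows; `tethered_eif4e` forces the release rate to zero;
`ires_only` loads at the transcript's internal entry site with eIF4E never
engaged. Drug names label parameter sets; no concentration or binding
chemistry is simulated, and whether pateamine acts through dwell,
recognition, or both is unresolved — the preset changes dwell only.

## What a snapshot library is

`snapshot_library()` abstracts formaldehyde crosslinking: each simulated
complex is caught at uniformly random moments of its life and each snapshot
emits one protected fragment.

* **eIF4E-bound complex**: two fragments exist — the cap-anchored one
  (`[0, cap_complex_len)`) and the channel fragment around the P-site; a
  snapshot captures the cap side a third of the time (the channel complex
  presents the larger crosslinking surface).
* **Free scanning PIC**: a channel fragment of open- or closed-conformation
  length, split symmetrically about the P-site (`channel_up_frac` 0.5).
* **Start-codon-engaged PIC** (post-commitment, pre-joining): with
  probability `p_open × p_back/p_fwd` the complex is caught mid-excursion
  and its fragment lies wholly on one side of the codon, codon-proximal end
  at distance ~N(`osc_reach`, `osc_reach_sd`); otherwise it sits on the
  codon. Tying excursion frequency to both eIF4A engagement and backslide
  propensity is what makes flanking peaks collapse under the knockdown
  preset and vanish entirely without backsliding.
* **80S**: the canonical fragment with the P-site 12 nt from the 5' end.

Both fragment ends get Gaussian jitter and are clipped to the transcript.
Library classes filter complexes: `ribo80s` (80S only), `pic`
(scanning/cap only), `eif3` (everything). Each complex contributes
`snapshots_per_trajectory` (default 10) reads rather than one — a
variance/cost trade-off that leaves profile expectations unchanged while
making 10^6-read libraries cheap; per-transcript RNG streams are derived
from the root seed plus a stable hash of the transcript id, so results do
not depend on transcript order.

## The analysis pipeline, literally

The sequencing-side operations mirror a standard footprint-profiling
pipeline: 3'-adapter trimming (`CTGTAGGCACCATCAAT`) with a 15–35 nt
length filter; region classification with precedence
TSS > start_codon > 5'UTR > CDS > 3'UTR (the TSS class is reads starting
within 1 nt of the cap — a configurable margin, since "mapped to TSS" has
no unique definition); per-transcript-normalized end aggregation (counts at
each relative position divided by the transcript's average reads, i.e.
total selected ends over transcript length, then averaged across
transcripts — the whole-transcript mean, the simplest reading, not the
window mean); mitochondria-normalized RPKM with the "< 1 excluded" rule
read literally (RPKM exactly 1 is kept); and 5'UTR/CDS density ratios with
the 3'UTR-controlled alternative.

Numerical choices worth knowing: medians and modes break ties toward the
smaller length; the 3' end of `[start, end)` is `end − 1`, the last
protected nucleotide; adapter trimming iterates to a fixed point (so
trimming twice equals trimming once, for every input, at the price of
occasionally over-trimming an insert that genuinely ends in an adapter
prefix of ≥ 5 nt); 80S subtraction matches per-(position, length) counts
per transcript, defaults its scale to the per-transcript ratio of
start-codon-region totals, and rounds the fractional remainder *down* —
an enrichment operation should err toward removing contamination. A
`length_gate` strategy (drop reads within ±2 nt of the 80S modal length)
is provided as the alternative reading of how an 80S component might be
removed; the package asserts neither as "the" method.

## Model discrimination

The three loading models leave distinct TSS-anchored end-profile shapes,
quantified by `signature_statistics()`:

* `tss_3p_low_mass` — the fraction of near-TSS 3' ends at positions 5–25.
  Base-by-base threading entry produces short, growing footprints whose 3'
  ends populate this band densely; laterally loaded complexes cannot reach
  it except via backsliding, so the statistic cleanly orders
  threading ≫ bidirectional ≫ pure slot-in.
* `tss_3p_bump` — the secondary 3'-end structure beyond the cap-complex
  peak: the maximum over relative positions `(modal_cap + 5, 100]` divided
  by the tail-quartile median.
  It is fed by closed-conformation channel fragments of complexes dwelling
  against the cap-offset floor — the "eIF4E delays backsliding until
  dissociation" population — and rises monotonically with `p_back`.
* `tss_5p_peak_height`, `parallelism` and the two `length_gradient`
  regressions are computed and reported for auditability but are not
  decision axes: in this simulator cap-anchored fragments give *any*
  slot-in library a 5'-end spike and a near-unit length-vs-3'-end slope, so
  those statistics do not separate the models reliably.

`classify_loading_model()` applies a two-threshold rule — threading if
`tss_3p_low_mass` is high, otherwise bidirectional versus slot-in by
`tss_3p_bump` — with thresholds produced by `calibrate_classifier()` at
run time (geometric midpoints between the adjacent models' observed
ranges on fresh simulations). No threshold is hard-coded anywhere.

`flanking_peak_offsets()` recovers the oscillation reach: the upstream
3'-end peak and downstream 5'-end peak around the start codon, each
required to exceed 1.5× the local 21-nt median (configurable) before it
counts — absent peaks are reported as `NA`, never invented.

## What the generator emulates, and what it does not

`generate_transcriptome()` builds a single-isoform transcript world in
transcript coordinates: 5'UTR lengths lognormal around the mammalian
average of ~200 nt, CDS and 3'UTR lengths lognormal (means 1.2 kb and
0.5 kb), one annotated start AUG per transcript with context drawn from
[0.6, 1], an optional Poisson planting of weak decoy AUGs in the 5'UTR
(off by default; used for upstream-initiation experiments), and a
deterministic mitochondrial subset (`max(1, round(fraction × n))`) used
only as a normalization yardstick. Sequences, when requested, are random
ACGU with AUG planted at every annotated site.

What passing tests on this synthetic world do *not* show about real data:
there is no sequence-dependent recognition (context is declared, not
read from a Kozak motif), no uneven expression (reads are allocated evenly
across transcripts), no elongation — the only 80S ever seen sits at a
start codon, so CDS occupancy profiles are start-biased by construction —
no reinitiation after uORF translation, no isoform ambiguity, and no
ligation/PCR bias in the read model beyond Gaussian end jitter.

## Problem sizes and other deliberate choices

The packaged analyses run at desk scale: selection probabilities come from
the exact oracle (hundreds of states, milliseconds); Monte-Carlo
cross-checks use 10^4–10^5 trajectories; signature work uses 1000-transcript
annotations with 2×10^5-read libraries for calibration and 10^6-read
libraries for parameter-recovery and classifier-consistency runs. The
trajectory cap defaults to `max(50 × length, 30/dropoff_rate)` steps so
that censoring is a negligible tail event — a 10×-length cap, natural for
a strongly drifting walk, censors more than a third of non-committing
trajectories under the near-balanced default walk and visibly biases
censoring-excluded Monte-Carlo estimates away from the oracle. Censored
trajectories are still counted and reported, and are excluded from
selection probabilities.

Degenerate inputs are handled explicitly: a transcript too short for
slot-in loading is a counted loading failure, not an error; footprints are
re-drawn (up to 10 times) when jitter produces an empty interval; an
absorption chain with no reachable absorber raises a diagnostic error; a
zero-coverage aggregation raises rather than returning an empty profile.

## Known limitations

The bound-mobility restraint, the 1/3 cap-fragment emission ratio, the
engaged-phase dwell and the excursion-emission rule are modelling choices
made to reproduce the qualitative footprint signatures of the three
loading mechanisms; they are not measured quantities, and alternative
parameterizations could produce similar profiles. Selection probabilities
are exactly that — probabilities per loaded PIC; mapping them to reporter
luciferase or flow-cytometry units would require a proportionality
constant the model does not contain, so only relative comparisons are
meaningful. The classifier certifies internal consistency between the
simulator and the profile statistics, not a biological verdict on real
libraries.
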