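---
title: "Modelling meiotic drive and rearrangement sterility in fission yeast hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling meiotic drive and rearrangement sterility in fission yeast hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporedrive)
```

`sporedrive` models why *S. pombe* (Sp) × *S. kambucha* (Sk) hybrid diploids
are nearly sterile, and makes every step of the argument — from crossover
placement to killer-strength estimation — a computable, testable object.
This vignette explains the model, its parameters, and the choices made where
the underlying biology leaves the design open.

## The genome model

All coordinates are 1-based positions on the Sp reference; the ancestry of
any chromatid is a breakpoint list in those coordinates regardless of which
physical arrangement carries it. Two rearrangements distinguish the species:

* an inversion on chromosome 1 between 2,683,632 and 4,911,515, carried by
  the Sp lineage (Sk retains the ancestral arrangement);
* a reciprocal translocation between chromosomes 2 and 3, carried by the Sk
  lineage, with junctions at chr2:676,281 and chr3:1,932,034. The Sk-karyotype
  chromosome 2 ("K2") carries the chr2 arm distal of the junction plus the
  chr3 segment distal of 1,932,034; K3 carries the complementary blocks.
  This orientation is fixed by the sequenced recombinant strains: the
  `KRK` strain's chromosome 2 has Sp alleles distal of *mat1* (chr2
  ~2.11 Mb), which therefore must reside on K2, and the `KKR` strain's
  chromosome 2 carries chr3 content around 2.29 Mb.

The junctions partition chromosomes 2 and 3 into four blocks (`chr2L`,
`chr2R`, `chr3L`, `chr3R`), each treated as one essential unit — the
exchanged blocks carry known essential genes (*alr2*, *SPCP1E11.08*), and
the viability logic needs nothing finer than "every block must be present".
Chromosome lengths and centromere positions are fixed reference constants;
marker positions are approximate (no base-pair positions are printed for the
classical markers), chosen to respect the qualitative map: *lys1* and *lys7*
inside the inversion, *leu1* and *ade6* nearest the chromosome 2 and 3
killers, *ura4* near the chromosome 3 left telomere, *his5* on the
K2-retained arm so that it works as the chromosome 2 ploidy marker. Since
every derived quantity consumes positions only through the linear
bp-to-cM map (0.16 cM/kb, the genome average; hotspot structure is
deliberately ignored because crossover frequencies are fairly uniform in
this genome), marker placement shifts curves smoothly rather than changing
behaviour qualitatively.

## The meiosis engine

Crossovers per bivalent follow a Poisson process with mean `2d` events for a
genetic length of `d` Morgans, no chiasma or chromatid interference, and
uniform positions — the count-location model that reproduces Haldane's
mapping function exactly. Two implementation points matter for correctness:

* **Axis occupancy.** Each crossover pairs two synaptic axes (one chromatid
  slot per parent), but the molecules that exchange distal tails are the
  ones *currently occupying* those axes, and the occupancy itself swaps at
  every crossover. Events are therefore processed per chromosome arm,
  outward from the centromere, with an occupancy permutation per arm;
  occupancy carries across the translocation junctions, which also makes
  crossovers in a translocated arm exchange whatever is attached distally
  (this is how viable `KRK`/`KKR`-type recombinant chromosomes arise).
  Applying exchanges to fixed strand slots instead would undercount
  ancestry switches and bias two-point recombination below Haldane — a
  property the test suite checks directly at 5–100 cM.
* **Inversion parity.** Quadrivalent and inversion-loop geometry is not
  modelled structurally. Instead each chromatid counts the crossovers it has
  undergone inside the inversion; in an inversion-heterozygous meiosis an
  odd count marks the chromatid unbalanced (duplication/deficiency) and the
  spore dies. Each exchange product inherits its centromere-side parent's
  count plus one, which reproduces the classical two-strand and three-strand
  double-crossover outcomes.

Coincident integer cut positions (a ~10⁻⁵ event per meiosis) are dropped as
cancelling. In `rec12` null mode the Poisson process is replaced by a
residual Bernoulli crossover per chromosome per meiosis (default rate 0.005,
uniform position): rare Rec12-independent exchange is real but unquantified,
and 0.005 keeps recombinants below ~1% of viable spores as observed.

Meiosis I disjoins any bivalent that received a crossover (missegregation of
chiasmate bivalents is not modelled); an achiasmate bivalent disjoins
properly with probability `p_dist`, the fidelity of the distributive
(recombination-independent) segregation system, and otherwise each homolog
picks a pole at random — giving a spore 1 copy with probability 1/2 and 0 or
2 with probability 1/4 each. `p_dist` is a genuinely free parameter: the
system is known only to be "partially effective", so the default is 0.5 for
pure species and hybrids alike, and results that depend on it (notably the
viable fraction of `rec12` null crosses) should be read as conditional on
it. Meiosis II always separates sisters.

## Viability and drive

Death rules apply in a fixed order, and a dead spore records the first
failure: structural imbalance, missing essential block, copy-number
lethality (only haploids, diploids and chromosome 3 disomes survive;
chromosome 1/2 aneuploidy is lethal), then stochastic killing. Each killer
locus kills a non-carrier spore with probability `d`, independently across
loci; carrying one copy of the killer allele rescues completely. This
poison/antidote formulation *implements* the aneuploid-rescue hypothesis:
heterozygous diploids and chromosome 3 heterozygous disomes carry every
allele at the chromosome 3 killer loci and are immune, which is what
enriches them among hybrid survivors. Whether killers act on diploid spores
at reduced rather than zero intensity is untested biology; the model makes
carriers fully immune.

Default strengths are calibration, not measurement: the Sk killers use the
single-locus estimator `d = 2 - 1/t` applied to the printed transmissions of
the nearest markers (72%, 94%, 82% → 0.611, 0.936, 0.780), and the
hypothesised Sp chromosome 3 counter-killer defaults to 0.2 — a labelled
hypothesis parameter, since only the existence of a "weaker" opposing killer
is argued, never its size. A killer whose allele is absent from both parents
of a cross produces no poison and is inert.

## The exact enumeration oracle

With no crossovers, the three bivalents are independent and each spore's
per-chromosome state is one of {absent, parent-1 homolog, parent-2 homolog,
both}; 64 joint classes enumerate the whole distribution. Killing is applied
in expectation (survival weights, never sampled), making the enumeration
exact — it serves as the oracle for the simulator (total-variation agreement
on random configurations) and as the likelihood kernel for fitting. Two
published-style figures anchor it: translocation heterozygosity halves the
viable haploid fraction exactly, and fully random segregation (`p_dist = 0`)
gives a viable-complement probability of 13/64 ≈ 20.3%. The often-quoted
"~25%" figure for this quantity is *not* forced: 13/64 is what pure random
segregation yields under these viability rules, and a distributive system of
fidelity ≥ 0.2 raises the model's value to ≥ 25% (at 0.2 it is 29.6%). Both
numbers are reported rather than reconciled.

Transmission conditionals mirror the assay's exclusions: heterozygous
diploids are excluded for all loci, heterozygous chromosome 3 aneuploids
additionally for chromosome 3 loci, and heterozygous calls at the assayed
locus never enter the denominator. Homozygous diploids and disomes are
invisible to the codominant-marker assay and are deliberately miscounted as
haploids, exactly as the genotyping would.

## Inference

`fit_drive_model()` maximises the survivorship-conditioned multinomial
likelihood of the observed (marker calls × ploidy class) table over the free
killer strengths, with bounded L-BFGS-B from five seeded restarts and
profile likelihood-ratio intervals. Killers not heterozygous between the
parents are flagged non-identifiable rather than silently pinned. Observed
classes outside the exact kernel's support (rare residual recombinants) are
dropped and counted in the diagnostics. The chromosome 3 killer and the Sp
counter-killer are both exposed, but a single cross constrains mainly their
ratio of effects on the two non-carrier classes; joint estimates from one
table should be read with that confounding in mind.

`localize_driver()` maps a killer from per-marker transmission gradients
under `t(x) = (1 - r(x) d)/(2 - d)`, maximising the binomial likelihood on a
10-kb grid with local refinement — killer loci are only coarsely mappable
this way, and finer output would be spurious precision. Because the curve is
identically 1/2 at `r = 1/2` regardless of `d`, no-signal data produce a
flat likelihood ridge; the fit is declared unidentifiable unless it beats
the no-killer likelihood, in which case the position is undefined and the
interval is the whole chromosome.

## What the synthetic generator does and does not emulate

`simulate_cross()` reproduces the study's cross designs (presets for the
pure-species, hybrid, and single-heterozygous-chromosome crosses, with the
sequenced breakpoints of the recombinant `R` chromosomes) and the genotyping
assay, including its blind spots. It does **not** emulate: crossover
interference or hotspots; gene conversion; mitotic divisions before meiosis
(so simulated viable-spores-per-meiosis is not on the scale of the plated
viable-spore-yield assay, which can exceed 4); germination-time versus
sporulation-time death; or growth-rate differences among surviving
genotypes. Passing tests therefore show the model's internal consistency and
its qualitative agreement with the published spore-genotype patterns, not
that real meioses lack interference or that killer strengths equal their
calibrated defaults.

Two quantitative gaps are worth stating plainly. First, simulated marker
transmissions in the recombining hybrid land near the printed values
(e.g. ~72% at *lys1*, ~90% at *leu1*) because the calibration targets them;
the agreement at the *other* markers (e.g. ~65% at *his5* versus the printed
67%) is emergent and encouragingly close. Second, the genotyped
recombination-free census shows 289 chromosome 3 aneuploids against 38 pure-Sk
haploids — a >7-fold excess. Under this model the ratio of those two classes
is bounded by `((1-p)/4) / ((p/2 + (1-p)/4)(1-c))` with `p = p_dist` and `c`
the counter-killer strength, which cannot exceed ~1.25 at the defaults;
reproducing 7.6 would need `c ≈ 0.87`. Either the counter-killer is far
stronger than "weaker" suggests, or something outside this model (e.g.
differential germination of aneuploids) inflates the observed ratio. The
package reports the printed counts as data and leaves the model's bound as a
limitation.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 4,000–10,000 meioses for
oracle agreement, 20,000 chromatids for the Haldane check, 5,000 meioses for
strength recovery (±0.05) and ~800 recombining meioses for position recovery
(within the 1.4-Mb inter-marker spacing) — sizes at which Monte-Carlo error
is comfortably below the assertions' tolerances while a full run stays in
the minutes range. Every stochastic entry point takes a seed and threads it
through R's RNG (`withr::with_seed`), so identical seed + configuration
yields byte-identical spore tables and bit-identical fits. Cross
configurations serialise to YAML (the block structure mirrors the
configuration object: parents, drive, recombination, segregation, genome)
and spore tables to commented TSV with the configuration hash and seed in
the header.
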