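---
title: "Detecting PCR chimeras in AIRR-seq data with a duplicated-state HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting PCR chimeras in AIRR-seq data with a duplicated-state HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Every PCR cycle applied to rearranged V(D)J amplicons can produce chimeric
molecules: an incompletely extended product of one template anneals to a
similar, but different, template and is extended to completion. The result is
a read whose 5' part comes from one germline V allele and whose 3' part from
another. In B-cell data such artifacts are easily mistaken for heavily
somatically hypermutated (SHM) receptors — exactly the sequences analysts
tend to prioritize — so repertoire pipelines need a detector that can tell
"many real mutations" apart from "two templates spliced together".

Two properties of AIRR-seq make a reference-based probabilistic approach
attractive: germline V alleles are catalogued in curated databases, and every
standard annotation pipeline already aligns each read to its best-matching
germline. `airrchimera` exploits both.

## The model

Let the reference database be G aligned germline alleles in a multiple
sequence alignment (MSA) with L columns, and let the query, re-expressed in
MSA coordinates, be O = O1..OL over {A,C,G,T,-,N}. The HMM has 2GK states:
each of the G alleles appears at K mutation-rate categories, once in a
*non-chimeric* copy and once in a *chimeric* copy. A state emits the query
nucleotide with probability 1−m when it matches the reference nucleotide,
m/3 when both are plain nucleotides and differ, and 1 when either side is a
gap or N (such columns can neither support nor contradict any allele, and
contribute the same factor to every state, so they cancel from the
posterior).

Transitions encode template switching:

* self-transition: 1 − ψ − μ (1 − ψ when K = 1; see "Numerical choices"),
* switching rate category within the same allele and class: μ/(K−1),
* switching to the *chimeric* copy of a **different** allele: ψ/((G−1)K),
* all transitions into non-chimeric states of another allele, or into the
  chimeric copy of the *same* allele, are forbidden.

Initial mass is uniform over the GK non-chimeric states. Because a path can
enter the chimeric half but never leave it, the Forward mass of the chimeric
half at the final column, normalized by the total, is exactly the posterior
probability that the query switched template at least once:
P(chimera | O) = Σ_{i∈C} α_L(i) / Σ_i α_L(i).

The naive Forward induction costs O(L(GK)²). The transition matrix has only
three distinct off-diagonal values arranged block-wise, so the induction can
be rewritten using the per-column total mass and G per-allele partial sums,
giving O(LGK). `chmm_forward()` implements this; `chmm_forward_oracle()`
keeps the dense quadratic version as an independent reference, and the test
suite drives both over hundreds of randomized instances (agreement is at the
1e−9 level or better, typically machine precision). The same restructuring
applies to the Backward pass and, with maxima instead of sums, to Viterbi
decoding, which reports the most likely parent alleles and the breakpoint
columns where the path switches reference.

### Handling SHM: DB and BW modes

* **DB (discretized) mode** handles mutation by a grid of fixed rate
  categories. For TCR data, which lacks SHM, a single category at 0.005
  absorbs sequencing error. For IG data the grid is 15 categories evenly
  spaced over [0, 0.25] (endpoints included; a rate of exactly 0 is allowed —
  those states simply die on the first mismatch while other categories absorb
  the mass).
* **BW mode** uses K = 1 and instead re-estimates a continuous per-allele
  mutation rate by Baum-Welch EM, per query: each iteration runs the scaled
  Forward/Backward pass and replaces each allele's rate by its
  occupancy-weighted mismatch fraction over informative columns (both sides
  plain nucleotides), pooling that allele's chimeric and non-chimeric states.
  Rates are clamped to [1e−6, 0.5]; defaults are 10 iterations, tolerance
  1e−3, initialization 0.05. Per-query estimation keeps the tool free of
  batch context; the EM ascent property and rate recovery (MAE < 0.03 for
  planted rates of 0.05 and 0.10 on 300-column queries) are tested.

`detection_config()`'s receptor presets choose between these: `TCR` → DB at
0.005, `IG` → BW initialized at 0.05.

## Threading

Queries are never re-aligned. The AIRR Rearrangement record already contains
the pairwise alignment of the query's V segment against its best-matching
allele (`v_sequence_alignment` / `v_germline_alignment`) plus the germline
coordinates. `thread_query()` walks that alignment: germline-ungapped
positions map through the allele's gap structure to MSA columns; query
insertions (germline-side gaps) are dropped — insertions are rare and carry
almost no information about which reference produced the query; query
deletions become `-`; all columns never written (outside the aligned
interval, or gap columns of the assigned allele) become `N`. Every query
therefore occupies the same L-column lattice regardless of indels. When
`v_call` lists several alleles the first (best-scoring, by AIRR convention)
is used.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `psi` | 0.002 /column | prior probability of a template switch |
| `mu` | 0.002 /column | prior probability of a rate-category switch (DB) |
| `threshold` | 0.95 | posterior above which a query is called chimeric |
| `fixed_rate` | 0.005 | DB rate for TCR (sequencing error scale) |
| `rate_grid` | 15 over [0, 0.25] | DB grid for IG |
| `bw_init` | 0.05 | BW initialization rate |
| `min_dfr` | 0 (off) | skip queries with fewer mismatches than this |

ψ and μ are genuinely free parameters. The defaults of 0.002 per column were
fixed once, on the reasoning that over a ~300-column V gene they put roughly
45% prior mass on "at least one switch" spread across all (G−1)K·L
alternatives, small enough that emissions dominate any individual call; both
are exposed for users who want a different sensitivity/specificity trade-off.
The `min_dfr` prefilter implements the observation that a chimera of two
different alleles must disagree with any single allele: queries with fewer
than `min_dfr` differences from their assigned reference are passed through
as non-chimeric without HMM evaluation (a pure runtime optimization; 2 is a
sensible value for TCR data).

## Numerical choices

* **Scaling.** Forward/Backward use per-column normalization with an
  accumulated log scale rather than log-space max-sum arithmetic; this keeps
  the linear-time algebra in plain multiplications. With the shared scales,
  `alpha * beta` columns are posterior state marginals summing to 1.
* **K = 1 and μ.** The μ channel moves mass between rate categories of the
  same allele. At K = 1 no such targets exist; the self-transition is then
  1 − ψ, keeping every transition row stochastic (this also matches the
  closed form for uninformative queries, P(chimera) = 1 − (1−ψ)^(L−1),
  which the tests verify).
* **ψ = 0** is accepted and gives posterior exactly 0 — useful as a
  degenerate control.
* **Viterbi ties** break toward the lowest state index, making decoded paths
  deterministic.
* **Breakpoints** are reported in 1-based MSA columns — the model's native
  frame, stable under query indels. A breakpoint is only identifiable up to
  the interval between the flanking columns at which the two parents differ;
  tests assert exactly that interval.
* **Degenerate inputs.** All-gap/all-N queries have flat emissions and are
  scored purely by the transition prior. Reference-side `N` characters emit
  1 for any observation, symmetric to query-side N handling (the least
  surprising extension; reference databases normally contain none).

## The simulator, and what it does (not) show

`simulate_dataset()` reproduces a standard simulation design: 10,000
sequences per dataset at 5% chimerism (exactly 500/9,500 by construction),
non-chimeric reads generated by uniformly mutating one genotype allele,
chimeric reads by joining two uniformly mutated alleles at a breakpoint
uniform over columns 2..L. A flat per-site error rate emulates sequencing
noise (0.005 is a reasonable short-read scale). `v_call` is assigned by
nearest Hamming distance — the detector is never handed the true parent.
Genotypes are sampled one-allele-per-gene from a larger allele set, as
personalized genotypes are in practice.

Because no real germline download is bundled, `synthesize_germline_msa()`
generates a synthetic aligned allele set with the hierarchical structure of
real V loci: ~6 families diverged ~20% from a common ancestor, ~8 genes per
family diverged ~6% from their family founder (inter-gene distances of a few
tens of nucleotides — the range where chimeras both form and are detectable),
1–3 alleles per gene differing by 1–2 substitutions, and occasional short
deletions so the MSA contains gaps.

Two deliberate simplifications matter when extrapolating to real data:

* **SHM is uniform**, not hotspot-targeted. Targeted SHM concentrates
  mutations in motifs; uniform SHM spreads them evenly, which makes
  "accidental mosaic" patterns — a mutated read that genuinely looks like a
  splice of two same-family genes — somewhat *more* likely. In full-scale
  runs (9,500 non-chimeric IGHV-like reads, DB grid mode, threshold 0.95)
  we observe 0–2 false positives at 10% uniform SHM and ~6 at 20%, rather
  than exactly zero; single borderline false calls at high uniform SHM are
  an artifact of the uniform-mutation stand-in rather than of the detector.
* **No clonal structure, no targeted error profiles, no D/J simulation.**
  The simulator draws independent sequences; real repertoires have lineage
  structure that correlates errors across reads but does not change the
  per-read decision problem.

## Problem sizes used in the tests

Oracle equivalence runs 200 random instances with G ≤ 5, K ≤ 3, L ≤ 50 plus
exhaustive path enumeration (4^8 paths) for Viterbi; rate recovery uses 50
replicates per planted rate at L = 300; the false-positive and AUC studies
run the full 10,000-sequence design and a 2,000-sequence TCR-like design
end-to-end through file I/O, threading, and the CLI-equivalent entry points.

## Known limitations

* V-segment chimeras are the target; J analysis is possible
  (`segment = "J"`) but inherently less sensitive (the J segment is short),
  and D segments are too short to analyze at all.
* Accuracy depends on database completeness: a genuine allele missing from
  the database tends to be flagged as a recurrent chimera of its nearest
  relatives. `subsample_genotype()` plus `normalized_recombination_counts()`
  reproduce this diagnostic: overrepresented gene-pair cells point at
  missing alleles.
* The emission model ignores SHM hotspot bias and query insertions.
* Posteriors are calibrated by the ψ prior; they are posterior probabilities
  under this model, not frequentist error rates.
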