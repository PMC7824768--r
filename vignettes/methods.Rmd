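---
title: "Methods: models, parameters and validation design in venomtk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation design in venomtk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtk)
```

`venomtk` chains five analysis stages — precursor annotation, mass/isotope
arithmetic, in-silico digestion, spectral and intact-mass matching, and
ICK structural metrics — and validates each of them closed-loop against
synthetic data with known ground truth. This vignette documents the models
behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the validation does and does not demonstrate.

## Precursor annotation

A toxin precursor is segmented into signal peptide, propeptide, mature
region and amidation tail; the four intervals always partition the
sequence.

**Signal peptide.** Full signal-peptide predictors are HMM/NN models; here
the signal length $k$ is chosen by a documented physicochemical heuristic
instead. Candidates $k \in 15..30$ (the empirical length range of secreted
peptide signal sequences) must satisfy two constraints: a hydrophobic
h-core — at least 8 consecutive residues with Kyte–Doolittle hydropathy
above +1.5 inside positions $1..k$ — and small residues (A/G/S/C) at
positions $k$ and $k-2$, the classical −1/−3 rule for signal-peptidase
cleavage sites. Among admissible candidates, the one maximizing the mean
hydropathy of residues $5..k-5$ wins. All thresholds are arguments of
`segmentation_params()`. This is an approximation: on real, diverse signal
peptides it will mis-place some boundaries, which is why the package's
recovery guarantees are stated against the synthetic generator, not
against nature.

**Propeptide.** Spider toxin propeptides end in a processing quadruplet
motif. We operationalize it as three residues containing at least one
acidic (D/E) followed by Arg, with cleavage after the Arg; the segmenter
takes the *last* such Arg before the first cysteine of the mature region.
When no motif exists the propeptide is empty and the mature region starts
directly after the signal.

**Amidation.** A C-terminus matching Gly-(Lys|Arg)\{0,2\} is removed
(tail of 1–3 residues) and the product flagged amidated: the glycine is
the amide donor, trailing basics are carboxypeptidase substrates. The rule
is a pure function; on sequences ending in Gly-Gly a second application
could trim again, so idempotence is guaranteed (and tested) for
framework-style matures that end in cysteine, not for arbitrary strings.

**Cysteine frameworks and families.** The framework is stored as ordered
cysteine positions plus a canonical spacing pattern — leading gap,
inter-cysteine gaps and trailing gap interleaved with `C`
(`0C6C5C0C1C2C1C6C1C7C0` for the built-in 10-Cys framework) — chosen so
that `parse_cys_pattern()` inverts it exactly. Family grouping is
single-linkage on global Needleman–Wunsch identity (match 1, mismatch 0,
gap −1; identity = matches / alignment length, computed with Biostrings)
with an identical cysteine count required for linkage; representatives
are lexicographic minima, making results independent of input order.

## Masses and isotopes

All masses derive from one vendored table of isotope masses and
abundances (NIST atomic weights) over C/H/N/O/S; the proton mass is
1.007276466 Da and m/z $= (M + z \cdot m_p)/z$. Disulfide bonds subtract
two hydrogen atoms (−2 × 1.0078250319 Da); C-terminal amidation is −O +N
+H (−0.9840 Da); carbamidomethylation is +C2H3NO (+57.02146 Da).

Isotope envelopes are exact polynomial convolutions of per-element
distributions, aggregated in unit-resolution (nominal offset) bins — the
resolution at which MS1 cluster peaks are read; fine structure within a
bin is collapsed to the abundance-weighted mean mass. Convolution uses
binary exponentiation per element with an internal abundance floor of
1e−9 so that pruning cannot bias retained bins at the user's floor
(default 1e−6, capped at 0.01). Correctness is established against an
oracle that enumerates every isotopologue assignment for compositions of
up to 8 atoms, and by the identity that the abundance-weighted envelope
mean equals the average mass from the same table.

## Digestion, fragments and search

Trypsin cleaves after K/R, GluC after E and D (the Asp specificity it
acquires in ammonium bicarbonate buffer). The "no cleavage before
proline" exception is off by default — the identified peptides of the
built-in case do not constrain it and its mature sequence contains no
KP/RP — and available via `proline_rule = TRUE`. Peptides carry parent
coordinates and missed-cleavage counts; C-terminal peptides of amidated
parents inherit the amide, which shifts y-ions only.

The search engine is deliberately simple and fully documented rather than
a re-implementation of any production engine: candidates are digest
peptidoforms within the precursor tolerance (default 10 ppm) at the
observed charge; fragments are 1+ b/y ions greedily matched one-peak-one-
fragment in m/z order within the fragment tolerance (default 0.02 Da,
appropriate for ~30K-resolution fragment spectra, where 1+ matching
suffices); the score is a hyperscore variant
$\log(n_b!\,n_y!) + \log(\text{matched}/\text{total} + 10^{-6})$,
invariant to peak order and uniform intensity scaling. Ties break by
fewer variable modifications, then lexicographic peptide. Because the
score is ours, all FDR behaviour is validated by simulation with known
ground truth, never by comparison to another engine's output.

Target–decoy FDR uses full sequence reversal, decoys 1:1 with targets,
and $q(s) = \min_{t \le s} \#\{decoys \ge t\}/\max(1, \#\{targets \ge
t\})$ with tied scores sharing the block-end estimate before
monotonization. C-terminal amidation is a protein-level variable
modification: it is enumerated only for C-terminal peptides of mature
entries, symmetrically for their decoys to keep the candidate space
balanced.

## Intact matching

Isotope clusters are detected by greedy longest-run-first grouping of
peaks spaced $1.00336/z$ (the ¹³C spacing constant, adequate below 10
kDa) for $z \in 1..8$ within a spacing tolerance (default 0.01 Da);
charge comes from the spacing, the monoisotopic m/z is the first peak of
the run, and runs shorter than `min_peaks` are discarded. Longest-first
ordering prevents a $2z$ cluster from being consumed as a $z$ run over
every other peak. Chromatographic peak-shape fitting is out of scope;
XICs reduce to per-scan detection plus aggregation by neutral mass.

Candidate sequences are scored over an exhaustive hypothesis grid —
disulfide count $0..\lfloor n_{Cys}/2 \rfloor$ × amidation — by absolute
ppm error of the inferred neutral mass; the amide hypothesis is
distinguishable because its 0.984 Da offset is ~234 ppm at 4.2 kDa,
far outside the 10–20 ppm window. Propeptides join the candidate list;
their absence from the MS1 data is a reported outcome, not an error.

## Structural metrics

Disulfides: all Sγ–Sγ pairs within 2.5 Å (canonical bond ≈ 2.05 Å),
assigned greedily shortest-first so each cysteine bonds at most once.
Turn classification follows the Hutchinson–Thornton convention: β-turns
need Cα(i)–Cα(i+3) ≤ 7 Å, non-helical central residues, and (φ, ψ) of
i+1/i+2 within ±30° of a canonical type (one angle may deviate 45°),
falling back to type IV; γ-turns are typed from (φ, ψ) of the central
residue against classic (75°, −64°) / inverse (−79°, 69°) values. Since
the reference turn lists in the literature come from unstated tools,
agreement with any published per-residue turn list is an integration
check against deposited coordinates, not a unit test.

The ICK classifier searches all 3-subsets of bonds for the abcabc core —
connectivity (1–4)(2–5)(3–6) after ranking the subset's six cysteines —
and labels remaining bonds "C-terminal clamp" (one partner is the last
framework cysteine) or "hairpin staple" (both partners strictly between
core ranks 4 and 6). It is verified against an independently formulated
oracle on 500 random 4–6-bond topologies.

Superposition is Kabsch (SVD with determinant correction); optimality is
cross-checked against a random-rotation search on small point sets. The
Q score consumes precomputed alignment statistics; the SSE-graph
alignment search behind published structure-similarity servers is not
reimplemented. NOE calibration applies the $r^{-6}$ law with a documented
clip to [2.0, 6.0] Å. Disulfide restraints follow the conventional
annealing scheme of three upper and three lower bounds per bond
(Sγ–Sγ 2.0–2.1 Å, Cβ–Sγ twice at 3.0–3.1 Å). The hydrophobicity profile
is a sliding-window mean of the Wimley–White interface scale (ionised
D/E/H values), windows truncated at the termini.

## The synthetic generators: what they emulate, and what they don't

`gen_precursor_library()` emits precursors with signal peptides of 15–30
residues built from an L/I/V/F core with Ala at the −1/−3 positions,
propeptides of 5–25 residues from a polar/acidic pool ending in `EExR`,
matures drawn from a cysteine-framework template with randomized loops,
and (probability 0.7) the canonical `GKR` amidation tail. Two deliberate
idealizations make ground truth unambiguous: precursor bodies are
Met-free — as is the built-in toxin itself — so the initiator ATG is the
only in-frame start, and records are rejection-sampled until the embedded
precursor is the unique ORF of ≥ 40 codons. Residue pools are disjoint
enough that the segmentation constraints identify the true boundaries
exactly; consequently the measured boundary-recovery rate characterizes
the *consistency* of generator and segmenter, not performance on real
signal peptides. Reverse translation uses one fixed codon per residue,
with ATG-free UTR padding.

`gen_msms_run()` draws Gaussian precursor errors (default 2 ppm against
the 10 ppm search window) and 0.002 Da fragment jitter (against 0.02 Da),
log-normal intensities, uniform noise peaks and optional fragment
dropout; `gen_noise_spectra()` provides the matched null with precursors
near real candidate masses so the tolerance gate admits candidates.
`gen_ms1_run()` lays exact envelopes down at each charge state 4–7.
`gen_toy_structure()` builds a backbone by internal-coordinate (NeRF)
chain extension with near-extended torsions and pins Sγ pairs at 2.03 Å;
the geometry is a detection fixture, not a physical model. No
chromatography, charge-state abundance physics or chimeric spectra are
emulated. Every generator seeds a local RNG stream and restores the
global state, so fixtures are pure functions of (parameters, seed).

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(brute-force ORF enumeration, exhaustive isotopologue enumeration,
binomial modification counts, a pairing-matrix ICK oracle, random-rotation
superposition search) and runs closed-loop checks at these sizes, chosen
to keep the default suite fast while leaving comfortable statistical
margins: 200-record precursor libraries for boundary recovery, 300
noise-free spectra for rank-1 identification, a 1000-spectrum mixed run
(800 true / 200 null) for empirical FDR at the 1% threshold, 50 random
scaffolds for disulfide recovery, and 500 random bond topologies for the
ICK oracle.

## Known limitations

* The signal-peptide heuristic and the quadruplet-motif operationalization
  are documented approximations; both will disagree with dedicated
  predictors on some real precursors.
* Fragment matching is 1+ b/y only — no a/c/x/z ions, neutral losses,
  internal fragments or multiply charged fragments.
* Envelope arithmetic is unit-resolution; fine isotope structure and
  deconvolution of overlapping envelopes are out of scope.
* The mzML reader covers only the subset this pipeline writes and reads
  (64/32-bit little-endian arrays, optional zlib, MS1/MS2 with selected
  ion); it is not a general implementation.
* Sheet detection is a reciprocal N–O hydrogen-bond test, far short of
  DSSP; turn typing tolerances (±30°/±45°) are conventional but sharp
  boundaries near them are arbitrary.
* PSM counts observed on real instruments depend on duty cycle and
  chromatography and are not reproducible from synthetic data; the
  package reports them, it does not predict them.
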