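---
title: "Identifying isomeric glycan components of a mixture from MSn spectra"
author: "gipsmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying isomeric glycan components of a mixture from MSn spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gipsmix)
```

## The problem

Glycans released from glycoproteins, glycolipids or human milk rarely come
as pure compounds: a single molecular ion in a MALDI spectrum usually hides
several isomeric structures with different branching patterns (for example
the Lewis-a/x, Lewis-b/y and blood-group-H arrangements of fucose on a
lacto-type backbone). MS2 alone is seldom enough to tell which *set* of
isomers is present, because the product-ion spectrum of a mixture is the
superposition of the components' spectra.

`gipsmix` addresses mixture deconvolution at the branching-pattern level by
*group opting*: instead of asking which single candidate explains the
spectra best, it enumerates **every non-empty subset** of the candidate
structures (2^n − 1 groups for n candidates), simulates the fragment
spectrum of each group, and opts in the group whose simulated spectra best
match the whole acquired MSn spectra tree. When several groups tie, an
information-theoretic criterion picks the next MS3 precursor to acquire.

The unit of identification is the **branching pattern**: the rooted tree of
monosaccharide classes with linkage positions and anomericity ignored.
Discriminating linkage isomers would require linkage-specific fragmentation
rules and cross-ring cleavages, which are outside the scope of this model.

## The spectra tree and candidate generation

All ions are singly sodiated, fully permethylated species (MNa+). From the
MS1 survey spectrum the molecular ion is read off; every database structure
whose permethylated m/z lies within the matching tolerance (default 0.5 Da,
consistent with nominal MALDI ion-trap labelling) becomes a candidate.
Candidates are collapsed to branching patterns by rooted-tree isomorphism;
one representative per pattern enters the grouping stage. The MS2 spectrum
of the molecular ion and MS3 spectra of every MS2 fragment above a 10%
relative-intensity threshold form the *spectra tree*.

Masses are assembled from a monoisotopic element table: residue masses
(native Hex 162.0528, HexNAc 203.0794, dHex 146.0579; permethylated
204.0998 / 245.1263 / 174.0892), one water for a free reducing glycan, a
C2H6O-equivalent terminal-group term (46.0419) plus Na (22.9898) for the
permethylated sodiated molecular ion. The registry is extensible; the
default covers the neutral residues of milk oligosaccharides (sialylated or
anionic residues can be registered by the user but are not needed here).

## Theoretical fragmentation

Fragments arise from single and double glycosidic cleavage only. Cleaving
one bond yields the nonreducing piece as a B ion (+CH2 terminus, 14.0157)
or C ion (+CH4O, 32.0262) and the reducing piece with the intact methylated
reducing end (+C2H6O, 46.0419) and one *scar*. Double cleavage adds
internal pieces (B/C terminus plus one scar) and reducing pieces with two
scars. These offsets satisfy an exact complementarity: for any single
cleavage, m/z(B piece) + m/z(reducing piece with a free scar) − 2·m(Na)
equals the neutral permethylated mass of the intact glycan.

A scar is the position exposed by a cleavage. On a permethylated analyte
the exposed hydroxyl is unmethylated, so the default **free-hydroxyl
convention** shifts each scarred fragment by −14.0157 relative to full
methylation. The alternative methyl-migration convention (no shift, as in
the well-known −174 fucose loss) and the union of both are available via
`scoring_config(scar = )`. The free convention is the default because it is
the chemically standard state and it preserves the diagnostic value of the
terminal-ion anchors: the B/C pair of an *unsubstituted* terminal hexose at
241.11/259.12 then appears only when such a terminus really exists. That is
exactly what makes m/z 660 → 241/259 a clean probe for the Lewis-x
arrangement among the difucosylated hexaoses:

```{r anchors}
lex <- parse_glycan("Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc")
leb <- parse_glycan("Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc")
round(theo_mz(theoretical_ms3(lex, 660.32)), 2)  # contains 241.11, 259.12
length(theo_mz(theoretical_ms3(leb, 660.32)))    # no 660 piece at all
```

MS3 simulation isolates every fragment whose m/z matches the precursor
within tolerance, re-fragments its retained substructure with the terminus
and scars it inherited, and unions the results over all matching isolation
paths; deeper MSn levels iterate the same step along the precursor chain.
Theoretical intensities are uniform — only experimental intensities enter
the score.

## Scoring candidate groups

The theoretical spectrum of a group is the union of its members' spectra
(set semantics, annotations merged). A group G with n members is scored
against the spectra tree S as

  similarity(G, S) = Σ_spectra Σ_{p matched} tanh(β · I_p) − α · n,

where I_p is the relative intensity of matched experimental peak p in
percent and MS2 and MS3 spectra carry identical weight. The tanh squashes
the intensity scale: with β = 0.2 an 80% peak contributes tanh(16) ≈ 1.00
and an 8% peak tanh(1.6) ≈ 0.92, so presence matters far more than a
tenfold intensity difference. The percent scale is essential here — on a
0–1 scale the tanh would stay nearly linear and the compression would be
lost. The −αn term (α = 1) makes every added component cost one matched
peak's worth of score, so a larger group is only preferred when it explains
genuinely new peaks. Matching assigns each experimental peak to its nearest
theoretical m/z within the tolerance (exact ties to the lower m/z); each
peak contributes at most once per spectrum, and a spectrum's own residual
precursor ion is excluded because it carries no structural information.
Groups within `tie_epsilon` (0.01) of the maximal similarity are returned
together as the opted set.

## Tie breaking

If several groups tie, each surviving group receives a probability
proportional to f(G) = Σ peaks explainable by G, weighted by tanh(β·I_p) —
the same indicator-style score, without the size penalty, normalized over
the surviving groups (a uniform posterior if nothing matches). The penalty
is omitted from f deliberately: f asks only how much of the data each
hypothesis can explain. Normalizing over the *tied* groups rather than all
2^n − 1 subsets matters, because without the penalty every superset of a
good group explains at least as much, and a posterior over all subsets
could never concentrate.

The *distinguishing power value* of a candidate precursor p is the expected
information gain of scanning it:

  DPv(p) = H(posterior) − Σ_i P(G_i) · H(posterior after the scan G_i would produce),

where the hypothetical scan under "G_i is true" is G_i's theoretical
product spectrum at p, taken at a flat 50% relative intensity since
theoretical intensities are unknown. DPv is clamped at zero, is exactly
zero when all groups predict identical product spectra, and peaks below
200 m/z are excluded from recommendation (small terminal fragments shared
by all candidates). The full DPv-ranked list is returned, not just the
best peak: in practice the top precursor can fail experimentally (weak
ions, uninformative fragmentation), and the operator or the loop then
falls back to the next one.

A session (`run_session()`) terminates when a single group survives the
similarity ranking, when one surviving group's posterior clears
`prob_threshold` (default 0.9 — the acceptance threshold on a probability,
chosen conservatively), when no informative precursor remains
(`exhausted`), or — in interactive mode — by emitting the recommendation
(`tied`). Each iteration consumes one precursor from a finite peak list,
so the loop always terminates.

## The synthetic-data generator

`mixture_spec()` + `simulate_spectra_tree()` emulate the MALDI workflow on
a known mixture: a peak at every theoretical fragment m/z of every
component, intensities proportional to molar ratio times a lognormal draw
(sdlog 0.5 — positive, heavy-tailed, a realistic spread for ion yields),
summed across components at shared m/z; spurious peaks as a Poisson process
of 2 peaks per 100 Th, capped at 8% relative intensity so acquisition is
not driven by noise (a stress mode lifts the cap); and MS3 scans for every
MS2 peak above the 10% threshold. Everything is deterministic given the
seed, and `virtual_instrument()` turns a mixture into the scan provider
that `run_session()` calls for tie-breaking scans.

What the generator does *not* emulate: fragmentation efficiencies and
linkage-dependent ion yields (intensities are phenomenological), isotope
envelopes, adduct heterogeneity, and detector saturation. Passing
closed-loop tests therefore demonstrates that the inference machinery
recovers the truth *when the fragment model is correct*, not that the
fragment model captures every feature of real spectra.

## Numerical and design choices

* Tolerances: 0.5 Da for peak and precursor matching (configurable); m/z
  keys are rounded to 4 decimals; centroids closer than 0.01 Da are merged
  (intensity-weighted).
* Degenerate inputs: empty compositions have a defined native mass (water)
  but no permethylated ion; an empty match set gives similarity −αn; an
  all-zero f gives a uniform posterior; a precursor matching no fragment
  yields an empty theoretical MS3.
* Ties: equal-distance peak matches go to the lower theoretical m/z; equal
  similarities are kept together (tie set); equal DPv ranks by intensity.
* The candidate cap (12, i.e. 4095 groups) guards the exponential
  enumeration; beyond it the user is asked to pre-filter (in practice the
  branching-pattern collapse keeps n small).
* Problem sizes in the shipped tests: families of up to 8 database isomers
  (3 patterns, 7 groups), spectra trees with up to ~30 MS3 scans, 6
  noiseless and 20 noisy closed-loop recovery sessions — sizes chosen to
  mirror the standard-mixture experiments while keeping a full check run
  in minutes.

## Known limitations

* Branching patterns only: linkage isomers (e.g. LNDFH-I vs LNDFH-II
  differing only in linkage positions) are indistinguishable by design.
* The probability function f is an internally consistent reconstruction
  (indicator sum with tanh weighting, normalized over tied groups); other
  weightings would change DPv magnitudes, though rarely the ranking.
* No abundance estimation: the method reports which components are
  present, not their ratios.
* Singly sodiated ions are assumed throughout; no deisotoping or charge
  deconvolution is performed on input spectra.
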