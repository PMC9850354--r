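# gipsmix

Identification of the isomeric glycan components of a mixture from
multistage mass spectra (MALDI-MSⁿ of permethylated, sodiated glycans),
using a group-opting strategy.

## The problem and the approach

A glycan sample usually contains several isomers under a single molecular
ion, and the MS² spectrum of such a mixture is the superposition of its
components' spectra — naming one best-matching structure is the wrong
question. `gipsmix` instead asks which **set** of candidate structures is
present:

1. **Candidates.** From the MS¹ molecular ion (MNa⁺ of the permethylated
   glycan), all structures at that mass are pulled from a local sequence
   database and collapsed to *branching patterns* (rooted trees of
   monosaccharide classes; linkage positions ignored) by tree isomorphism.
2. **Grouping.** All `2^n − 1` non-empty subsets of the n patterns are
   enumerated as candidate groups; the theoretical spectrum of a group is
   the union of its members' simulated glycosidic-cleavage spectra (single
   and double cleavage; B/C ions and reducing-end pieces with cleavage
   scars).
3. **Opting.** Each group G with n members is scored against the whole
   spectra tree S (MS² and every MS³, equal weights):

       similarity(G, S) = Σ_spectra Σ_{matched peaks p} tanh(β·I_p) − α·n

   with I_p the relative intensity in percent, β = 0.2 and α = 1. The tanh
   rewards peak *presence* over raw intensity; the −α·n term prefers the
   fewest components that explain the data. The top group(s) within a tie
   margin are opted in.
4. **Tie breaking.** If several groups tie, each gets a posterior
   probability from an indicator score (how much matched intensity the
   group can explain), and every acquired fragment ion gets a
   *distinguishing power value* — the expected drop in posterior entropy
   if that ion were fragmented further. The highest-DPv ion is recommended
   as the next MS³ precursor; with a scan provider (a virtual instrument,
   or scripted acquisitions) the loop runs until one group clears the
   probability threshold.

A synthetic-spectra generator doubles as the virtual instrument, so the
whole closed loop is testable offline.

## Worked example

A 1:1 mixture of two difucosylated hexaoses — LNDFH-I (Lewis-b type) and
LNnDFH-II (Lewis-x type), both dHex₂·Hex₃·HexNAc₁:

```r
library(gipsmix)

permethylated_mz(glycan_composition(dHex = 2, Hex = 3, HexNAc = 1))
#> [1] 1274.636     # the MNa+ label "1274" seen in MS1

db <- gips_db("standards")
lewis_b <- parse_glycan("Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc")
lewis_x <- parse_glycan("Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc")

mix  <- mixture_spec(list(lewis_b, lewis_x), ratios = c(1, 1), seed = 7)
tree <- simulate_spectra_tree(mix)          # MS1, MS2, MS3s of peaks >10%
sess <- run_session(tree, db, instrument = virtual_instrument(mix))
sess
#> <gips_session> status: resolved
#>   candidates: 8 (3 branching patterns)
#>   opted {g1,g3}  similarity 277.2124
#>   max posterior: 1.000

df <- score_report(sess$scores)[, 1:3]
df[order(-df$similarity), ]
#>       group n similarity
#>     {g1,g3} 2  277.21236
#>  {g1,g2,g3} 3  277.14286
#>     {g1,g2} 2  238.26912
#>     {g2,g3} 2  198.21971
#>        {g1} 1  197.91961
#>        {g3} 1  189.28983
#>        {g2} 1   79.34886
```

The 8 database isomers at m/z 1274 collapse to 3 branching patterns (g1 =
Lewis-b type, g2 = blood-group-H + core fucose, g3 = Lewis-x type). The
pair {g1,g3} — the true composition — beats every other group: the full
triple {g1,g2,g3} explains essentially the same peaks and pays the extra
group-size penalty, and each singleton leaves the other component's peaks
unexplained. The diagnostic chemistry is visible in the simulated MS³ of
m/z 660 (the Fuc·Hex·HexNAc B ion):

```r
head(round(theo_mz(theoretical_ms3(lewis_x, 660.32)), 2))
#> [1] 211.09 229.11 241.11 254.10 259.12 442.21
```

The 241.11/259.12 B/C pair of an unsubstituted terminal galactose appears
for the Lewis-x pattern only — the Lewis-b isomer has no unscarred
Fuc·Hex·HexNAc fragment at 660 at all — which is what lets a single MS³
scan separate the tied groups.

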