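---
title: "Natural-product-likeness scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural-product-likeness scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nplikeness)
library(dplyr)
```

## The scoring model

Natural products — small molecules made by living organisms — occupy a
characteristic region of chemical space: compared with typical synthetic
screening compounds they are richer in sp3 carbons, oxygen and fused
saturated ring systems, and poorer in halogens and flat heteroaromatics.
NP-likeness condenses this contrast into one interpretable number per
molecule.

Every heavy atom of a molecule is described by a *circular atom signature*:
a canonical string for the subgraph of all atoms within a fixed number of
bonds (the *height*) of that atom. For a fragment $i$ with document
frequencies $NP_i$ and $SM_i$ — the numbers of molecules in the
natural-product and synthetic training corpora that contain it at least
once — and corpus sizes $NP_t$ and $SM_t$, the fragment contribution is the
log-ratio of relative document frequencies

$$ f_i \;=\; \ln\!\left(\frac{NP_i + \alpha}{SM_i + \alpha}\cdot
   \frac{SM_t}{NP_t}\right), $$

and a query molecule with $N$ heavy atoms (hence $N$ signatures, duplicates
scored per occurrence) receives

$$ \mathrm{NP\text{-}likeness} \;=\; \frac{1}{N}\sum_{i=1}^{N} f_i . $$

Positive scores mean natural-product-like, negative synthetic-like. The
normalisation by $N$ keeps large molecules from accumulating score simply
by having more atoms; a molecule and its disjoint duplicate score
identically. Because the score is a sum of per-fragment terms it stays
fully interpretable: `top_fragments()` ranks the vocabulary by $f_i$ and
`decode_signature()` rebuilds each fragment's structure, which is what
makes the score usable for fragment-based design and not just ranking.

A deliberately linear model is used; no non-linear discriminant is fitted.
Scores are not clipped: the often-quoted range of roughly $-3$ to $+3$ is
an empirical property of typical corpora, not a bound.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `height` | 2 bonds | radius of the atom environment; 2 captures substituent patterns without memorising whole scaffolds |
| `alpha` | 1 | pseudo-count added to $NP_i$ and $SM_i$ |
| `min_fragment_atoms` | 6 heavy atoms | smallest disconnected fragment kept in curation |
| `allowed_elements` | C,H,N,O,P,S,F,Cl,Br,I,As,Se,B | the non-metal whitelist |
| `remove_sugars` | TRUE | strip glycosidically bound sugars before signing |

The literal frequency ratio ($\alpha = 0$) is undefined for a fragment seen
in only one corpus ($\ln 0$ or division by zero). The pseudo-count bounds
those contributions at roughly $\pm\ln(\mathrm{corpus\ size})$, vanishes
relative to real counts as corpora grow, and gives an unseen fragment a
score of exactly 0 when the corpora are equally sized. Set `alpha = 0` to
recover the literal ratio on fully covered vocabularies; the scorer then
raises an error rather than returning an infinity. The natural logarithm is
used throughout; the base only rescales scores and cannot change a ranking.

## Canonical atom signatures

The height-$h$ environment of an atom is the induced subgraph on all atoms
within graph distance $h$, rooted at that atom. Atom labels carry element,
formal charge, implicit-hydrogen count and an aromaticity flag; bond labels
carry order (`-`, `=`, `#`) or aromaticity (`:`). Stereochemistry and
isotopes are ignored — the descriptor is topological.

Canonicalisation works by colour refinement with individualisation on the
rooted environment graph: vertices are iteratively partitioned by (label,
multiset of labelled neighbour colours); while classes remain ambiguous,
each candidate vertex of the first non-singleton class is individualised in
turn and the lexicographically smallest serialisation wins. Two atoms
therefore receive the same text exactly when their rooted environments are
isomorphic, and the text cannot depend on the input atom order. The
serialisation is a depth-first spanning tree with numbered ring closures
(grammar in `?atom_signature`), so `decode_signature()` can parse any
signature back into its environment graph and re-encoding reproduces the
text byte for byte. The environment extraction and canonical search run in
C++; environments at height 2 are small (usually under 20 atoms), and the
refinement partition is almost always discrete after one or two rounds, so
the worst-case exponential branching is never reached in practice on
molecular graphs.

Signatures produced by different toolkits are not byte-compatible — each
canonicalizer defines its own string — so corpora and queries must be
signed by the same implementation. Equivalence across implementations holds
at the level of the partition into identical-environment classes.

### Aromaticity and implicit hydrogens

Aromaticity is perceived in-package with a single Hückel-style model:
5- and 6-membered rings of sp2-capable atoms (C, N, O, S, Se) whose
π-electron count is 6, iterated so a ring that only aromatises next to an
already-aromatic fused neighbour is still found. Exocyclic double bonds
contribute no electrons (quinones stay non-aromatic); ring heteroatoms with
only single bonds contribute a lone pair. The point of fixing one model in
the package rather than trusting the input file is consistency: training
corpora and queries are always described identically, which matters more
than any particular aromaticity convention.

Hydrogens are implicit everywhere. Counts are filled from charge-adjusted
default valences (S/Se may be 2/4/6, P/As 3/5); explicit hydrogens in input
files are folded into the counts on read. Kekulé (alternating-bond) input
is the reliable dialect: for SDF files that use the nonstandard aromatic
bond order 4, hydrogen counts on π-donor ring heteroatoms (e.g. a
pyrrole-type NH) can come out low, so such files are better supplied
kekulized.

## Curation

Standardisation before signing, in a fixed order:

1. **Connectivity**: connected components with fewer than
   `min_fragment_atoms` heavy atoms (counter-ions, solvent) are deleted.
2. **Element whitelist**: any remaining atom outside the non-metal list
   discards the whole record (`metal_element`). Running this *after* the
   component filter means a removable metal counter-ion does not doom an
   organic parent.
3. **Deglycosylation**: see below; a record that is entirely sugar is
   discarded as `empty_after_curation`.
4. Kept material is split into connected fragments that share the parent's
   UUID, so the scorer can pool them back into one molecule.

Atom counts are heavy-atom counts throughout. The cutoff is applied again
after sugar removal, so a stub left behind by a stripped glycoside does not
survive as a six-atom-rule violation.

### What counts as a sugar

No universal structural definition of "sugar" exists, so the package fixes
one. A *ring sugar* is a 5- or 6-membered ring with exactly one ring
oxygen, carbons elsewhere, no C=C bond inside the ring, and at least
(ring size − 3) ring carbons bearing an exocyclic single-bonded oxygen —
this captures furanoses and pyranoses while excluding THF/pyran ethers. A
*linear sugar* is an acyclic chain of ≥ 3 contiguous sp3 carbons, each
bearing exactly one single-bonded oxygen, none in a ring — open-chain
saccharide fragments, but not isolated diols. A sugar *unit* is the
detected core plus its oxygen substituents and terminal hydroxymethyl arms
(glucose C6–O6).

A unit is removed when all of its links to the rest of the molecule run
through its oxygens — the glycosidic C–O pattern; the bridging oxygen is
deleted with the sugar, leaving a clean aglycone. C–C-linked (C-glycosidic)
sugars are deliberately kept. Removal iterates outside-in, so
oligosaccharide chains strip completely, and a sugar bridging two scaffolds
splits the molecule into fragments that keep the parent UUID.

## The fixture generator

Real training corpora (natural products from the literature, lead-like
synthetic vendor compounds) are large downloads; the package instead ships
a seeded generator that reproduces the *structural contrast* the scorer
exploits. NP-like molecules are assembled from saturated mono-, fused- and
bridged-ring blocks and short branched chains, decorated mostly with
hydroxyl/methoxy/carboxyl groups; a configurable fraction (default 0.3, a
typical glycosylation rate in natural-product collections) carries a
pyranose on a glycosidic bond. Synthetic-like molecules are flat
(hetero)aromatics joined by amide, sulfonamide, ether or ketone linkers,
decorated with halogens, nitro, cyano and methoxy groups; defaults of 15%
counter-ion and 5% iron-containing records exist purely to exercise the
curation filters. Corpus sizes default to 200 per class — large enough for
stable document frequencies over the block vocabulary, small enough that
the full pipeline runs in seconds. All assembly is valence-checked, fully
deterministic given the config, and template-based rather than learned, so
every generated structure is inspectable.

What the generator does **not** emulate: the size and diversity of real
chemical space (a few dozen building blocks versus millions of scaffolds),
stereochemistry and tautomerism, realistic molecular-weight distributions,
and the substantial *overlap* between real NP and synthetic collections.
Separation measured on fixtures (AUC near 1) is therefore a correctness
check of the pipeline, not a performance claim about real libraries, where
the two distributions genuinely overlap and drug-like sets straddle both.

## Numerical choices

* Score files print six decimals; model files are versioned plain text
  storing counts, totals, height and `alpha`, so a model is
  self-describing.
* `top_fragments()` breaks score ties lexicographically on the signature
  text (radix order), making output identical across locales.
* Density plots use a Gaussian kernel with Silverman's bandwidth on a
  512-point grid spanning the data range ± 3 bandwidths; a degenerate set
  of identical scores is drawn as a narrow spike rather than an error.
* Fragment scores are computed as grouped differences of logarithms, so
  swapping the two corpora negates every score *bitwise*, and identical
  corpora give exact zeros — properties the test suite asserts literally.
* UUIDs are RFC-4122 v4 from R's RNG; `uuid_seed` derives them
  deterministically from seed + record index for reproducible pipelines.

## Problem sizes and verification

The test suite builds everything it needs from the generator at run time:
round trips over 50–100 molecules, canonical invariance over 50 molecules ×
20 random atom permutations, signature/atom count conservation over 200
molecules, an exhaustive rooted-isomorphism oracle on molecules of ≤ 12
atoms, and a train-200/score-100-per-class discrimination check (seed 42).
`scripts/acceptance.R` re-runs the train/score pipeline at the same scale
and reports the separation AUC, per-class mean scores, the identical-corpora
null check and count conservation.

## Known limitations

* Aromatic-bond-order (4) SDF input can under-count hydrogens on π-donor
  ring heteroatoms; supply kekulized input.
* No tautomer canonicalisation, salt dictionaries or charge neutralisation:
  two tautomers of one molecule can score differently.
* The sugar definitions are heuristic; exotic sugars (keto sugars, amino
  sugars with N-glycosidic bonds, C-glycosides) are intentionally or
  incidentally kept.
* Signature files are portable only among users of this package; other
  toolkits' signature strings differ byte-wise.
* V3000 SDF is rejected, not parsed.
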