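---
title: "Methods: alignment-free phage phylogenomics, lifestyle prediction and annotation comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-free phage phylogenomics, lifestyle prediction and annotation comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetools)
```

phagetools bundles four analyses that recur in phage genomics — whole-genome
phylogeny without alignment, static tree visualization with tip metadata,
temperate/lytic lifestyle classification, and reconciliation of genome
annotations from different pipelines — as composable tibble-in/tibble-out
functions plus a small command-line wrapper. This vignette explains the
models and procedures, the parameters that matter, the numerical choices,
and what the built-in simulators do and do not establish.

## Alignment-free phylogeny from feature-frequency profiles

A genome of length $L$ contains $L - k + 1$ overlapping windows of length
$k$; the $m = 4^k$ possible $k$-mers form the feature space. The count
vector $C_k = \langle C_{k,1}, \dots, C_{k,m} \rangle$ is normalized by its
total to a *feature-frequency profile* $F_k$, a probability distribution
over $k$-mers. Pairwise genome distances are Jensen–Shannon divergences

$$
\mathrm{JS}(P, Q) = H\!\left(\tfrac{P+Q}{2}\right) - \tfrac{1}{2}H(P) - \tfrac{1}{2}H(Q),
$$

with entropies in log base 2 so that $\mathrm{JS} \in [0, 1]$: 0 exactly
when the profiles coincide, 1 exactly when their supports are disjoint.
The resulting distance matrix is clustered with the Saitou–Nei
neighbor-joining algorithm into an unrooted tree.

Choices a user should know about:

* **Base 2 for the entropies.** Bounds every distance to $[0,1]$ and makes
  "1" interpretable as complete $k$-mer turnover. The divergence is used
  directly as the distance (no square-root transform).
* **Single-strand counting.** The profile is defined over the literal
  character sequence. A `canonical = TRUE` toggle collapses each $k$-mer
  with its reverse complement for assemblies with arbitrary strand
  orientation; it is off by default.
* **Windows containing `N` are skipped**, not counted into a pseudo-feature;
  the total reflects only counted windows. On ingest all non-ACGTN IUPAC
  codes become `N` (a strict mode rejects them instead).
* **Choice of k.** `choose_k()` uses `round(log4(median genome length))`
  clamped to $[6, 14]$ — the scale at which the feature space is comparable
  to the number of windows per genome, so profiles are informative without
  being dominated by sampling zeros. For 20–60 kb phage genomes this gives
  $k = 7$–8. An explicit override in $[1, 16]$ is accepted. Note that $k$
  near $\log_4 L$ maximizes resolution per feature but also sampling noise;
  for very diverged inputs a smaller $k$ (6) is often more stable.
* **Neighbor joining.** Implemented from the standard Q-criterion with two
  determinism conventions: ties in Q within $10^{-12}$ are resolved toward
  the smallest $(i, j)$ index pair, and negative branch lengths are clamped
  to zero. For an additive input matrix the generating tree is recovered
  exactly (the test suite checks patristic distances to $10^{-9}$ and
  topology on 100 random trees of 4–16 taxa).
* **MinHash alternative.** `minhash_sketch()` / `minhash_jaccard_distance()`
  provide a bottom-$s$ sketch estimate of the Jaccard distance over distinct
  $k$-mers, using a fixed multiplicative hash
  $h(x) = (1048573\,x + 12345) \bmod (2^{31}-1)$ over base-4 $k$-mer codes
  (exact in double arithmetic for $k \le 16$). This path exists as a
  documented alternative estimator; the default pipeline uses full profiles
  with Jensen–Shannon divergence, which is what the distance matrix and the
  trees in this package are built from.

### What the genome simulator emulates

`evolve_genomes()` draws a uniform random root genome and evolves it along a
given tree under a Jukes–Cantor-style process: on a branch of length $p$
each site independently substitutes to one of the three other bases with
probability $p$. Branch lengths are therefore per-site substitution
probabilities and must stay below the saturation ceiling 0.75; no indels or
rearrangements are simulated by default.

`sim_phage_tree()` generates the tree for recovery experiments: a random
topology with edge lengths uniform on $[0.3, 1]$, rescaled so the deepest
root-to-tip path has substitution probability 0.2. Two properties motivate
these defaults, chosen once for the study conditions the package tests
itself under. First, the path bound: after a root-to-tip divergence of $p$,
the probability that a $k$-mer window is unchanged is roughly $(1-p)^k$, so
path probabilities much beyond 0.2–0.3 at $k = 7$ leave few shared features
and the distance matrix saturates — no distance method can recover deep
structure from saturated profiles, and in our own experiments drawing every
*edge* (rather than every path) up to 0.2 drops 12-tip recovery to roughly
a quarter of replicates at every $k$ from 4 to 8. Second, the relative
lower bound 0.3 keeps every internal edge supported by hundreds of
substitutions at 20 kb, so no split in the generating tree is statistically
invisible. Under these conditions the default pipeline recovers the
generating 12-tip topology in at least 18 of 20 seeded replicates
(20 kb genomes), which the acceptance checks recompute.

The simulator does **not** emulate real phage genome architecture: no
mosaicism, recombination, gene gain/loss, or compositional bias. Passing
recovery tests therefore shows the estimator chain (counting →
normalization → divergence → neighbor joining) is implemented correctly and
is consistent under its own generative model — not that the method resolves
any particular real phage clade.

## Tree toolkit

Newick (including `.tre`) and NEXUS files are read and written through ape,
behind wrappers that add what the wrappers need: a balance check that
reports the character position of a parenthesis error, single-quoted label
support on both read and write (labels containing spaces or punctuation
survive round trips), and 12-significant-digit branch lengths so ten
consecutive round trips do not drift.

`annotate_tips()` joins a metadata table to tip labels by exact string
match; unmatched tips are listed, never dropped, and metadata rows without
a tip are ignored. `layout_tree()` computes four static layouts:

* *phylogram* — tips at consecutive integer y, x = root-to-node path length;
* *cladogram* — x = depth in edges, branch lengths ignored;
* *fan* — tips at equal angles ($2\pi/n$), radius = path length, arc edges;
* *radial* — equal angles, radius = edge depth, straight edges.

A "tidy" layout is deliberately not offered: there is no citable definition
of it in the tree-drawing stacks this renderer follows, so the name is
rejected with the list of supported layouts rather than guessed at.
Unrooted trees with branch lengths are midpoint-rooted *for display only*;
serialized output keeps the tree as built. `render_svg()` emits
deterministic standalone SVG 1.1 — one path per edge, one circle per tip, a
legend when coloring by a metadata column — with a fixed 12-color palette
assigned by sorted category name, so identical inputs give byte-identical
files.

## Lifestyle prediction

The classifier follows the domain-presence paradigm: temperate phages carry
recognizable lysogeny machinery (integrases, excisionases, repressors),
so a binary vector of domain presence/absence over a fixed, ordered domain
collection is an effective feature representation.

1. **Six-frame translation.** Each genome is translated in all six frames
   with genetic code table 11 (bacterial/phage; the appropriate table for
   phage ORFs). Each frame's translation is split at stop codons and the
   maximal stop-free fragments of at least `min_aa = 40` residues are kept —
   fragments, not ATG-initiated ORFs, because domain hits do not require a
   correctly called start, and the 40-residue floor removes the noise
   fragments shorter than any domain of interest. Codons containing `N`
   translate to `X`, which is allowed inside a fragment. The first codon of
   a frame is never treated as an initiator.
2. **Domain scanning.** Two interchangeable backends satisfy one contract
   (bit $d$ = 1 iff any fragment matches domain $d$): a profile-HMM backend
   that shells out to `hmmsearch` with a full-sequence E-value cutoff
   (default $10^{-5}$, configurable — a conventional stringency for
   presence/absence calls), and an exact-motif backend used for hermetic
   testing, where a domain is an amino-acid substring. Feature vectors are
   ordered by the domain set, which carries an md5 fingerprint; models
   refuse feature matrices from a different domain set.
3. **Training.** The labeled data are split 60:40 (train:test) by seeded
   shuffle, `floor(0.6 n)` to training. A random forest is grid-searched
   over trees $\in \{100, 500, 1000\}$ and mtry rules
   $\{\sqrt{p}, \log_2 p\}$ with stratified 5-fold cross-validation, and
   the configuration with the **highest minimum fold accuracy** is selected
   — a worst-case criterion that penalizes configurations that are good on
   average but unstable across folds. Ties go to fewer trees (cheaper,
   less variance in prediction time), then to the sqrt rule. The selected
   configuration is refitted on all provided training data. The grid
   contents are this package's choice; the selection criterion is the
   worst-fold rule stated above.
4. **Prediction.** Class probabilities are the forest's vote fractions;
   `p_lytic + p_temperate = 1` by construction. The exported probability
   table prints three decimals (a full-precision flag exists).

The shipped package trains from scratch on user data or simulated
fixtures; it does not ship trained weights, a curated HMM collection, or
claims about any published benchmark.

### What the lifestyle simulator emulates

`implant_domains()` builds random background genomes and, per temperate
genome, inserts each of five synthetic 12-residue marker motifs
(reverse-translated with a fixed codon per residue) in frame +1 inside a
stop-flanked, stop-free window of ≥ 40 codons — so an implanted motif is
guaranteed to be recovered by translate-and-scan, and an unimplanted one is
effectively impossible to hit by chance ($20^{-12}$ per window). Implant
rates per class are configurable: rates 1/0 give a perfectly separable
dataset (held-out error must be 0); rates 0.8/0.1 give an overlap regime
where held-out accuracy ≥ 0.9 is expected; shuffled labels give a
permutation null whose CV accuracy must sit near 0.5. These recoveries test
the pipeline's correctness, not biological generalization: real domain
architectures are position-diffuse, partially shared between classes, and
detected by remote homology rather than exact match.

## Annotation comparison

Pharokka-style GFF3, PHASTER-style region-detail text, and RAST-style
tab-separated exports are parsed into a common record shape (1-based
inclusive coordinates, strand, product; RAST start/stop are re-oriented so
start ≤ end; `complement(a..b)` means the minus strand). Records from 2–3
tools are grouped into features:

* **tolerance 0 (default):** exact `(start, end, strand)` identity — an
  equivalence relation, so grouping is unambiguous and transitive;
* **tolerance T > 0:** single-linkage over same-strand records whose starts
  and ends each differ by ≤ T. Single linkage is *not* transitive by
  construction — chains of near-misses merge — which is documented rather
  than hidden, because any fixed pairwise tolerance rule has this property.

Every record lands in exactly one group; a group is *common* when every
input tool contributes to it, *tool-only* when it is a singleton, *partial*
otherwise, and the per-tool identity (common + only + partial = total) is
checked property-style on random designs. Comparison tables carry one
product and one `start..end(strand)` column per tool, sort by location
(start ascending), length (descending, ties by start), or product, and
export to CSV/TSV. No consensus annotation is produced: the comparison is
coordinate-driven, and differing product strings never block a match.

When two pipelines' annotations count as "the same gene" is a genuine
modeling decision; exact coordinate identity was chosen as the default
because it is the only rule that is simultaneously unambiguous, symmetric
and transitive, with the tolerance mode available when near-miss boundaries
matter more than rule purity.

## Determinism, degenerate inputs, problem sizes

Every stochastic step (splits, folds, forest fits, simulators) takes an
explicit integer seed, and all generators are pure functions of
(configuration, seed); reruns are byte-identical, which the CLI tests
assert on whole output directories. Degenerate inputs are defined, not
accidental: a genome shorter than $k$ yields an empty profile (an error
only once frequencies are requested); a genome with no 40-residue fragment
gets an all-zero feature row; an all-zero vector predicts from the forest's
training balance; an empty comparison mode yields a header-only export.

The built-in verification runs at deliberately modest problem sizes — 12
taxa × 20 kb × 20 replicates for topology recovery, 200 genomes × 3 kb for
classifier recovery, 50 random annotation designs, 100 random trees and
FASTA sets for round trips — sizes at which the checked properties are
already sharp (exact recovery, zero error, exact count identity) while a
full run stays in the minutes range on one CPU.

## Known limitations

* Jensen–Shannon divergence is not additive on trees; neighbor joining on
  JSD matrices is a heuristic that degrades with divergence (see the
  saturation discussion above). Bootstrap support is not provided.
* The profile-HMM backend requires HMMER on the PATH and one profile per
  file; gathering thresholds are not read from the profiles.
* `.xls`-style RAST exports must be tab-separated text; binary spreadsheets
  are out of scope.
* SVG is the only first-class graphic format; PDF/JPEG conversions belong
  to external tools.
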