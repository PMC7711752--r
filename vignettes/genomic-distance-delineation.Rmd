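---
title: "Delineating species by k-mer genomic distances: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating species by k-mer genomic distances: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Given a collection of genome assemblies annotated with a taxonomic lineage
(species, genus, family, order, class, phylum), can a *fixed* genomic-distance
threshold decide whether two genomes belong to the same species? fungidist
implements the full pipeline behind that question: pairwise k-mer distances by
three methods, enumeration of genome pairs stratified by the most specific
taxonomic rank they share, and an equal-error-rate search for the threshold
separating adjacent rank strata, together with a clade simulator that provides
genomes with known divergence for validation.

```{r, eval = FALSE}
library(fungidist)
reg <- generate_registry(clade_config(seed = 1))
fit <- delineate(reg, methods = c("mash", "hll_similarity", "kmer_overlap"),
                 sketch_size = 10000, hll_p = 14)
fit
summary(fit)
```

## Distances

All three methods work on the set of distinct **canonical k-mers** of an
assembly: each k-bp window (windows with ambiguity codes skipped; windows
never spanning record boundaries) contributes the lexicographically smaller
of the k-mer and its reverse complement, which makes the set strand-invariant.

**Exact corrected overlap (`kmer_overlap`).** With k-mer sets $A$ and $B$,
the number of shared k-mers is compared with the overlap two *unrelated* sets
of the same sizes would show by chance. Under uniform sampling of the
$4^k$-element k-mer space the expected chance overlap is $|A||B|/4^k$
(the capture–recapture estimate), so the statistic is

$$ S = \frac{|A \cap B| - |A||B|/4^k}{\min(|A|,|B|)} . $$

$S$ is a similarity: about 1 for identical genomes (exactly $1 - |A|/4^k$ for
$A = B$), about 0 — possibly slightly negative — for unrelated genomes. It is
the exact, slow reference path; the sketch methods below are the practical
ones.

**MinHash / Mash (`mash`).** A genome is summarised by the $s$ smallest
distinct values of a seedable hash over its canonical k-mers. For two such
sketches the bottom-$\min(s, |A \cup B|)$ values of the merged lists form a
uniform sample of the union, and the fraction of them present in both
sketches is an unbiased estimate $\hat\jmath$ of the Jaccard index
$j = |A \cap B| / |A \cup B|$, with standard error about
$\sqrt{j(1-j)/s}$. The Poisson substitution model converts $j$ into a
per-site distance,

$$ D = -\frac{1}{k} \ln \frac{2j}{1+j}, $$

a proxy for $1 - \mathrm{ANI}$: a genome mutated at per-site rate $p$ keeps
each k-mer with probability $(1-p)^k \approx e^{-pk}$, which gives
$j = e^{-pk}/(2 - e^{-pk})$ and hence $D \approx p$. $j = 0$ is mapped to
$D = 1$ (a cap, not infinity) and values are capped at 1.

**HyperLogLog (`hll_similarity`).** Each genome's k-mer cardinality is
summarised in $2^p$ registers holding the maximal leading-zero rank of the
hashed k-mers routed to them; cardinalities are estimated with the classic
harmonic-mean estimator plus the small-range linear-counting correction
(no large-range correction is needed with a 64-bit hash). Registers of two
genomes combine by position-wise maximum into a sketch of the union, and
inclusion–exclusion yields a Jaccard similarity estimate
$\hat J = \max(0, (\hat C_A + \hat C_B - \hat C_{A\cup B})/\hat C_{A\cup B})$,
exactly 1 for identical sketches. The fancier maximum-likelihood HLL
estimators are deliberately out of scope; the relative error of the classic
estimator, about $1.04/\sqrt{2^p}$, is already far below the between-rank
signal at the default $p$.

### Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 16 | k-mer length (bases). A compromise: larger k resolves closely related genomes better, smaller k retains sensitivity for divergent ones. Thresholds shift with k, accuracy changes little across 12–22 (`threshold_k_sweep()`). |
| `sketch_size` (s) | 100000 | MinHash capacity. Large on purpose: Jaccard noise $\sqrt{j(1-j)/s}$ must stay below the species–genus gap even for divergent pairs. |
| `hll_p` | 20 | log2 register count; ~1M registers give ~0.1% cardinality error. |
| `hash_seed` | 42 | seed of the k-mer hash; sketches are comparable only at equal seeds. |
| `tolerance` | 1e-4 | equal-error stopping rule on the wrong-side share difference. |
| `max_iter` | 100 | bisection cap. |

## Rank strata and thresholds

Pairs are stratified by the most specific rank the two lineages share: the
species stratum holds within-species pairs; the genus stratum pairs of
*different species in the same genus*; the family stratum pairs of different
genera in the same family; and so on. The six strata partition all
complete-lineage pairs except those differing already at phylum. A record
missing the taxon needed for a decision is skipped for that stratum — pairs
with missing intermediate ranks are dropped rather than pooled, a documented
choice.

The **equal-error threshold** between two adjacent strata is found by
bisection on the interval between the two stratum medians: at each midpoint
the wrong-side shares (fraction of within-pairs above the cut, fraction of
between-pairs at or below it, for a distance; mirrored for a similarity) are
evaluated, and the half containing the stratum with the larger share is
kept, until the shares differ by less than `tolerance` or 100 iterations are
spent. Values exactly at the threshold count as correctly classified for the
lower (more similar) stratum; stating the tie rule makes the floating-point
behaviour reproducible. The search equalises the two error shares rather
than globally minimising the pooled error; at the equal-error point the two
notions coincide up to count granularity, and the pooled misclassification —
wrong pairs over all pairs — is reported as the headline number because it
stays well-defined when the search hits the iteration cap. Both per-stratum
shares are returned alongside.

The dataset conventions mirror genome-registry practice: species represented
by fewer than 3 genomes are dropped, species with more than 10 are randomly
downsampled to 10 (seeded), and an optional curation step removes
hybrid-named species (`" x "` or "hybrid" in the name), species named by a
strain code (`"Genus sp. CODE"`), and user-listed outlier genera/species,
with every removal written to an audit table. Hybrid and strain-name
detection is by explicit regular expressions, since registries do not flag
them consistently; the patterns are exported knobs, not magic.

## The clade simulator

`generate_registry()` grows a balanced taxon tree from one random root
genome: each new taxon at a rank is its parent's ancestor mutated at that
rank's per-branch divergence, and each genome is its species ancestor
mutated at the strain divergence. The default divergence profile
(strain 0.002, species 0.03, genus 0.08, family 0.12, order 0.16,
class 0.20, phylum 0.25 substitutions per site per branch) increases
strictly with rank, producing the layered distance structure the analysis
assumes. A truth table records the realised substitution load along the path
connecting every pair.

Two design points deserve emphasis:

* **Rate heterogeneity.** Real clades show within-rank distance spreads of
  orders of magnitude; a generator with deterministic branch lengths would
  make every threshold trivially perfect. Each branch therefore draws a
  lognormal rate multiplier (sdlog `rate_dispersion = 0.7`, mean 1)
  truncated to $[1/3, 3]$. The truncation keeps heterogeneity within an
  order of magnitude, so strata whose nominal divergences differ by more
  than ~9x (the default species vs strain profile) can never cross, while
  closely spaced profiles overlap substantially — the simulator reproduces
  both the clean species|genus separation and its breakdown when
  species-level divergence approaches within-species diversity (see the
  acceptance script, which measures both regimes).
* **Star-like, substitution-only branches.** Each child is mutated
  independently from its parent ancestor; no coalescent, no recombination,
  and indels default to 0 so closed-form k-mer survival checks hold exactly
  (an indel mode exists for robustness tests). The simulator also does not
  emulate repeats, ploidy, chromosome structure, GC heterogeneity or real
  nomenclature. Passing tests on simulated clades therefore validate the
  *pipeline arithmetic* — extraction, estimators, stratification, search —
  not the empirical claim that real taxa obey a single threshold.

`edge_cases = TRUE` appends three curation test cases to the first genus: a
hybrid-named species and a strain-code-named species sitting almost on top
of an existing species (as their real counterparts do — both are usually the
same biological species under a different label), and an overdispersed
species whose within-species divergence exceeds the species-level
divergence. These produce the expected direction of the curation effect:
removing them can only sharpen the species|genus boundary.

## Numerical choices

* Canonical k-mers are stored as 2-bit integer codes, exposed to R as
  doubles; codes are exact for $k \le 26$ ($2k \le 52 < 53$ mantissa bits),
  so the API accepts 1–26 and the pipeline 8–26, covering every k in common
  use (12–22). Code order equals lexicographic k-mer order, so sorted dumps
  come for free.
* The hash is a seedable splitmix64-style 64-bit mixer; MinHash keeps the
  top 53 bits so hash values are also exact doubles. Hash values are *not*
  bit-compatible with any external sketching tool — agreement is
  statistical, which is what thresholds rely on.
* HLL registers use the full 64-bit hash: $p$ top bits select the register,
  the leading-zero rank of the rest (bounded by $64-p+1$) fills it.
* Degenerate inputs: empty k-mer sets are legal (cardinality 0) but Jaccard
  and overlap statistics on them raise errors rather than returning NaN;
  `mash_distance(0, k)` returns the cap 1; identical stratum medians
  short-circuit the bisection at that value.
* Determinism: every stochastic step (genome simulation, mutation,
  downsampling) takes an explicit seed and restores the caller's RNG
  stream; sketching is deterministic given `hash_seed`.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
registries of 90–99 genomes of 50 kb (two phyla, five genera per family,
three species of three genomes), with `sketch_size = 10000` and
`hll_p = 14`; at these sizes the estimator noise is an order of magnitude
below the strata gaps, and a complete three-method run takes well under a
minute on one core. Estimator-accuracy checks use genomes up to 1 Mb.
Defaults for real assemblies remain `s = 100000`, `p = 20`.

## Limitations

* Thresholds are dataset-dependent: the pipeline recomputes them for any
  input, and values obtained on one genome collection do not transfer
  automatically to another.
* The sketch estimators lose accuracy as divergence grows (few shared
  k-mers); above total k-mer turnover the mash transform saturates at 1 and
  ranks become uninformative, which is why deep strata separate less well.
* Taxon names are compared as exact strings; synonym resolution and
  registry reconciliation are out of scope.
* The simulator validates arithmetic, not biology (see above); conclusions
  about real clades require real genomes.
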