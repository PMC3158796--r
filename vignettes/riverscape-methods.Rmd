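---
title: "Methods: whole-dataset comparison of aquatic metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-dataset comparison of aquatic metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverscape)
```

`riverscape` compares shotgun metagenomes as whole read datasets, without
assembly. This vignette is the package's account of the models and
procedures it implements, the parameters that matter, the numerical
choices made where conventions diverge, and what the synthetic-data tests
do and do not demonstrate about real data.

## The dataset-level distance model

The central statistic treats a metagenome as a bag of alignable sequence
and asks how much bit-score mass two datasets share. Reads of each dataset
are aligned all-vs-all (both directions and each dataset against itself)
and hits are filtered with strict thresholds — identity > 70% and alignment
length > 100 bp — so that only confident, informative local alignments
contribute. With `AA_s` and `BB_s` the total bit scores of the
self-comparisons and `AB_s` the symmetrized cross total, the Jaccard
distance is

$$D = 1 - \frac{AB_s}{AA_s + BB_s - AB_s}.$$

This is the canonical set-theoretic Jaccard form on bit-score mass, used as
the default; a Sørensen–Dice variant $1 - 2AB_s/(AA_s+BB_s)$ is available
via `form = "dice"` for sensitivity analysis. Three conventions had to be
fixed where practice varies:

* **Directionality.** Cross-comparison totals depend on which dataset is
  the query; `AB_s` is the average of both directions.
* **Self-hits.** A dataset aligned against itself includes each read's hit
  to itself; these are kept in `AA_s` by default (`include_self_hits`
  toggles this). Because they inflate both self totals equally, they push
  distances upward but preserve ordering.
* **Hit selection.** Totals sum the best hit per query by default;
  best-per-pair and all-HSP policies are available (`policy`), since
  aggregate scores from different BLAST-style tools differ in exactly this
  respect.

The distance is invariant under uniform positive rescaling of all bit
scores, so the choice of Karlin–Altschul parameters cannot change the
matrix, only the absolute totals. Property tests verify symmetry, zero
diagonal, range, scale invariance, and that the distance decreases
monotonically in the planted fraction of shared genomes.

Trees are built from the distance matrix by Saitou–Nei neighbor joining.
NJ is standard machinery, so the package delegates to `ape::nj()` and
clamps negative branch lengths (which arise on non-additive matrices) to
zero for presentation, as PHYLIP-style workflows do. On additive matrices
NJ recovers the generating topology and branch lengths exactly, which the
tests assert in closed form for 3 and 4 taxa.

## The internal aligner

Alignment is the workhorse, not the contribution, but the package carries
its own seed-and-extend nucleotide aligner so results are self-contained
and reproducible: exact k-mer seeding (default word size 11) on both
strands, merging of seeds on a common diagonal, and ungapped extension with
an X-drop of 20 score units under match +1 / mismatch −2 scoring. Raw
scores are converted to bits with $(\lambda S - \ln K)/\ln 2$ (defaults
$\lambda = 1.28$, $K = 0.46$) and e-values as $m\,n\,2^{-\text{bits}}$ over
the total subject length. One best HSP per (query, subject) pair is
reported by default, with an all-HSP mode for sensitivity checks.

Gapped extension is not implemented: the simulator introduces
substitutions only (see below), and for substitution-only divergence
ungapped extension recovers full-length alignments, keeping identity
accounting exact. The `gapopen` column is therefore always 0. Real 454
data contains homopolymer indels that this aligner would split into
multiple HSPs or truncate; for such data, hits from an external aligner
can be ingested via `read_tabular_hits()` (12-column BLAST tabular,
`outfmt 6` order), and all downstream stages operate on them unchanged.
Coordinates are 1-based inclusive with minus-strand hits encoded by
`sstart > send`, the tabular convention.

## The synthetic community model

The simulator defines the study conditions under which every stage is
validated:

* **Genomes** are i.i.d. base sequences with prescribed GC fraction;
  pairs of communities draw a controllable fraction of their genomes from
  a shared pool. Genome GC targets alternate between 45% and 65%, the two
  modes characteristic of freshwater datasets.
* **Reads** have lengths from a normal distribution with mean 325 bp
  (typical pyrosequencing read length) and sd 75, truncated below at 60 bp
  so every simulated read survives the standard <60 bp discard filter;
  sources are drawn by abundance, strands uniformly.
* **Errors** are i.i.d. substitutions at a configurable rate (0–20%).
  Homopolymer indels of real pyrosequencing are deliberately not modeled;
  this keeps percent identity an exact function of the planted error rate,
  at the cost of realism noted above.
* **Marker references** emulate an rRNA database: entries are mutated
  copies of per-collection seed markers (1200 bp), either carrying genus
  and higher-rank labels or annotated only as "uncultured bacterium", so
  identity-threshold classification has a known right answer.
* **Functional profiles** are multinomial draws over a shared category
  universe, with planted categories' proportions multiplied by a fold
  change on one side and renormalized.

Everything is bit-reproducible for a fixed seed; truth objects record each
read's source genome, coordinates and strand, the community's abundances,
and the planted sharing fraction.

What passing tests show: the implemented rules and statistics behave as
specified on data whose truth is known exactly. What they do not show:
robustness to chimeras, contamination, uneven quality, indel-rich error
profiles, or real database annotation noise — none of which the generator
emulates.

## GC profiling

GC% excludes `N` bases from numerator and denominator (textbook
definitions are silent on ambiguity codes; exclusion avoids biasing
low-quality reads toward 0). Histograms use half-open bins `[lo, hi)` with the last
bin closed. Mode detection smooths the binned counts with a Gaussian
kernel (sd 2 percentage points) and keeps local maxima whose prominence is
at least 5% of the global maximum; boundary bins get zero prominence,
suppressing edge artifacts. The defaults resolve modes ~20 points apart,
the separation seen between low- and high-GC freshwater populations; both
are configurable. At 10,000 reads the planted 45/65 mixture is recovered
within ±2 points (bin-midpoint resolution dominates the error).

The low/high split uses open intervals on both sides of 50% in its
figure-style definition, which leaves boundary reads unassigned; the
package needs a total partition, so reads at exactly the threshold go to
the low set. This is a stated convention, not derived from any source.

## Recruitment and overlap

Recruitment keeps hits at ≥95% identity over ≥50 bp — inclusive
thresholds, because the criteria are phrased as minima, unlike the
strictly-greater dataset-distance filters — then one best hit per read,
plotted at the subject-midpoint coordinate. Translated-search recruitment
modes are approximated, if desired, by lowering `min_identity` rather than
implementing protein-space alignment. Genome ranking counts best-hit
recruited reads per genome; whether historical server-based binning
counted all hits or best hits is not documented, so best-hit is used and
stated. The dataset-overlap fraction counts query reads with any hit at
>90% identity covering ≥50% of the read.

## Taxonomic classification

The rRNA rule ladder discards alignments ≤100 bp (strict, matching the
"longer than 100 bp" phrasing), then takes the best *named* hit — highest
bit score among references not annotated "uncultured"/"unidentified".
Identity >95% assigns that record's genus; 90–95% only its higher taxon;
<90%, uncultured-only matches, or no hits leave the read unidentified. Two
boundary cases are fixed by the strict readings of ">95%" and "<90%":
identity exactly 95 and exactly 90 both fall in the higher-taxon band.
"Best" is by bit score (the metric behind "best named hit" is otherwise
unspecified); property tests confirm the three bands are exhaustive and
exclusive over randomized identities.

Bulk-read binning takes the best bit-score hit passing e-value ≤ 1e-5 and
alignment ≥ 50 bp, with ties broken by ascending subject id for
determinism. On a 3-genome community at 1–2% error, ≥95% of classified
reads match their true source taxon.

## Enrichment statistics

Per category, a 2×2 table of category count versus the remainder of each
dataset is tested with the two-sided Fisher's exact test under the
sum-of-smaller-point-probabilities convention (the one STAMP-style tools
use; mid-p is not offered). The implementation delegates to R's
`fisher.test` and the test suite checks it against full hypergeometric
enumeration for every table with row margins up to 30.

Storey q-values estimate the null proportion at a single tuning point,
$\hat\pi_0 = \min(1, \#\{p > \lambda\}/((1-\lambda)m))$ with
$\lambda = 0.5$, rather than the spline-smoothed estimator — smaller,
deterministic, and exact to cross-check: with $\pi_0$ pinned to 1 the
procedure reduces to Benjamini–Hochberg, which the tests assert to
machine precision.

The significance filter is `q ≤ 0.05` AND `≥ 100 sequences` AND
`ratio > 2`. "100 sequences" is ambiguous between combined and
per-dataset counts; combined is the default and a `per_dataset` option is
provided. Proportion ratios involving a zero count use a 0.5 pseudocount
on the zero cell only, and such rows are flagged. Under the null (200
categories, totals 10⁴) the filter yields any false positive in well
under 10% of seeds; a 3-fold effect at expected count ~300 is recovered
in ≥90% of seeds.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → align → distance/tree → GC →
recruitment → classification → enrichment, writing every intermediate in
plain text (FASTA, 12-column hits, TSV, Newick) plus a manifest of
stages, parameters and timings. All stage thresholds live in a flat
key:value config with the defaults above; the same seed and config give
byte-identical outputs for every artifact except the manifest, whose
elapsed-time column is inherently run-dependent.

Default demo sizes — three datasets of 2000 reads from six 20 kb genomes —
run the full pipeline in well under a minute on one CPU; the validation
suite uses 80–400 reads per dataset for alignment-heavy properties and
10⁴-count profiles over 100 seeds for the error-rate simulations. These
sizes were chosen so each statistical check has enough resolution for its
assertion (e.g. mode error ≤ 2 points needs ~10⁴ reads; power ≥ 90% needs
expected counts ~300) while the whole suite stays fast enough to run
routinely.

## Known limitations

* Substitution-only error model; no homopolymer indels, chimeras or
  contamination.
* Ungapped extension only; indel-rich divergence needs an external
  aligner's hits.
* No translated (protein-space) search; no composition-adjusted or
  edge-corrected alignment statistics.
* No bootstrapping of the dataset tree.
* rRNA classification is a rule ladder over alignment identity, not
  phylogenetic placement; lowest-common-ancestor binning is out of scope.
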