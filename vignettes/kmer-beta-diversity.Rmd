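---
title: "Benchmarking k-mer spectrum beta-diversity on simulated metagenomes"
author: "kmerBeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking k-mer spectrum beta-diversity on simulated metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerBeta)
```

## The question the package answers

Reference-free ("de novo") comparative metagenomics replaces taxonomic
profiling with a bag-of-words view of a sample: the multiset of its DNA
words of length $k$ (the *k-mer spectrum*). Between two samples $a$ and $b$
one then computes the same beta-diversity dissimilarities ecologists use on
taxon tables, directly on k-mer counts $c_a(w)$:

* quantitative **Bray-Curtis**,
  $d_{BC} = 1 - \dfrac{2 \sum_w \min(c_a(w), c_b(w))}{N_a + N_b}$, where
  $N$ is a sample's total k-mer count (for normalized taxon profiles this
  equals half the $L_1$ distance);
* **presence/absence Jaccard**,
  $d_J = 1 - \lvert A \cap B \rvert / \lvert A \cup B \rvert$ over the
  distinct-k-mer sets.

How faithfully do these sequence-level distances track the *true*
community-level distances — and how is that fidelity affected by k-mer
length, sequencing depth and technology, contamination, community richness
and taxonomic breadth, MinHash sketching, and abundance filtering? Because
the truth is unknowable for real metagenomes, the package answers by
simulation: it generates communities whose composition is known exactly,
simulates reads from them, and correlates the k-mer distances with the
ground-truth taxonomic distances.

## The simulation model

**Genome pools.** A pool is the taxa universe of an experiment. In
`all_taxa` mode every genome is an independent uniform A/C/G/T sequence
(expected pairwise identity 25%), emulating unrelated species. The
reduced-diversity modes draw one ancestor and substitute each site
independently with probability `perSiteDivergence` — 0.15 for a same-class
pool, 0.05 for a same-family pool — giving genomes that share long exact
k-mers at short $k$ but diverge at long $k$, the mechanism behind the
taxonomic-diversity experiment. Genome *sizes* are heterogeneous by
default: per-genome lengths are log-uniform over $[0.3, 2] \times$ the
nominal length (1.5–10 Mb around the 5 Mb full-scale nominal), the span
typical of complete bacterial genomes. Size heterogeneity matters for the
headline contrast between the two metrics: because abundances are read
proportions, a taxon's share of the *total* k-mer count is independent of
its genome size (Bray-Curtis is unaffected), while its share of the
*distinct*-k-mer set is proportional to genome size — so the
presence/absence Jaccard distance weights taxa by size, scrambling its
ranks against the count-based taxonomic Jaccard. With equal-size genomes
the k-mer Jaccard would be an almost deterministic function of the
shared-taxon count and would correlate with taxonomy far better than any
real pool allows.

**Communities.** A sample draws `nTaxa` genomes uniformly without
replacement and gives them log-normal relative abundances (raw weights
$\mathrm{LN}(\mu, \sigma)$, normalized to sum 1). The distribution family
is standard for rank-abundance structure in microbial communities; since
no canonical parameter values exist for mock communities we fix
$\mu = 0, \sigma = 1$ (configurable), which spans roughly two orders of
magnitude of abundance across 25 taxa. Abundances are **read proportions**:
they parameterize the read simulator directly, so the expected taxonomic
profile equals the simulation parameters exactly and genome length does not
re-weight abundances. (The alternative — genome-copy weighting — would
fold genome length into the ground truth itself; keeping abundance as read
proportion leaves size acting only where it physically does, on the
distinct-k-mer sets.)

**Reads.** Paired-end fragments start uniformly on the linear genome, both
strands equally likely; R2 is the reverse complement end of the fragment
(insert length normal, default mean 350 bp / sd 30 bp for the HiSeq-like
preset). Sequencing error is a substitution-only model whose per-base
probability ramps linearly over the read, with platform presets
(miseq 2x300 bp, 0.1%→1%; hiseq 2x125 bp, 0.1%→0.5%; novaseq 2x150 bp,
0.05%→0.3%). This replaces KDE-trained quality models with a transparent
two-parameter family; it reproduces the feature that matters for k-mer
analysis — a realistic density of erroneous, mostly singleton k-mers
increasing toward read ends — while deliberately not modeling indels,
chimeras or GC bias. FASTQ qualities encode each cycle's substitution
probability as a Phred+33 score. Every read pair's source genome is
recorded in a truth table, from which the **realized profile** (the read
fractions actually emitted) is computed; it stands in for a read
classifier under the idealization of perfect classification.

**Contamination.** A spike replaces a fraction $f$ of a sample's reads
with a contaminant genome: a long host-like genome (default 500 kb at the
default scale, i.e. ten bacterial genome equivalents — many foreign
k-mers) or a PhiX-like 5,386 bp genome (few foreign k-mers, repeated at
high coverage).

**Scaling.** Full-scale conditions (5 Mb genomes, 50 K – 50 M read pairs)
are divided by a joint `scaleFactor` (default 100) on depth *and* genome
length. Per-taxon coverage — the quantity that drives depth saturation and
filter effects — is preserved: 200 K pairs on 50 kb genomes give the same
coverage regime as 20 M pairs on 5 Mb genomes. What scaling does *not*
preserve is the absolute k-mer space size, so distinct-k-mer counts and
collision rates at small $k$ are those of a proportionally smaller
metagenome.

## The k-mer machinery

Counting is canonical (a k-mer is identified with the lexicographic
minimum of itself and its reverse complement, making counts
strand-independent), streams over both mates, and skips any window
containing a non-ACGT base rather than randomizing it. $k$ is capped at 31
so a k-mer packs into a 64-bit word (2 bits per base, with A<C<G<T chosen
so numeric key order equals lexicographic string order); spectra are
sorted key/count vectors and all pair statistics are single merge passes.

`countKmers()` returns the **unfiltered** spectrum; filtering is an
explicit step (`filterSpectrum()`). The benchmark grids, however, apply a
minimum-abundance filter of 2 before distance computation
(`spectrumFilterMin`; Simka, the reference implementation of exact
k-mer-spectrum distances, ships the same default), which removes error
singletons but also the genuine k-mers
of taxa sequenced below ~2x coverage. The filtering experiment isolates
exactly this trade-off — its baseline is unfiltered and it shows that the
minimum-abundance filter *degrades* the agreement with taxonomic
distances, presence/absence Jaccard far more than Bray-Curtis.

**Sketching** is bottom-$s$ MinHash: every distinct canonical k-mer is
hashed with a seeded 64-bit mixing hash and the $s$ smallest hashes are
kept with their counts. Two sketches are compared on the merged bottom-$m$
window, $m = \min(s, \lvert \text{union} \rvert)$: the Jaccard estimate is
the shared fraction among the $m$ smallest union hashes (the classical
unbiased bottom-sketch estimator), and the Bray-Curtis estimate applies
the exact formula restricted to the k-mers inside that window (counts from
each sketch, absent = 0). The restriction-based Bray-Curtis is this
package's convention; when $s$ reaches the union size both estimators
degenerate to the exact distances, which the tests assert. Hash seeds are
recorded in the sketch so cross-sample comparability is checkable; a
64-bit hash collision between distinct k-mers aborts with an error rather
than silently merging counts (ties would otherwise be unresolvable).
Default $s$ = 100,000, past the point where larger sketches stop improving
the estimate in the sketching experiment.

## The evaluation harness

Distance matrices are compared pair-by-pair: the strictly-upper-triangle
vectors (samples sorted by label, row-major) feed a plain Spearman
correlation with average-rank ties — the agreement statistic reported
everywhere — plus median/mean/max absolute-difference summaries for
sketching and filtering costs. This is deliberately *not* a Mantel test:
the question is how well ranks agree, not whether association is
significant. Clustering support uses Ward-D2 linkage cut to the number of
true groups, scored by purity (each cluster labeled by its majority group;
purity = fraction of samples whose group matches). PERMANOVA is delegated
to `vegan::adonis2` (999 permutations, seeded, add-one p-value) and PCoA
to classical metric scaling via `stats::cmdscale`, with axes restricted to
positive eigenvalues; the tests cross-check the PERMANOVA pseudo-F against
a hand-written partitioning of squared distances with exhaustive label
permutations, and PCoA against planted configurations.

## The experiment runner

`experimentConfig()` + `runExperiment()` drive six designs: the technical
grid (depth x technology x k), contamination arms (clean, 0–2% host,
10–25% host, 0–2% PhiX), richness arms (5/25/50/100/500 taxa from pools of
10/40/80/130/530), taxonomic-diversity arms (all-taxa / same-class /
same-family pools), and the sketching and filtering sweeps at one fixed
depth. All randomness derives from one master seed through fixed-order
seed streams; read seeds depend on (sample, depth, technology) but not on
the contamination arm, so an arm with zero spiking reproduces the clean
run exactly — an identity the tests assert. Results are a tidy one-row-
per-condition table (Spearman rho against expected and realized profiles,
mean k-mer distance, absolute-difference summaries) plus all distance
matrices and a manifest from which the configuration can be rebuilt and
re-run to identical output.

```{r tiny-run}
cfg <- experimentConfig("simset1_technical", nSamples = 4,
                        genomeLengthBp = 2e5, depths = c(2e4, 2e5),
                        ks = c(11, 21), masterSeed = 7)
res <- runExperiment(cfg)
res$results[, c("depth", "pairs", "k", "metric", "rho", "meanKmerDist")]
```

Even at this toy scale the two headline phenomena are visible: agreement
improves with depth, and presence/absence Jaccard trails Bray-Curtis.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script use, as the package's own
scaled study conditions: the technical grid with 30 samples, a 40-genome
pool, depths 2K/20K/200K pairs and $k \in \{10,15,20,25,30\}$ (scale
factor 100 against the 200K–20M full-scale regime); 20-sample single-depth
arms (50 K pairs, 5M-pair equivalent) for the richness
(5/25/50/500 taxa), contamination ($k$ = 25) and filtering ($k$ = 30)
experiments; and a 15-sample pair set for sketching
($s \in \{10^2, 10^3, 10^4, 5 \cdot 10^4, 10^5\}$). Sample counts below
the full 100 keep pair counts proportionate while leaving the rank
correlations stable to a few hundredths.

Numerical conventions worth knowing:

* distances are computed in double precision from exact integer counts;
* profile comparisons align taxa on the union of supports (absent = 0);
* `upperTriangle()` fixes the pair order (label-sorted, row-major) so
  correlations are reproducible regardless of matrix construction order;
* the read simulator clamps a drawn fragment to the genome length, and a
  taxon whose genome is shorter than the mean insert is skipped with a
  warning and its mass renormalized;
* degenerate correlation inputs (zero variance in a distance vector) are
  an error at the operation level and an `NA` row in experiment tables;
* the simulator's RNG is a self-contained xoshiro256++ so identical seeds
  give byte-identical reads across platforms; R-side draws (pools,
  communities, multinomial read allocation) use R's RNG under fixed seeds
  and restore the caller's RNG state.

## What passing tests do and do not show

The generator reproduces the features that drive the phenomena under
study: shared k-mer mass proportional to shared taxon abundance, error
k-mers as mostly-singleton noise, contamination as foreign k-mer mass,
coverage as the depth-limiting resource. It does not reproduce real
genome phylogenetic structure (except through the ancestor-divergence
modes), repeat content, indels, strain-level variation, uneven coverage
biases, or classifier error in read-based profiles (realized profiles
assume perfect classification). Conclusions transfer to real data at the
level of mechanisms and rankings — e.g. *quantitative distances track
taxonomy far better than presence/absence ones*, *shallow depth inflates
distances toward 1*, *minimum-abundance filters hurt* — not at the level
of exact correlation values.

## Known limitations

* Spectra are held in memory (sorted key/count vectors); the counter is
  desk-scale by design, not a disk-partitioned billion-k-mer engine.
* $k \le 31$ (64-bit packing).
* The maximum-abundance filter is exposed (`filterSpectrum()`) but the
  config-driven experiment sweeps only the minimum-abundance grid, which
  is where the headline filtering result lives.
* Genome-size heterogeneity is log-uniform and independent of abundance;
  real communities can correlate the two, which would further modulate
  the presence/absence metrics.
* Real-data benchmarking (download, trimming, host-read removal, read
  classification) is out of scope; the package's realized profiles are a
  truth-table idealization of that pipeline.
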