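---
title: "Dating a gene pathway: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a gene pathway: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylage)
library(dplyr)
```

phylage estimates, for every gene in a pathway, the oldest clade in
which a related sequence is still detectable — its *phylostratum* — and
annotates the resulting age cohorts with selection and expression
statistics. This vignette explains the model behind each stage, the
parameters that matter, and the design decisions taken where the
procedure is genuinely open.

## The evolutionary frame

The timeline is a lineage-specific ladder of 20 phylostrata, from
cellular organisms (PS 1, the oldest) to the reference clade (PS 20).
Each stratum is represented by one or more extant *proxy species* whose
genome stands in for the ancestral lineage. The packaged 39-species
panel (26 non-vertebrate proxies for PS 1–10, 13 vertebrate proxies for
PS 11–20) mirrors the panel of the oxytocin-pathway study this package
grew from; stratum assignments for a handful of intermediate vertebrate
clades are only partially documented in public sources, so the packaged
panel is labelled synthetic and validated structurally instead: stratum
indices must form a contiguous range, every species must be a tree tip,
and strata must increase monotonically along the root-to-reference path
of the tree. Branch lengths are ignored throughout — the assignment
needs topology only.

Genes are binned into three age cohorts: *ancient* (PS 1–3), that is
cellular organisms through opisthokonta; *medium-aged* (PS 4–10),
holozoa through olfactores; and *modern* (PS 11–20), the vertebrate
strata. The cut points are study choices, not biology, so
`age_category()` exposes them as a `boundaries` argument with 3/10 as
the default.

## Homology from length-normalized BLAST scores

Protein-BLAST bit scores grow with alignment length, so a fixed score
threshold would systematically favor long proteins. The pipeline
therefore works on the *scaled max score*

$$s = \frac{\text{max score}}{L_{\text{subject}} + L_{\text{query}}},$$

the best-HSP bit score divided by the summed lengths of the two
proteins. For each non-vertebrate species the per-gene scaled scores of
all best hits are averaged, and that species-specific mean is the
cutoff: a gene's hit in the species counts as a putative homolog only
when its scaled score lies strictly *above* the cutoff. Three details
are deliberate:

* "Max score" is read as the bit score of the best HSP, matching the
  value that the NCBI web interface reports under that name.
* The comparison is strict (`>`), and the boundary case is tested: a
  score exactly at the cutoff is not a call.
* Only genes with at least one hit contribute to a species' cutoff;
  absent genes neither raise nor lower it. Ties in best-hit selection
  are broken by max score and then lexicographically by accession, so
  results are deterministic.

This cutoff construction works because best-hit scores are bimodal:
genuine homologs sit in a high mode, while chance hits sit in a low
mode, and the species mean lands between the two whenever both modes
are populated. The synthetic-data generator reproduces exactly this
structure (see below).

## Microsynteny confirmation in vertebrates

Sequence similarity alone cannot separate orthologs from paralogs. In
the vertebrate strata, where annotation quality permits, the pipeline
therefore requires *microsynteny*: the ten protein-coding genes
flanking the focal gene (five per side) must re-occur in the target
species. Windows are built over gene-level records only; pseudogenes
and RNA genes are skipped, not counted, and a window truncated at a
contig edge is flagged. Matching is case-insensitive, order- and
strand-insensitive, and an optional alias map handles cross-species
symbol drift; unmatched or uncharacterized flanks count as non-shared.
Where a genome carries the focal gene at several loci — the legacy of
the teleost whole-genome duplication — every locus is scored and the
best window kept.

The source procedure judged conservation visually; reproducibility
demands an explicit rule, so conservation is declared when at least
`threshold_k` of the ten flank genes re-occur, with `threshold_k = 3`
as the default, configurable and always carried into reports. A
vertebrate ortholog call then requires *both* a best hit and a
conserved window. In non-vertebrates no synteny is attempted (genome
assemblies there are too fragmented for stable neighborhoods), which is
why those calls are reported as homologs, not orthologs.

## Earliest-stratum assignment

A gene's age is the smallest stratum index among its positive calls.
The staged protocol mirrors the original search order: non-vertebrate
evidence only counts for genes that have an ortholog in one of the two
oldest vertebrate strata (the jawless- and jawed-vertebrate proxies);
genes without that anchor are dated from their vertebrate calls alone
and flagged `staged_stop`, because a staged search would never have
queried non-vertebrates for them. An exhaustive mode ignores the
stopping rule for sensitivity analysis; by construction it can only
ever date a gene the same or older, and a property test asserts exactly
that. Presence gaps do not block assignment — the earliest positive
call wins — and a gene with no positive call anywhere is returned as
explicitly unassigned rather than defaulted.

## Selection post-processing

Branch-site tests (of the adaptive branch-site random-effects
likelihood family) are consumed, never re-fit: the package reads
per-gene, per-branch raw P values, likelihood-ratio statistics and the
maximum dN/dS, from either a flat TSV or the JSON layout those tools
emit. Unfinished runs are flagged and excluded from every numerator and
denominator. Raw P values are corrected with the Benjamini–Hochberg
step-up procedure; the default family pools all gene-by-branch tests,
matching a correction applied to "all resulting raw P values", with
per-gene and per-branch scopes available for sensitivity. Some
branch-site tools already apply an internal correction across branches
within a gene; whether upstream values are raw or pre-corrected cannot
be detected from the file, so the choice of input is the caller's and
the scope is always recorded in the output.

For classification, the maximum dN/dS is transformed as
$t = \ln(1 + \omega)$, which maps neutrality ($\omega = 1$) to
$\ln 2 = 0.693147181$ — the neutral anchor used in the figure this
reproduces. Values below the anchor indicate purifying selection, above
it positive selection; a tolerance band of $10^{-9}$ defines "neutral",
since exact equality is measure-zero. The transform is monotone, so the
classification is too.

## Expression annotation

**Tissue enrichment.** Overlaps between a gene set and per-tissue
differentially-expressed-gene sets are scored with the upper-tail
hypergeometric probability against a background universe (canonically
all protein-coding genes), Bonferroni-corrected across the 30 tissues.
A property test checks the probability against exhaustive enumeration
for every background of at most 15 genes.

**Region-versus-whole-brain tests.** For a gene set and a parcellated
donor-by-region-by-gene matrix, the sampling unit is the per-donor
gene-set mean: each region yields one mean per donor (n = 6 in the
atlas data this models), tested against the grand mean over all
regions and donors with a two-sided one-sample t test, and corrected
across the 42 tested regions with Benjamini–Hochberg. The effect size
is Cohen's d for one-sample designs, $d = (\bar{x} - \mu_0)/s$, tied
to the statistic by $|d| = |t|/\sqrt{n}$. That identity is what pins
down the sampling unit: the published t/d pairs this package was
checked against satisfy $d = t/\sqrt{6}$ for eight of nine significant
regions. The ninth (the accumbens pair) violates the relation that all
others obey and its sign conflicts with the surrounding text; it is
treated as an inconsistency in the source and the implementation
follows the formula, not the outlier. Zero-variance samples leave the
statistic undefined and are flagged `degenerate` rather than
fabricated.

**Differential stability.** Expression reproducibility per gene is the
mean Pearson correlation of regional profiles over all donor pairs,
computed on jointly observed regions (at least 3 per pair). Pairs with
a constant profile are skipped and counted; genes with no usable pair
propagate as missing, mirroring upstream toolchains that report "no
data" for such genes. `top_fraction()` reports the share of a gene set
at or above the background's median stability, with exclusions counted
on both sides.

## The synthetic-data generators

Every stage is testable offline because generators produce inputs with
the exact statistical structure the stages assume, plus a truth table:

* **Homology**: each gene gets a planted stratum drawn with the
  study's per-stratum proportions (the published per-stratum counts of
  the 154-gene pathway). Species at or after the planted stratum yield
  best-hit scaled scores around 0.5, decaying linearly by 0.02 per
  stratum of distance; species before it yield, with probability 0.5,
  a weak chance hit around 0.08. Gaussian noise (s.d. 0.005, small
  relative to the decay step) perturbs both modes. The weak-hit mode is
  essential, not a nuisance: it is what places each species' mean
  cutoff between the two modes, exactly as in real score
  distributions. Annotation tables carry conserved flank symbols with
  probability 0.9 per flank where the gene exists and junk symbols
  otherwise, and the reference annotation plants a pseudogene inside
  every window so biotype exclusion is exercised on each run. Score
  decay is linear because the caller only assumes monotonicity; the
  generator documents rather than hides this choice.
* **Selection**: uniform-null raw P values with planted positives at
  or below $10^{-6}$ and dN/dS above 1.
* **Expression**: intensities are a baseline plus a shared
  donor-by-region fluctuation (s.d. 0.05 — the sampling unit of the
  region tests) plus per-gene noise (s.d. 0.10); planted regional
  effects are expressed directly in Cohen's d units of the
  donor-by-region s.d., so the planted value is the quantity the test
  stage estimates.

All generators are deterministic under a fixed seed, byte-identically
so for written files, and their outputs round-trip through the package
parsers.

What the generators deliberately do **not** emulate: real sequence
content (scores are simulated directly, since running the similarity
search itself is out of scope), assembly fragmentation and annotation
errors in old genomes, correlated noise across species induced by
shared phylogeny, and the spatial covariance of neighboring brain
regions. Passing recovery tests on synthetic data therefore
demonstrates that the *inference logic* is correct under the stated
model, not that the model captures every pathology of real data.

## Verification and problem sizes

The test suite checks, among others: the worked normalization example
(92.8 over 364 + 431 residues giving 0.1167296) and its rejection
against the 0.2098398 tunicate cutoff; reproduction of that cutoff
from the packaged per-gene score sheet; the 28/28/98
ancient/medium/modern split with 34 jawed-vertebrate genes in the
packaged 154-gene table; 17 of 38 genes significant in the packaged
branch-site table under the global Benjamini–Hochberg policy; the
neutral anchor to nine decimals; agreement of the correction with a
brute-force step-up oracle to $10^{-12}$ over 1,000 random vectors;
hypergeometric probabilities against exhaustive enumeration; t, p and
the d–t identity against closed forms to $10^{-9}$; recovery of at
least 90% of 200 planted strata under the default noise model (the
observed rate is typically 100%); and false-discovery control of the
region tests over 2,000 simulated null cohorts of 10 genes, whose
any-discovery rate must stay inside the 99% binomial band around the
nominal 5%. Planted expression effects of d = 3 with six donors are
assessed over 60 replicate cohorts — single-cohort power after
correction is only ≈ 55% at that effect size, so the test asserts the
replicate-level detection rate, the top-ranking of the shifted region,
and unbiasedness of the d estimate instead of a single draw.

A small worked example:

```{r example}
sim <- simulate_homology_data(sim_config(seed = 7, n_genes = 40))
dated <- date_genes(sim$hits, sim$annotations, sim$panel)
dated$summary
cmp <- inner_join(dated$records, sim$truth, by = "gene")
mean(cmp$earliest_ps == cmp$true_ps)
```

## Known limitations

* The synteny threshold `k = 3` is a declared parameter, not a
  recovered constant; the qualitative judgement it replaces cannot be
  reconstructed exactly, which is why the threshold is configurable
  and always reported.
* Cutoff-based homolog calling inherits the bimodality assumption; for
  a species whose hit list contains essentially only true homologs (or
  only chance hits) the mean cutoff degenerates towards the single
  mode and calls become conservative.
* Paralog/ortholog disambiguation in non-vertebrates is out of scope
  by design, as is inference of duplication events.
* The region tests treat donors as exchangeable replicates; demographic
  structure between donors is not modelled.
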