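---
title: "Estimating DNA sample contamination from hom-alt reference reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating DNA sample contamination from hom-alt reference reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charr)
```

## The model

At a site where a sample is truly homozygous for the alternate allele,
every sequenced read should carry that allele; reference reads observed
there can only come from sequencing error or from contaminating DNA. If a
fraction $c$ of the reads in a library originate from other individuals,
a contaminating read carries the reference allele with probability equal
to the reference-allele frequency $p$ of the contaminating population
(a random contaminant is hom-ref with probability $p^2$ and het with
probability $2p(1-p)$, contributing $p^2 + p(1-p) = p$). The expected
reference allele balance at a hom-alt site is therefore

$$E[\mathrm{AB}_{\mathrm{ref}}] \;=\; (1 - c)\cdot 0 + c\,p \;=\; c\,p ,$$

where $\mathrm{AB}_{\mathrm{ref}} = RR / (RR + AR)$, the reference-allele
read depth over the sum of reference and alternate allele depths. Dividing
by $p$ and averaging over the $m$ retained hom-alt sites of a sample gives
the estimator

$$\widehat{c} \;=\; \frac{1}{m} \sum_{j=1}^{m}
  \frac{RR_j}{p_j\,(AR_j + RR_j)} ,$$

computable from GT/AD alone — a VCF is sufficient; no BAM/CRAM access is
needed. The denominator uses $AR_j + RR_j$, not DP: DP may count reads
assigned to neither allele.

Treating each read at a hom-alt site as reference with probability $c p_j$
gives the per-sample log-likelihood

$$\ell(c) = \sum_j AR_j \log(1 - c\,p_j) + RR_j \log(c\,p_j),$$

maximized by `charrGridMLE()` over a grid (default $0$ to $0.1$ in steps
of $0.001$). When every $1 - c p_j \approx 1$ the maximizer is
approximately $\sum_j RR_j / \sum_j p_j (AR_j + RR_j)$, returned as the
closed form; the mean-per-site estimator tracks both closely at low
contamination (the suite checks a correlation of at least 0.99 across
simulated samples at $c \le 0.05$, and per-sample agreement of grid and
closed form to one grid step).

## Variant selection

Only sites where the hom-alt call is trustworthy and $p$ is informative
should contribute. `filterConfig()` defaults encode the recommended
operating point:

| parameter | default | why |
|---|---|---|
| `minGq` | 20 | below this, the hom-alt call itself is in doubt |
| `minDp`, `maxDp` | 20, 100 (inclusive) | low depth makes AB noisy; extreme depth marks artifacts |
| `minRefAf`, `maxRefAf` | 0.10, 0.90 (exclusive) | a site with tiny $p$ turns one noisy reference read into an enormous $RR/(p \cdot \mathrm{AD})$ term; the window should be symmetric and at least (0.05, 0.95) |
| `variantTypes` | `"snv"` | indels also work and are far fewer (a cheaper alternative), but SNVs are the default |
| `autosomesOnly` | `TRUE` | sex chromosomes violate the diploid model |
| `minSites` | 500 | below ~500 sites the mean is too noisy; the result is flagged, not suppressed |

Rejection reasons are assigned in a fixed precedence (non-autosomal,
multi-allelic, variant type, GQ, depth, genotype, AF missing, AF window)
so the audit report is deterministic and partitions the input exactly.
Multi-allelic records are marked and rejected rather than split: splitting
would require re-deriving AD. Sites with no allele-frequency entry are
rejected rather than given a default $p$, since a wrong $p$ biases the
estimate directly. Allele-frequency keys never match with REF/ALT
swapped, for the same reason. Depth bounds are inclusive and the AF window
exclusive, matching how the thresholds are stated; the estimator applies
no per-site winsorization — extreme terms are controlled only through the
AF window.

Choosing the allele-frequency source matters: the adjustment wants the
reference-allele frequency of the population the *contaminant* comes
from, which is unknown. Frequencies from a large external panel
(`readAlleleFrequencies(..., mode = "sites_table")`) are preferable when
the local callset is small; `mode = "info_af"` uses the callset's own
INFO/AF.

## The simulator

`simulateCohort()` / `runSimulationStudy()` generate cohorts with known
contamination at the genotype level:

1. site alternate-allele frequencies $q_j$ are i.i.d. Beta draws
   restricted to $[0.05, 0.95]$ by resampling (default shape $(1,1)$ —
   flat over the window — emulating the common-variant sites actually
   used for estimation; a U-shaped spectrum is available via the shape
   parameters);
2. truth genotypes follow Hardy–Weinberg: alt dosage
   $\sim \mathrm{Binomial}(2, q_j)$ per sample;
3. per sample and site, depth $\sim \mathrm{Poisson}(30)$; each read
   independently comes from a contaminant with probability $c$ — in
   two-way mode a fixed partner (a random cross-stratum permutation in
   which every sample is original and contaminant exactly once), in n-way
   mode a sample drawn fresh and uniformly from all others per read — and
   the read's allele is drawn from the origin's *true* genotype, then
   flipped to the site's other allele with probability `seqError`
   (default 0.001). `ad_ref + ad_alt = dp` always: no third allele is
   modeled;
4. a flat-prior maximum-likelihood caller produces GT and GQ from the
   allele counts: per-read likelihoods $1-e$, $\tfrac12$, $e$ of a
   reference read under hom-ref/het/hom-alt, GQ the phred-scaled ratio of
   best to second-best genotype, capped at 99, ties resolved toward the
   first of (hom-ref, het, hom-alt).

The default cohort is 30 samples in 6 strata of 5; strata only constrain
two-way pairing (there is no per-stratum AF differentiation). All
randomness flows from one stream seeded at `simScenario(seed = )`, in the
documented order, so cohorts and truth tables are byte-reproducible.

What the simulator deliberately does **not** emulate: read positions,
mapping error, base-quality structure (collapsed into the single
`seqError` flip), reference blocks/gVCF structure, linkage between sites,
population structure in the AFs, and the behavior of production callers.
Passing tests therefore demonstrate the estimator's properties under its
own read-mixing model, not pipeline-specific effects in real data.

## Behavior at the extremes, by design

**High contamination deflates the estimate.** At $c = 0.10$ and depth 30,
a true hom-alt site carries ~$3 p$ reference reads on average; sites in
the upper tail are either called het (removed by the genotype gate) or
keep a GQ near 0 (removed by the GQ gate). The retained sites are exactly
the ones with *fewer* reference reads than expected, so the mean is biased
down. The acceptance suite measures this bias at $c = 0.10$ under the
default n-way scenario and requires it to fall in $[5\%, 20\%]$; with
this package's flat-prior caller it sits near the upper part of that
range (the caller's GQ drops to 0 at ~$dp/10$ reference reads, a harder
truncation than quality-aware production callers apply). The practical
consequence, and the recommended QC companion, is the het/hom-alt call
ratio (`hetHomRatio()`): hom→het conversion inflates it exactly when the
estimate deflates, flagging highly contaminated samples that a typical
$\sim$5% QC cutoff would still catch.

**Sequencing error inflates the estimate at very low contamination.**
Under the collapsed flip-error model, a hom-alt read becomes a reference
read with probability $e$, so each retained site contributes
$\approx c + e/p_j$ in expectation and the cohort mean carries an additive
floor of $e \cdot \overline{1/p} \approx 0.004$ at $e = 0.001$ under the
flat AF spectrum. Estimates at sub-percent true contamination are
therefore dominated by this floor in simulation — the acceptance check
asking for 15% relative recovery at $c = 0.005$–$0.01$ fails for exactly
this reason, and the failure is informative rather than a defect of the
estimator: real pipelines see a smaller floor because only about a third
of base errors convert the alternate to the specific reference base and
because quality-aware callers discount erroneous bases. Interpreting very
small estimates as upper bounds, or calibrating against known-clean
samples, is the right reading at that scale.

## Numerical choices

* $0 \cdot \log 0 \equiv 0$ in the likelihood, so a contamination-free
  sample is finite (and maximal) at $c = 0$; any observed reference read
  sends $\ell(0^+) \to -\infty$.
* Grid ties resolve to the smallest $c$ (conservative); grid points with
  any $c\,p_j \ge 1$ are skipped.
* An empty filtered set yields `charr = NA` with `insufficient = TRUE`
  instead of an error: batch runs over many samples must not abort.
* Records whose AD sums to zero fail the depth gate (every estimator term
  divides by $AR + RR$).
* Contig names are normalized by stripping a leading `"chr"`; autosomes
  are contigs `"1"`–`"22"` after normalization.
* Two-way pairing uses rejection sampling over permutations (cap 10,000)
  with a deterministic rotate-by-largest-stratum fallback; pairing is
  impossible, and refused, when one stratum holds more than half the
  cohort.

## Problem sizes

The test suite and the acceptance script use cohorts of 30 samples by
20,000 sites (about 5,000–6,000 retained hom-alt sites per sample after
filtering — comfortably above the 500-site sufficiency line, and an
order of magnitude more per-sample information than exome-scale data
provides), with smaller cohorts for unit-level checks. These sizes make
Monte-Carlo error small relative to the tolerances tested while keeping a
full run in tens of seconds.

## Session info

```{r}
sessionInfo()
```
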