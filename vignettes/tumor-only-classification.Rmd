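---
title: "Tumor-only somatic/germline classification: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only somatic/germline classification: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsieve)
```

## The problem and the model

A variant called in a tumor sample is either an acquired somatic mutation
or an inherited germline variant. With a matched normal the distinction is
made by subtraction; without one, it must be inferred from external
evidence. `somaticsieve` implements a three-phase decision tree over six
local evidence sources and makes three structural assumptions explicit:

* **Sequential, early-exiting phases.** Quality filtration runs first; a
  phase-2 germline call (population-database evidence) is final and is
  never revisited by phase 3. This mirrors the filtration-pipeline design
  the tree descends from, and makes every label attributable to exactly
  one deciding phase.
* **Somatic-catalogue dominance.** Catalogue membership (COSMIC-style)
  labels a variant somatic even when germline-database evidence coexists —
  recurrent hotspot positions do appear in population databases, and the
  catalogue is treated as the stronger signal. By default this dominance
  also extends over a benign clinical assertion, by analogy with the
  explicit dominance over population databases; the switch
  `clinvar_overrides_cosmic` inverts that, because the interaction of the
  two sources is genuinely underdetermined and catalogues are known to
  harbour some germline variants.
* **Totality.** A passing variant with no evidence anywhere defaults to
  somatic: a novel protein-altering variant absent from every germline
  catalogue is the canonical somatic candidate, and a classifier used for
  ranking must label 100% of its inputs rather than keep an "unknown"
  bucket.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `germline_maf_cutoff` | 0.01 | population AF at/above which a database hit is germline evidence; the comparison is inclusive (`>= 1%`), the common convention for "at a MAF of 1%" |
| `normal_af_cutoff` | 0.05 | matched-normal allele fraction *strictly above* which a tumor variant is gold-standard germline |
| `min_vaf`, `min_depth` | 0.05 / 50 (TS), 0.05 / 20 (WES) | phase-1 gates; these depth/VAF values are this package's suggested defaults for deep targeted panels and exomes, not published constants, and should be tuned per assay |
| `consequence_whitelist` | 10 protein-altering SO terms | operationalizes "non-synonymous" in phase 1 |
| `dbsnp_presence_is_germline` | off | whether a presence-only population hit without a common flag counts as germline evidence |
| `maf_folding` | off | whether stored AFs are folded to the minor allele (`min(af, 1-af)`) before the cutoff comparison |

Two points deserve emphasis. First, the four population databases are
pooled *any-hit* for allele-frequency evidence: a single qualifying AF in
any source makes the call germline. The per-database priorities (ExAC
highest, then 1000 Genomes, ESP, dbSNP) govern only which source the
reason code attributes the call to, plus the dbSNP-specific gating:
because dbSNP mixes germline and pathogenic entries and classifies
germline variants less reliably than frequency databases, its
presence-only records decide nothing unless flagged common (or the user
opts in). A presence-only record in *any* source is treated under the same
gate; in practice only dbSNP-style sources produce such records. Second,
AFs are compared unfolded by default: the simplest faithful reading of a
"1% MAF" rule when databases store alternate-allele frequencies. Folding
is provided as a switch because truly high-frequency alternate alleles
(AF > 0.99, minor allele < 1%) flip under it.

## Variant normalization

All joins between calls, databases and truth sets use a normalized
(chrom, pos, ref, alt) key: shared trailing bases trimmed, then shared
leading bases trimmed with a position shift, each while both alleles keep
at least one base — the standard parsimony reduction, which leaves the
single anchor base VCF requires for indels. Normalization is
*reference-free*: it cannot left-shift an indel through a repeat tract
beyond the context present in the alleles themselves, because that
requires the genome sequence. All spellings that extend a VCF-anchored
indel with shared context collapse to the same key (this is tested by
enumeration); spellings anchored on the *right* of a repeat tract would
need FASTA-aware realignment, which is an explicit extension point, not a
feature. Contig-name policy (`strip`/`add`/`asis` for the `chr` prefix)
is applied before any comparison, defaulting to `strip` since sources mix
both conventions across genome builds.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws a matched tumor/normal pair with known truth:

* class balance `germline_fraction = 0.57`, matching the germline share
  typically observed when paired targeted panels are validated;
* germline variants heterozygous (true AF 0.5, two thirds) or homozygous
  (1.0), identical in tumor and normal; somatic variants at
  `tumor_purity/2` in the tumor (default purity 0.8 → AF 0.4) and absent
  from the normal;
* read depth Poisson around `mean_depth = 200` (deep targeted panel) and
  alt reads binomial given depth and true AF — the simplest noise model
  consistent with depth/VAF thresholds;
* database membership as independent Bernoulli channels:
  `db_sensitivity = 0.9` per germline database, `db_false_common = 0.01`,
  `cosmic_sensitivity = 0.8`, `cosmic_germline_leak = 0.02`,
  `clinvar_benign_rate = 0.3`, plus a 5% channel of sub-cutoff (rare)
  records that must *not* decide anything;
* 10% indels, written to disk with a deliberately non-parsimonious extra
  trailing base so the readers' normalization path is always exercised;
  10% synonymous consequences exercising phase 1.

These rates were fixed once as a plausible description of a
targeted-sequencing study against mature databases. The generator does
**not** model mutational signatures, linkage, copy-number structure,
subclonality, or sequencing artifacts; membership channels are
independent across databases, which real databases (which share source
cohorts) are not. Passing tests on simulated cohorts therefore
demonstrate the correctness of the decision logic, the bookkeeping and
the I/O under the stated evidence model — not the field accuracy of the
method on any particular cohort, which depends on database
completeness for the population being sequenced.

## Numerical and degenerate-input choices

* The MAF comparison is inclusive (`af >= cutoff`); the normal-AF rule is
  strict (`> 0.05`), and both boundaries are pinned by tests.
* A zero-depth call has undefined VAF (never silently 0) and cannot pass
  phase 1; it is kept, flagged, and excluded from evaluation like any
  filtered call (a switch scores filtered calls as errors instead).
* When an explicit `AF` field and the `AD`-derived fraction disagree by
  more than 0.01 the explicit field wins and a warning is raised.
* Duplicate database keys after normalization collapse to max AF
  (population), summed occurrence counts (somatic), or the union of
  significance terms (clinical).
* Evaluation refuses predictions that assign two different labels to one
  key; metrics over an empty truth class are reported as undefined
  (`NA`), never 0/0.
* Classification is order-independent; cohorts are processed as vectors
  and reasons are ordered with the deciding code first.

## Problem sizes

The test suite and the acceptance script run the exhaustive evidence
truth table (10,240 states × 8 switch combinations), end-to-end benches
at 10<sup>4</sup> variants, and property tests at 10<sup>2</sup>–10<sup>3</sup>
variants — sizes chosen so the full decision space is covered exactly
while any single check completes in seconds.

## Known limitations

* Reference-free normalization (above) cannot reconcile right-anchored
  indel spellings across repeat tracts.
* No tumor purity/ploidy modeling: posterior-probability somatic/germline
  genotyping from copy number (the "hybrid" approach that pairs a
  filtration tree with purity-aware reclassification) is out of scope;
  the tree is the "pure" tumor-only path only, and published comparisons
  consistently show purity-aware reclassification recovering specificity
  that database filtering alone cannot, especially on exomes.
* Consequence terms are taken as given on input; the package does not
  annotate consequences itself.
* VCF floats round-trip at 5 significant digits through the writer, so
  VAFs are preserved to ~10<sup>-4</sup>, not bit-exactly.
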