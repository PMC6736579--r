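---
title: "Methods: blank-informed contaminant screening and amplicon-to-MAG linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blank-informed contaminant screening and amplicon-to-MAG linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxonsluice)
```

This vignette is the package's own account of its models and the choices
behind them: what is computed, under what assumptions, which parameters
matter, and what the synthetic fixtures do and do not demonstrate.

## 1. The contaminant screen

### Model and assumptions

Low-biomass amplicon libraries mix two communities: the specimen community
and a reagent ("kit") community that enters during extraction and library
preparation. Extraction blanks sample the kit community almost purely;
specimens sample mostly the native community with a small kit admixture.
When several blanks are sequenced, each is an independent observation of
the kit community, which is what makes a screening statistic stable.

The screen reduces each OTU to a single number. With `b` the mean of the
OTU's relative abundances over blank libraries and `s` the mean over
specimen libraries, the *blank share* is

$$ w = \frac{b}{b + s}, \qquad w = 0 \text{ when } b = s = 0 . $$

An OTU is flagged when `w >= tau`. The statistic assumes that library-depth
differences carry no information (each library is normalized to its total
before averaging), and that blanks are exchangeable (they are aggregated by
the mean; the per-blank values are retained on every flag record so a
reviewer can inspect disagreement between blanks).

Design alternatives we considered and rejected for the default: pooling raw
reads across blanks (lets one deep blank dominate), and max-over-blanks
(flags on single-blank artifacts). The statistic is isolated in one
function (`blank_shares()`), so alternatives can be added without touching
the flagging, annotation or culling steps.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.10 | flagging threshold on the blank share, boundary inclusive |
| `top_k` | 10 | reference hits reported per flagged OTU |
| `pseudo_depth_min` | 1 | smallest usable library size |

`tau = 0.10` is the conventional 10% screening default; it is deliberately
permissive because flagging is not removal — every cull requires an
explicit reviewer decision, recorded per OTU (`remove`, `retain`, or
`pending` when undecided). The flagging is a deterministic screen, not a
hypothesis test, so no multiple-testing machinery is attached.

Degenerate inputs are errors, not silent results: a zero-depth library, a
table without both roles, a decision on an unflagged OTU, and a flagged OTU
without a representative sequence all raise typed conditions.

## 2. The alignment engine

Annotation of flagged OTUs and amplicon recruitment both need local
nucleotide alignment with identity, query coverage and an e-value. The
engine is an affine-gap Smith–Waterman with:

* scoring `+2 / −3 / −5 / −2` (match, mismatch, gap open, gap extend); a
  gap of length L costs `gap_open + L·gap_extend`;
* IUPAC-aware matching: a column is a match iff the two codes' nucleotide
  sets intersect, and such columns count toward the aligned length —
  deterministic and permissive, and ambiguity codes are kept as read,
  never converted to `N`;
* identity = matches / aligned columns of the local alignment (there are
  no end gaps in a local alignment, so the denominator is the aligned
  span), and query coverage = aligned query positions / query length;
* e-value `E = K·m·n·exp(−λS)` with `K = 0.711`, `λ = 1.374`, `m` the
  query length, `n` the total database length.

These constants mimic ungapped BLASTN conventions but the contract is the
*thresholding behaviour* — which pairs clear 99% identity and 90%
coverage — not bit-for-bit BLAST equivalence. Word size, scoring and the
Karlin–Altschul constants are all configurable.

Determinism is part of the contract. Ties are broken by highest score,
then smallest query start, then smallest subject start (and then smallest
end coordinates); traceback prefers diagonal over vertical over horizontal
moves, and gap states prefer closing the gap. The search ranks hits by
score, then e-value, then lexicographic subject id. Every one of these
rules is mirrored by an independent plain-R dynamic-programming oracle in
the test suite, and the two are required to agree exactly — score,
identity, coverage and span — on hundreds of random pairs.

The seeded search aligns only candidates sharing at least one exact k-mer
(`k = 8`) with the query on either strand. On databases where a candidate
is seeded on one strand only, the seeded result can differ from an
exhaustive best-of-both-strands ranking for *weak* hits; the equivalence
tests therefore use fixtures in which every record is seeded on both
strands, which is also the regime the toolkit operates in (mutated copies
of reference sequences always share seeds at the divergence levels the
thresholds accept).

## 3. Amplicon-to-MAG linking

### Recruitment thresholds

A MAG is *biofilm-linked* when at least one amplicon aligns to one of its
16S genes at `>= 99%` identity over `>= 90%` of the amplicon length (both
boundaries inclusive, coverage per best local alignment). There is no vote
counting: one passing match suffices, matching the binary fraction
assignment the workflow produces. At an amplicon length of 250 nt the
identity threshold admits at most 2 substitutions (248/250 = 99.2%) and
rejects 3 (247/250 = 98.8%); a 200-of-250 alignable amplicon fails
coverage at 80%. Substitutions closer than 2 nt to an amplicon end are a
boundary subtlety: the optimal local alignment trims a terminal mismatch,
so identity and coverage both shift; the fixtures plant interior edits.

For read recruitment (OTU representatives vs metagenome read sets),
coverage is measured on the *shorter* of read and representative, because
reads may be shorter than the amplicon; each read goes to the single best
passing OTU (score, then identity, then lexicographic id), so per-read
assignments are unique and column sums are bounded by read counts.

### Coverage-uniformity QC

Reconstructed 16S genes are error-prone; chimeric assemblies show uneven
read coverage along the gene or a depth mismatch against the parent
contig. The package replaces by-eye inspection with a reproducible
surrogate: the coefficient of variation (population standard deviation /
mean) of per-base gene depth must satisfy `cv <= cv_max` (default 1.0) and
the gene/contig mean-depth ratio must fall in `[0.25, 4.0]`, all
boundaries inclusive. A gene with zero mean depth fails with `cv`
recorded as infinite. These bounds are declared surrogates for a manual
judgement, not inferences of any particular analyst's criteria, and are
fully configurable. The verdict is invariant under joint rescaling of both
depth tracks.

MAGs with no 16S gene, or whose genes all fail QC, are *excluded* and
contribute to neither fraction downstream — the three fractions are always
a disjoint cover of the input MAG set.

### Functional comparison

Category abundance for a fraction is (annotated genes in the category,
summed over the fraction's MAGs) / (total predicted ORFs over those MAGs).
ORF-based normalization is used rather than read-based; annotation counts
are what the upstream annotators emit, and ORF totals make fractions of
different aggregate genome size comparable. Per-gene values within a
category are rescaled to [0, 1] by each gene's maximum across the two
fractions — the dominant fraction sits at 1 unless both are 0 — which is
the radial axis convention of the spider plots; this rescale rule is
declared and isolated in `compare_profiles()`. Marker-panel presence is
existential: a panel entry is present in a fraction iff any of its MAGs
carries at least one gene of the entry's symbol set.

## 4. The synthetic-data generator

Every input format the toolkit reads can be generated with planted truth
(`simulate_count_table()`, `simulate_refdb()`, `simulate_mag_set()`,
`simulate_depth_tracks()`, `simulate_annotations()`, `simulate_all()`),
deterministically per seed.

**Count tables.** Each library is one multinomial draw of fixed depth from
an expected composition, so library sizes are exact. Blanks draw 98.5%
of their mass from a log-normal kit community (the planted contaminants)
and 1.5% from the background; specimens draw from a log-normal background
plus per-contaminant leak coefficients solved from the planted blank-share
targets (default targets evenly spaced 0.35–1.0, total specimen kit mass
capped at 0.15). Background base abundances mix a log-normal with a 30%
uniform floor. The floor is what guarantees the planted separation: at the
default depth of 5×10⁴ reads the rarest background OTU still receives
enough specimen reads that its sampled blank share sits several binomial
standard errors below `tau = 0.10`, so perfect recall/specificity on the
planted truth is a property of the design, not luck. The recorded truth is
the *realized* expected share of the generating composition.

**MAG sets.** The default set mirrors the workflow's reference scenario:
23 MAGs of which 12 carry a 16S gene whose amplicon-region window matches
a supplied amplicon (0–2 interior substitutions, capped at 1% of the
amplicon length so a planted match always clears the identity threshold,
and always sharing seed k-mers), 8 carry unrelated genes, and 3 carry no
16S gene. Genes are planted on contigs with flanks, half on the minus
strand, so coordinate conversion and sense-strand extraction are
exercised; per-base depth tracks come in `uniform` (20×), `spiked` (100×
over half the gene, 0 over the rest — cv exactly 1, gene/contig ratio 2.5
against a 20× contig) and `zero` profiles.

**What the fixtures do not emulate:** per-base sequencing error and
quality profiles (no FASTQ), chimeras, taxonomically structured reference
databases, batch-specific blank pairing, and compositional correlations
between contaminants and specimens. Passing tests demonstrate the
algorithms' contracts — thresholds, bookkeeping, determinism, recovery of
planted structure — not field performance on real surveys, where the
blank share of a true contaminant depends on how faithfully blanks sample
the kit community.

## 5. Problem sizes and numerical conventions

The test and acceptance workloads use the generator's default scale — 200
OTUs across 6 libraries of 5×10⁴ reads, 23 MAGs with 1200-nt genes and
250-nt amplicons, 50-record reference databases — and smaller randomized
fixtures (tens of OTUs, 300-nt genes) for property sweeps across 100
seeds. These sizes were chosen so the full suite exercises every code path
at realistic shapes while remaining quick to rerun during development.

Conventions worth restating: external GFF3 and depth files are 1-based
inclusive, all internal coordinates are 0-based half-open, and conversion
happens only at the I/O boundary; minus-strand genes are
reverse-complemented at extraction so downstream comparisons are on the
sense strand; all threshold comparisons are boundary-inclusive; report
JSON always carries a `version` and a `parameters` block, and every CLI
run writes a manifest with input digests and the seed (the manifest's
wall-clock timestamp is the one deliberately non-deterministic output).

## 6. Known limitations

* The blank share is a screen, not an error model: it has no notion of
  cross-contamination between specimens, index hopping, or
  concentration-dependent contamination, and it will flag genuinely shared
  taxa that are abundant in both blanks and specimens only if their blank
  mass dominates.
* The alignment engine is quadratic per pair; it is built for amplicon- and
  gene-scale sequences, not genome-scale alignment.
* QC thresholds quantify a qualitative judgement; different `cv_max` and
  ratio bounds will move borderline MAGs between `excluded` and the
  analyzed fractions.
* Marker presence is existential and unweighted; a single annotated gene
  in a large fraction produces the same mark as universal presence.
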