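---
title: "Methods: fusion filtering, validation, and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion filtering, validation, and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and rules
each stage implements, the assumptions behind them, the decisions taken where
the underlying procedures are conventionally under-specified, and what the
synthetic cohort generator does and does not emulate.

## Coordinate model and breakpoint location

Gene models hold one canonical transcript per gene — the isoform with the
longest CDS, ties broken by smallest transcript identifier — because fusion
callers report gene-level events and a deterministic isoform choice keeps
every downstream annotation reproducible. Internally all intervals are
0-based half-open; GTF input is read as 1-based closed and all emitted
breakpoints are 1-based, matching caller conventions.

`locate_breakpoint()` maps a genomic position to 5' UTR, CDS, 3' UTR, intron,
or non-coding. Non-coding biotypes map to the non-coding region regardless of
exon position. A subtlety matters for frame arithmetic: callers report the 5'
partner's breakpoint as the **last transcribed base retained** and the 3'
partner's as the **first base retained**, so "coding bases 5' of the
junction" differs by one base between the two sides — and one base matters
modulo 3. The `side` argument makes the convention explicit: the default
counts coding bases strictly before the breakpoint base (the discarded bases
of a 3' partner); `side = "5prime"` also counts the breakpoint base itself
(the retained bases of a 5' partner). In both modes `aa_pos` is the residue
containing the breakpoint base, and a breakpoint on an exon–intron boundary
is exonic (callers report exon-edge junctions).

A fusion is **inframe** when retained 5' coding bases and discarded 3' coding
bases agree modulo 3; if either breakpoint is outside a CDS there is no frame
information. The test suite checks this arithmetic against an independent
codon-table translation oracle over all nine (mod-3, mod-3) phase
combinations: the prediction must match whether the translated chimeric CDS
actually ends with the wild-type 3' protein tail.

## Filter cascade

Five conjunctive rules, evaluated cohort-wide:

| rule | removes | default |
|------|---------|---------|
| R1 | either partner on the exclusion list | fixture list |
| R2 | self-fusions and paralog pairs | fixture pairs |
| R3 | gene pairs seen in normals (panel of normals) | fixture pairs |
| R4 | single-caller calls with FFPM ≤ `ffpm_min` | 0.1 |
| R5 | identical breakpoints in ≥ `recurrence_max` samples across ≥ 2 cancer types, unless allowlisted | 10 |

Because the rules are conjunctive the kept set cannot depend on evaluation
order; only the `failed_rule` label (the first violated rule) does, and the
order is an explicit argument so this invariance is testable. Decisions where
the convention was open: R5 matches **exact breakpoint coordinates** (not
gene pairs), and a recurrence confined to one cancer type is kept — a
ten-sample within-type recurrence is the signature of genuine biology, not of
a technical artifact. Normals-panel and paralog matching use unordered gene
pairs, since breakpoints in normal tissue differ run to run. FFPM uses the
strict inequality (support must exceed 0.1 per million), and calls reported
by two or more callers are exempt because cross-caller agreement is itself
evidence of support.

## WGS validation

Each partner gene defines a window of its span ± 100 kb (clipped at the
chromosome start). A template validates a call when its two primary mates
land one in each window with both MAPQ ≥ 20; ≥ 3 such pairs validate the
call, and samples without WGS are excluded from the rate's denominator. Two
decisions: both mates (not just one) must pass the MAPQ cut, the stricter
reading; and when the two windows overlap — genomic-neighbor partners — the
shared region is excluded from both windows, because an ordinary concordant
pair falls entirely inside it and would otherwise self-validate every
read-through. "Discordant" is defined by window membership rather than SAM
proper-pair flags so that low-pass and high-pass libraries mix cleanly.

## Kinase annotation

Kinase fusions are 5'-, 3'-, or both-kinase by table membership; a
both-kinase fusion with exactly one intact domain is reassigned to that side.
Domain retention is positional: a 5'-kinase keeps its domain when the
breakpoint residue is at or beyond the domain end (or in the 3' UTR) — the 3'
partner's frame is irrelevant because the kinase ORF is upstream of the
junction; a 3'-kinase keeps it when the breakpoint is in its 5' UTR (promoter
swap: the whole ORF survives) or at/before the domain start *with* an inframe
junction, since a frameshift destroys everything downstream. Boundary
residues count as retained (the codon is intact), and a gene with several
annotated domains is intact if any is. Per-cancer kinase-group composition is
reported as normalized percentages: pan-cancer group shares
`p_g = count_g / Σ count`, per-cancer counts divided by `p_g`, rescaled to
sum to 100. Groups absent pan-cancer are dropped before normalization (their
`p_g` would be 0), and cancer types with no kinase fusions are omitted with a
warning rather than reported as 0/0.

## Expression association

All expression work happens on the log2(x+1) scale; percentiles and Tukey
fences are monotone-invariant to this choice, and the t-test benefits from
the variance stabilization. Percentiles use average ranks rescaled so the
cohort minimum is 0 and maximum 100 (mean exactly 50). Quartiles use linear
interpolation between order statistics (quantile type 7) — the convention is
stated because Tukey fences are sensitive to it; fewer than four values is an
error rather than a silent unstable estimate. Two test families run per
(gene, cancer type): Welch's two-sided t-test (unequal variances are the norm
for outlier-driven genes) and Fisher's exact test of outlier status by fusion
status, computed separately for over- and under-expression outliers with
both reported. "Stringent FDR" is Benjamini–Hochberg at q < 0.05 by default,
applied within each p-value family across all tests. A gene is flagged for
review only with ≥ 3 fusion samples and a median fusion-sample percentile in
the top or bottom decile, so the flag means "consistent, directional, and
multiply observed". The flag set is a screen under FDR control: the tests
assert that every injected truth gene is recovered, not that nothing else is
ever flagged.

The kinase-vs-partner comparison is restricted to fusions whose kinase has
1–3 copies (inclusive), removing amplification-driven expression, and
compares the two genes' within-cohort percentiles in the fusion sample, with
a ±5-point band called equal. One modelling note: because both within-gene
percentiles have uniform margins, their joint distribution under any
carrier-level coupling is exchangeable, so conditioning on "partner above
kinase" mechanically selects lower kinase values. The biologically meaningful
statement — fusions under a more active partner promoter drive the kinase
higher — is therefore tested as a positive rank correlation between partner
percentile and kinase quantile across capture fusions, not as a difference
between the categorical groups; the categories remain available as
descriptive summaries.

## Driver landscape, druggability, smoking

Alteration profiles count seven MAF variant classes (inframe indels,
missense, nonsense, nonstop, splice site, translation start site) toward
driver-gene mutation status; curated driver mutations are an input flag
column on MAF rows, since such curation is external to this package. A
driver fusion is any kept fusion with either partner in the driver-gene
list. The six driver groups partition the cohort, with known-driver status
taking precedence over generic driver-gene mutation. Burden comparisons
remove samples with any mutation in POLE/MLH1/MLH3/MGMT/MSH6/MSH3/MSH2/
PMS1/PMS2 first (microsatellite-instability confounding), then apply a
two-sided Mann-Whitney test; the suite checks it against a brute-force
enumeration of the exact U distribution for group sizes ≤ 8 and verifies the
type-I error level over 1,000 null simulations. Both pooled and pairwise
group comparisons are supported since either reading of the burden figure is
defensible. Druggability matching is gene-level with optional
partner-restricted entries and an off-label switch (off-label inclusion is
the default, matching the "regardless of cancer type" reading); the smoking
association is a Pearson chi-square without continuity correction — at the
published table's sample sizes the correction is immaterial and the
uncorrected statistic is the common default.

## Neoepitopes

Fusion proteins are built from the partners' transcript sequences: retained
5' CDS prefix plus 3' CDS suffix, translated to the first stop; frameshift
products carry a novel tail; a 5' UTR–5' UTR promoter swap yields the intact
wild-type 3' protein (junction index 0). Other no-frame configurations have
no resolvable start codon and error. Candidate peptides are all full-length
8–11-mers spanning the junction, plus — for frameshift products — every
k-mer inside the novel tail (the tail-inclusive mode is the default; it is
what makes frameshift products the richer epitope source, and the
junction-only mode is available by taking `novel_tail = FALSE`). Windows
truncated by the protein ends are dropped, and because translation stops at
the first stop codon no emitted window crosses a stop. Peptides occurring
verbatim in either partner's wild-type protein are excluded — the minimal
reading of "not present in the wild type"; a whole-proteome exclusion is a
matter of passing more sequences. Affinity prediction is a contract, not a
model: any deterministic `(peptide, allele) -> nM` function plugs in; the
shipped toy predictor is hash-based, bounded in (0, 50000], and guarantees
≤ 500 nM for configured motifs. Fusions with fewer than 5 junction reads are
skipped; predictor failures degrade to `NA` calls rather than aborting a
cohort run. Default per-sample alleles come from metadata, with a
configurable fallback set.

## The synthetic cohort generator

`simulate_study()` writes a complete study to disk: GTF and transcript
FASTA, domain/kinase/paralog/exclusion/normals/allowlist/drug tables, three
caller TSVs, expression and copy-number matrices, a MAF, sample metadata,
per-sample SAM files, and a truth JSON. The default conditions: two
cancer-type labels of 60 samples; ~60 genes (multi-exon, both strands, CDS a
multiple of three, two kinase genes per group across the eight standard
groups); 5% of a type's samples carry each standard truth fusion; expression
is log-normal per gene (chosen for positivity and a heavy right tail, the
shape of RSEM abundances) with outlier shifts of ±5 cohort SDs on the log2
scale; background mutations at 30 per sample with driver and MMR genes
down-weighted (a driver list is a tiny slice of an exome); 10% MSI samples at
15× burden with a guaranteed MMR mutation; 15% never-smokers; WGS available
for 70% of samples; libraries of 4×10⁷ fragments. Promoter-capture fusions
couple the carrier's kinase expression to the partner's z-score (coupling
0.8) after a 1.5 SD partner activation — a detected capture fusion implies an
active partner locus. Each truth event fixes its breakpoints once, so
recurrence is exact; decoys violate each filter rule by construction,
including a ten-sample cross-type recurrent artifact and its allowlisted
twin; one event joins two genes 50 kb apart so that its WGS pairs are
swallowed by the window-overlap exclusion, exercising that rule end to end.

What the generator does **not** emulate: splice-isoform diversity (one
transcript per gene), read-level sequence noise, caller-specific sensitivity
profiles, correlated expression programs, subclonality, or realistic HLA
binding (alleles are toy labels and the affinity model is a hash). Green
tests therefore demonstrate that every rule and statistic does exactly what
it claims on data satisfying its assumptions — not that the thresholds are
optimal for any particular real cohort.

## Problem sizes and determinism

The test suite runs a 80-sample shared study end to end, 100 seeded
replicates of the outlier-recovery screen on 100-sample cohorts, 1,000 null
simulations for the Mann-Whitney level check, and exhaustive
oracle comparisons for translation, enumeration, and quantiles — a few
minutes on one CPU. All generator randomness flows from one seed through
per-stage derived streams; identical seed and configuration reproduce every
file byte for byte. The pipeline itself is deterministic given its inputs;
its only seeded component is the toy affinity predictor.

## Known limitations

Merging assumes callers agree on gene symbols; a symbol-level mismatch
(alias, readthrough naming) splits a record. Validation counts template
start positions, not aligned spans, so a mate straddling a window edge is
binned by its leftmost base. The expression screen tests one gene at a time
and inherits the usual caveats of outlier-based association at small carrier
counts. Driver-mutation curation quality is entirely the caller's
responsibility — the package treats the flag as ground truth.
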