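---
title: "Designer metatranscriptomes: simulating and scoring eukaryotic community assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designer metatranscriptomes: simulating and scoring eukaryotic community assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eukbench)
```

## The problem

De novo assembly of eukaryotic metatranscriptomes has no natural ground
truth: when reads from an environmental community are assembled, there is no
way to say which contigs are right. The standard way out is a *mock*
community — a "designer" metatranscriptome built from reference
transcriptomes whose content is known exactly — from which reads are
simulated, assembled, and compared back against the design.

`eukbench` implements that benchmarking loop end to end:

1. a **reference panel** of organism transcriptomes with known orthology
   (synthetic, or supplied as FASTA + orthogroup tables);
2. **community design**: six community archetypes with controlled
   proportions, plus ortholog-aware contig selection;
3. **read simulation** with an error model and a Trimmomatic-style trimmer;
4. the **merge/cluster hierarchy** used for multi-assembler outputs
   (AGM → CAG → MAD);
5. **recovery evaluation**: contig statistics, protein-space recovery,
   read representation, taxonomic/functional classification, and the
   concordance statistics used to summarize them.

## The synthetic panel model

`generate_panel()` realizes gene families under a deliberately simple
star-topology model: one ancestral sequence per family, each member mutated
independently from it at the within-family substitution rate. Pairwise
divergence between two members is therefore roughly twice the per-member
rate, which makes pairwise identity directly controllable. Families come in
three kinds:

* **single-copy families** — exactly one gene in *every* organism; these are
  the pool the "force 10%" selection rule draws from;
* **shared families** — random subsets of organisms (2–4 members);
* **exclusive families** — private to one organism.

Designated strain pairs are built by derivation: the second strain carries a
configurable fraction (default 0.8) of its partner's families, each gene
mutated at the strain-pair rate (default 0.02, i.e. ~98% identity). This is
the one place the model is not a star: strains are sampled from each other,
as real conspecific transcriptomes would be. A consequence worth knowing is
that a strain partner *depletes* its mate's exclusive-family pool — most of
what was private becomes pair-shared — so communities with partnered members
need panels with enough genes for the 25% exclusive draw to be feasible;
`select_contigs()` reports the organism and shortfall when it is not.

Transcripts are ORF-bearing by construction (ATG, no in-frame stops, a stop
codon), so protein-space evaluation is meaningful on fixtures. Defaults:
gene lengths uniform in [300, 3000] bp (transcript-scale contigs), 5%
within-family substitution (≈ 90% pairwise identity, comfortably above the
80% orthology-inference threshold), no indels unless requested.

What the generator does **not** emulate: codon usage, tree-shaped phylogeny
(beyond the strain derivation), UTR/intron structure, expression-level
realism, sequencing-depth heterogeneity. Tests that pass on these panels
demonstrate that the machinery is correct under controlled divergence — not
that any particular assembler will behave identically on real data.

## Community templates and contig selection

`make_template()` encodes six archetypes: (1) dominated by one organism
(richness 4, 0.85/0.05/0.05/0.05); (2) a strain pair holding the majority
(richness 5, 0.40/0.35, the pair forced into the two largest proportions);
(3) skewed, exclusive-gene-rich (richness 8, geometric ratio 0.7);
(4) high diversity with related groups (richness 10, near-even); (5) several
mutually related members, even (richness 7); (6) highest diversity, even
(richness 12). The source these templates paraphrase gives only qualitative
descriptions, so the numeric proportions are this package's own defaults and
can be overridden per call.

`select_contigs()` applies the selection rules:

* 10% of the single-copy orthogroups over the community roster are chosen at
  random and **every** member's gene from each chosen group is included
  (category `single_copy_forced`);
* each organism's remaining quota is
  `round(proportion × (budget − forced))`; forced genes do *not* count
  against quotas (the source is silent on this; counting them would make
  dominant-member quotas depend on the single-copy pool size, which seemed
  the less defensible reading);
* a member with a designated highly-related partner fills 75% of its quota
  from orthogroups containing at least one other community member and 25%
  from groups exclusive to it; an unpartnered member does the reverse.
  Splits use largest-remainder rounding (ties to the 75% category), so
  realized counts differ from nominal by at most one contig.

Expression weights are uniform within an organism
(`proportion / contig count`); the within-organism expression distribution
is not specified by the source and a uniform choice keeps per-contig read
counts interpretable in tests.

"Shannon index" is the conventional `H = −Σ p ln p` (the source's printed
formula has mixed indices and a dropped sign; the conventional form is
assumed). The composite similarity score is read literally from its printed
double sum: ordered pairs, diagonal zero, so each unordered pair counts
twice — `Σᵢ Σⱼ (1 − score᙮ᵢⱼ) · min(pᵢ, pⱼ)`.

## Sketch similarity and ANI

`kmer_sketch()` is a bottom-s MinHash over canonical k-mers (default k = 31,
s = 1000). Hashing is a seeded double-precision rolling hash: two ~26-bit
modular hashes packed into one value below 2^52, exact in IEEE doubles —
base R has no 64-bit integer hash, and this construction keeps collisions
negligible (birthday bound ≈ 10⁻⁴ at a million k-mers). Canonicalization
takes `min(hash(kmer), hash(revcomp))`, which partitions k-mer/reverse-
complement pairs identically to lexicographic canonicalization.

ANI is estimated from sketch Jaccard by the Mash distance transform
`ANI = 100·(1 + ln(2j/(1+j))/k)`, floored at 0, with Jaccard 0 flagged
"below detection". On mutated pairs this lands within ~2 points of the true
identity down to ≈ 85% and is what the ≥ 80% "highly related partner" rule
is applied to. Note the transform saturates from below: organisms sharing
even a modest fraction of near-identical gene content can estimate in the
low 80s, so partner detection on dense panels should rely on designated
strain pairs or a threshold chosen for the panel at hand.

## Read simulation and trimming

`simulate_reads()` draws a source contig per pair proportional to
`weight × (length − read_length + 1)`, a fragment length from
Normal(180, 40) **clamped** to `[read_length, contig_length]`, and a uniform
start; R1 is the fragment's 5′ end, R2 the reverse complement of its 3′ end.
Clamping (rather than rejection) was chosen because it leaves the mean
essentially unbiased — rejection shifts the truncated-normal mean by about
half a base pair, which is detectable at the simulation sizes used here.
Substitution errors are injected per cycle at `10^(−Q/10)`, always to a
different base; the default profile decays linearly Q38 → Q25 over 75
cycles. Q ≥ 60 is treated as exactly error-free so that the zero-error mode
really produces exact substrings. Read names and a truth table record
source contig, 0-based fragment start and fragment length. The default
library size is 10⁶ pairs (the source's "1 million … library" is ambiguous
between pairs and bases; pairs was chosen and is configurable).

`trim_reads()` mirrors `LEADING:2 TRAILING:2 SLIDINGWINDOW:4:2 MINLEN:50`:
clip low-quality leading/trailing bases, cut at the first full 4-base window
whose mean quality drops below the threshold, then drop reads under 50 bp,
routing widowed mates to an unpaired output. As in the tool it mirrors, the
window step also strips trailing bases below the window threshold, which
makes trimming idempotent. Adapter clipping is not simulated and not
implemented.

## Merging and clustering

The merge hierarchy concatenates per-assembler outputs for an assembly group
(AGM, ids rewritten `<group>_<assembler>_<id>`), removes contigs contained
at 100% identity over the full shorter-sequence span (`dedup_identical()`),
and clusters at 98% identity (`build_cag()`); CAGs from all samples are
concatenated (SWAM) and re-clustered at 98% into the final MAD.

Clustering is greedy and incremental (LINCLUST-style): sequences sorted by
length descending (ties by id), each joining the first representative it
meets both thresholds against, with a shared canonical 15-mer prefilter
before any alignment. Representatives are therefore always the longest
member, and every recorded (member, representative) pair has been verified
by the alignment kernel — a property the test suite re-checks with an
independent pure-R dynamic-programming aligner.

The kernel is Smith–Waterman local alignment (match 2, mismatch −3, gap
open 5, extend 2), identity = matches / alignment columns *including gap
columns* (the mmseqs2-like convention; stated explicitly because it moves
borderline cases), and, when strand-aware, the better of the two
orientations. The 98% rounds use shorter-sequence coverage 0.8: the source
pins identity but prints no coverage for this step ("defined the same way as
above" could mean the 100%-containment convention or nothing), and 0.8
keeps near-full-length duplicates collapsing while genuinely distinct
contigs survive.

## Evaluation

* `assembly_stats()` — contig count, length summaries, per-sequence GC, and
  N50 by the QUAST definition (sort descending; the length at which the
  cumulative sum first reaches half the total).
* `pseudomap()` — a documented k-mer proxy for read representation: a read
  maps to the contig sharing most of its canonical 31-mers if that share
  covers ≥ 70% of the read's k-mers; per-contig counts and TPM
  (count / kb, normalized to 10⁶). It stands where an external quantifier
  would in a full pipeline; externally computed count tables can be supplied
  to the downstream steps instead.
* `find_orfs()` — six-frame scan, ORFs from the first ATG (optional) of each
  stop-free stretch, default minimum 100 aa. This replaces model-based
  coding-region prediction; fixtures are built ORF-bearing so the
  simplification costs nothing there.
* `protein_recovery()` — an assembly contig is *matched* when at least one
  of its ORF proteins aligns to a designer protein at ≥ 90% identity
  covering ≥ 90% of the designer protein (target coverage, cov-mode-1
  style); contigs with ORFs but no match are *unmatched*, the rest *no_orf*.
  All matched designer ids are recorded; when different ORFs of one contig
  match different designer organisms the report keeps them all and leaves
  interpretation to the caller.
* `taxonomic_recovery()` / `functional_recovery()` — match/conflict/
  unannotated classification with abundance weighting, and exact set algebra
  over function tokens (match / false positive / not recovered).
* `consensus_support()` — clusters the union of labeled assemblies and
  reports how many assemblers support each cluster.
* `linear_regression()` (optionally through the origin, slope Σxy/Σx²) and
  `welch_t()` (Welch–Satterthwaite df; t = 0 when both samples are constant
  and equal) wrap the base-R fits and are oracle-checked in the tests.

## Numerical choices and degenerate inputs

Seeds are explicit everywhere; heavyweight entry points derive per-stage
seeds by fixed offsets, and all randomized functions restore the caller's
RNG state. Rounding of category counts is largest-remainder with
deterministic tie-breaks; `round`-half-up is used for single quantities to
avoid R's round-to-even surprises. Empty inputs error early with named
messages (empty assemblies, all-N sequences, k larger than every sequence,
constant regressors, zero-variance Welch samples).

## Problem sizes

The shipped tests and the reproduction script run entirely on synthetic
panels at desk scale, chosen so each stage exercises its logic without
ballast: panels of 2–5 organisms with 80–2,600 genes per organism
(13,000 genes at the largest, for the quota checks), designer budgets of
120–4,200 contigs, 10⁵ fragment draws for the fragment-model checks,
10⁵ read pairs for the weight-correlation property, and 200–300-contig
clustering fixtures. Full-scale runs (tens of thousands of contigs,
10⁶ read pairs) use the same code paths through the configuration.

## Known limitations

* The pseudo-mapper is a proxy, not a quantifier: no fragment-length model,
  no multi-mapping resolution; its percent-mapped is conservative for
  high-error reads.
* ANI via the Mash transform saturates near the 80% cutoff for organisms
  with shared gene content (see above); it is not a fragment-mapping ANI.
* Orthology inference is single-linkage over alignments: adequate at
  fixture divergences, but real paralog-rich transcriptomes would chain
  more aggressively than a tree-aware method.
* Six-frame ORF finding has no coding model; on real assemblies it will
  call spurious ORFs that model-based predictors would reject.
* E-values are never computed; all recovery decisions are identity/coverage
  thresholds.
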