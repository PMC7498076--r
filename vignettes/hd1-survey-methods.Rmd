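---
title: "Methods: loss-of-function haplotype surveys of rice Hd1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loss-of-function haplotype surveys of rice Hd1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hd1survey)
```

## The problem

*Heading date 1* (*Hd1*) is the rice ortholog of Arabidopsis *CONSTANS*: a
two-exon, plus-strand gene on chromosome 6 whose functional product delays
flowering under long days. Loss-of-function (LOF) *hd1* alleles release that
photoperiod sensitivity and have been repeatedly selected as rice cultivation
moved into subtropical and tropical Asia. Large resequencing panels make it
possible to type thousands of accessions for a catalog of known LOF
haplotypes — small frameshifting indels, premature-stop SNPs, and one
1.9-kb LTR-retrotransposon insertion — and then to ask population-genetic
questions about where each mutation arose and how strongly it was selected.

`hd1survey` implements that survey as a tested, reusable pipeline with five
analysis layers and a synthetic-data layer that makes every stage verifiable
without touching external databases:

1. **Variant I/O and filtering** (`read_vcf()`, `normalize_variants()`,
   `filter_high_quality()`, `vcf_to_alignment()`, `read_sam()`);
2. **Consequence annotation** (`annotate_variants()`, `translate_cds()`);
3. **Rule-based haplotype classification** (`hd1_rules()`,
   `classify_accessions()`, `collapse_haplotypes()`,
   `summarize_by_origin()`);
4. **Read-evidence structural screens** (`screen_large_insertion()`,
   `screen_small_insertion()`, `detect_terminal_repeats()`);
5. **Population genetics and phylogenetics** (`diversity_stats()`,
   `tajimas_D()`, `significance_of_D()`, `region_stats()`,
   `p_distance_matrix()`, `neighbor_joining()`, `bootstrap_support()`,
   `parsimony_network()`).

`run_pipeline()` composes all of them; `generate_cohort()` and its sibling
generators supply deterministic synthetic inputs.

## The rule table

The ten built-in rules (`hd1_rules()`) live on the IRGSP-1.0 Nipponbare
coordinate frame. Each rule is a (position, change-kind, payload) triple
plus a protein-consequence class: frameshift (`FS`) for the 1-, 2-, 4- and
43-bp deletions and the 1.9-kb insertion, premature stop (`STOP`) for the
four C/A-to-T/A nonsense SNPs. Classification (`classify_accessions()`)
matches normalized variant records against the rules:

* SNP rules need the exact alternate base at the exact position;
* deletion rules match on (position, length) only — callers represent
  deleted bases inconsistently, so records are first left-aligned by
  `normalize_variants()` and compared by their first deleted base;
* the large-insertion rule accepts any emitted insertion of at least 1 kb
  within 10 bp of the breakpoint **or** a `present` call from the read
  screen (short-read callers rarely assemble the full element, so the
  pipeline takes the union of the two evidence routes);
* a missing genotype at a rule site makes that rule *unevaluable*,
  reported separately from a confident non-match;
* heterozygous matches give the accession class `heterozygous-LOF`.

One rule (the 43-bp deletion) describes sequence that is absent from the
reference frame itself; it is classified by rule only and never
consequence-annotated against the real locus. On the synthetic locus the
tract exists, so it participates in annotation tests like any frameshift.

## The synthetic locus

The generators do not ship sequence data; they build it. `make_reference()`
draws a random 22,194-bp window (coordinates 9,326,376..9,348,569, the gene
plus and minus 10 kb) and embeds a two-exon gene whose geometry was derived
once from the published residue anchors of the stop rules: a 1,188-nt CDS
(395 residues plus stop) split 786 + 402 nt across two exons with a 637-bp
intron. Sixteen codons are pinned so that

* each rule site carries its published reference allele,
* each stop-rule SNP converts its codon to a stop at the published residue
  (Ser193, Gln206, Arg368, and the reference Arg at the fourth stop rule),
* each deletion tract is flanked by a different base, so the left-aligned
  representation of a planted deletion coincides with the rule coordinate.

Everything else is random under the seed, and fixed seeds give
byte-identical output. `plant_haplotype()` applies one rule to the
reference and returns the mutant genome, the expected normalized VCF
record, and a truth record for recovery tests. Large insertions receive a
synthetic LTR retrotransposon from `make_ltr_element()`: 1,901 bp with
448-bp identical terminal repeats around a random internal body — a
structural stand-in, not a reconstruction of the real element (whose
sequence is not republished here).

## Read simulation and the insertion screens

`simulate_read_pairs()` places reads by construction rather than through an
aligner: the screens consume alignment *signatures*, and constructing those
signatures directly keeps the tests hermetic. Fragments are uniform on the
mutant genome; insert lengths are normal with mean 250 bp and standard
deviation 25 bp, truncated at two standard deviations (200-300 bp). The
truncation is deliberate: the screens' premise is that ordinary pairs sit
"about 200 to 300 bp" apart, so the generator never emits a concordant
pair whose template length would trip the discordance test. Reads wholly
inside inserted sequence become unmapped-with-mapped-mate; reads crossing
an insertion boundary are soft-clipped at the boundary; reads spanning
small indels carry `I`/`D` CIGAR operations; everything else is a proper
pair with exact POS/PNEXT/TLEN.

`screen_large_insertion()` counts, among mapped reads starting within
`window` of the breakpoint, those with an unmapped mate, an out-of-range
|TLEN|, or a long soft-clip abutting the breakpoint, and calls three ways:
`present`, `absent`, or `inconclusive` (low coverage must never silently
mean absence). Two defaults deserve justification because simple geometry
fixes them:

* **window = 300 bp** (one insert length). Discordant mates of a true
  insertion cluster within one insert length of the breakpoint; widening
  the window only adds concordant reads to the denominator. With
  read-start density $\delta = d/\ell$ (depth $d$, read length $\ell$), a
  homozygous carrier's supporting fraction is roughly
  $\frac{2(\mu-\ell) \,\delta + 2(\ell - c)\,\delta}{2W\delta} \approx 0.4$
  at the defaults ($\mu = 250$, $\ell = 100$, clip minimum $c = 20$,
  $W = 300$); at $W = 500$ it falls to about 0.25.
* **f_min = 0.2**, half that geometric expectation, placing the threshold
  midway between the carrier expectation (~0.4) and the non-carrier
  expectation (0 by construction; a few percent in real data). At 20x the
  binomial noise of the fraction is about 0.04-0.05, so both calls sit
  more than four standard deviations from the threshold.

`screen_small_insertion()` shares the call logic but evaluates only the
reads that *span* the site (plus boundary-clipped reads): for an event
shorter than one read, non-spanning window reads cannot carry evidence
either way, and including them would cap even a perfect carrier's
supporting fraction at roughly $\ell/2W \approx 0.16$. Restricted to
spanning reads, a homozygous carrier scores near 1 and a non-carrier 0.

`detect_terminal_repeats()` formalizes the dot-matrix diagnosis of an LTR
element: the best local alignment (match +1, mismatch -1, gap -2) between
the 5' and 3' halves of the element, reporting the aligned length on each
side and the percent identity. On the synthetic element it returns
(448, 448, 100%); on a uniform-random 2-kb sequence the best local
alignment is far below any sensible `min_len`, so nothing is detected.

## Diversity statistics

`diversity_stats()` works on a cleaned alignment: `clean_alignment()` first
removes every column containing a gap or `N` in any row (complete
deletion, matching how the original analysis treated missing data). Over
$n$ sequences and $L$ clean sites it reports segregating sites $S$, total
mutations $\eta$ (a tri-allelic column adds 1 to $S$ but 2 to $\eta$),
mean pairwise differences $k$, per-site diversity $\pi = k/L$, theta per
sequence $\theta_{seq} = \eta/a_1$ with $a_1 = \sum_{i<n} 1/i$, and
Watterson's per-site $\theta_w = \theta_{seq}/L$.

Tajima's $D$ uses the $S$-based standardization
$D = (k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$. The survey's summary
statistics are reported from $\eta$ while $D$ is attributed to the
$\pi$-vs-$\theta_w$ discrepancy; this package resolves that accounting by
using $S$ inside $D$ (the convention of the software the original analysis
used) and $\eta$ for the reported estimators. On infinite-sites synthetic
data the two coincide ($S = \eta$), which the property tests assert.

Significance classes come from the beta-distribution approximation of the
null: $D$ is rescaled onto its analytic support $[D_{min}, D_{max}]$ for
the given $n$, a beta density with mean 0 and variance 1 on that support
supplies two-tailed mass, and classes are assigned at 0.05 / 0.01 / 0.001.
This reproduces all eleven starred categories of the published
selection-pressure table from their printed $(D, n)$ pairs — verified
numerically before the implementation was frozen. A coalescent-simulation
p-value was considered and rejected as the default because the starred
output being reproduced was itself produced by the beta approximation.

The neutral simulator (`simulate_neutral_alignment()`) is a single-locus
Hudson coalescent with infinite-sites mutations: exponential coalescence
times with rate $\binom{k}{2}$, Poisson$(\theta/2 \times$ tree length$)$
mutations placed proportionally to branch length, each at a distinct
uniform site. It supplies the null for the neutrality tests: over 500
replicates the mean $D$ is within 3 standard errors of 0 and mean $\pi$
within 3 standard errors of $\theta/L$. No recombination is modeled (the
surveyed region is analyzed as one locus) and no sequencing error; a green
neutrality test therefore establishes correctness of the estimators, not
robustness to artifacts of real pipelines.

## Alignments, trees, networks

`vcf_to_alignment()` uses a SNP-only dialect: each accession's row is the
reference slice with homozygous SNPs substituted; heterozygous or missing
genotypes and all indel footprints are masked `N`. Rows therefore stay
reference-length, and the masking agrees with the downstream "gaps as
missing data" treatment. p-distances are computed by `ape` (`model =
"raw"`) under pairwise or complete deletion; a pair with zero comparable
sites is an error naming the pair, never a silent 0.

`neighbor_joining()` delegates to `ape::nj()` (closed form at three taxa)
and post-processes negative branch lengths — an artifact of the NJ length
formulas — by clamping to zero and moving the deficit to the sibling
branches, preserving total tree length. Bootstrap supports
(`bootstrap_support()`) resample columns, rebuild the tree per replicate,
and map split frequencies onto the full-data tree (not onto a consensus;
with the published 1,000 replicates the two presentations rarely differ,
and the full-data tree is what the figure shows).

`parsimony_network()` is a fixed-limit statistical-parsimony (TCS-style)
construction. Distances count differing sites, excluding sites missing in
either haplotype. Pairs are processed distance-1 first, then distance-2,
ties broken by descending combined frequency then lexicographic labels
(the high-frequency-first convention; the original publication is silent,
so this tie-break is a documented decision). A pair already connected at
an equal-or-shorter path length is skipped, so loops occur only when a
distance-1 edge closes them; each accepted distance-2 connection inserts
one inferred intermediate node of frequency 0 (its sequence takes the
first differing site from one side — any choice on the path is equally
parsimonious). The connection limit defaults to 2 steps, the published
setting; the classical 95% parsimony-probability limit is intentionally
not computed. Haplotype sets more than `limit` steps apart stay in
separate components, which is exactly how the published network separates
its three groups.

## Tunable parameters

| parameter | default | where | meaning |
|---|---|---|---|
| `min_gq`, `min_ad` | 20, 4 | `filter_high_quality()` | strict `>` thresholds of the high-quality screen |
| `insert_mu`, `insert_sigma` | 250, 25 bp | `synth_config()` | insert-size model, truncated at 2 sigma |
| `depth` | 30x | `synth_config()` | mean simulated coverage |
| `theta` | 8 / region | `synth_config()` | background mutation parameter of the cohort |
| `window` | 300 bp | `screen_config()` | breakpoint window of the screens |
| `insert_range` | 200-300 bp | `screen_config()` | concordant template-length band |
| `clip_min`, `clip_tol` | 20, 10 bp | `screen_config()` | soft-clip evidence thresholds |
| `k_min`, `f_min` | 3, 0.2 | `screen_config()` | minimum support count and fraction |
| `limit` | 2 steps | `parsimony_network()` | parsimony connection limit |
| `reps` | 100 (tests), 1,000 (published) | `bootstrap_support()` | bootstrap replicates |

## Known limitations

* The synthetic locus mimics the surveyed gene's geometry and rule sites
  but not its actual sequence; consequence annotations on real data
  require the real reference and gene model (GFF3 in, via
  `read_gene_model()`).
* The read simulator models neither sequencing error nor mapping
  ambiguity; screen performance on real BAMs will be bounded by mapping
  quality in repetitive regions, which is why `read_sam()` exposes
  `mapq_min`.
* The published per-accession variant matrices and the 3K-cohort-wide
  carrier counts are not redistributable or recomputable offline; the
  collapsing machinery is exercised on a synthetic stand-in matrix
  (`synth_s7_like_matrix()`) constructed to the published summary
  structure (40 accessions in 5 groups with 34 in the first two; 262 in
  156 groups with 28 in the first two; 41 variable sites, 22 in the ORF).
  A green collapsing test establishes the collapsing logic, not the
  content of the original matrices.
* Splice-site consequences are not annotated (no rule requires them);
  intronic variants are `noncoding`. Indels spanning an exon boundary are
  an error rather than a guess.

## Reproducibility

Every generator and every stochastic analysis takes an explicit seed;
`run_pipeline()` stamps the seed and a configuration hash into its output
manifest, and re-running with the same configuration is byte-identical.
`scripts/acceptance.R --seed N --out results/acceptance.json` runs the
full synthetic survey end to end against the installed package.
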