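---
title: "Methods: panel QC, diversity estimation, parentage and mtDNA rules"
author: "bisonpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel QC, diversity estimation, parentage and mtDNA rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisonpanel)
```

## The data model

Everything in the package flows through a single container, the
`genotype_matrix`: a samples × loci matrix of diploid ALT-allele dosage
codes (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
alternate, `NA` = missing), with locus annotation (id, chromosome, 1-based
position, reference/alternate allele, source, mitochondrial flag), sample
annotation (id, population, optional known dam/sire), and an optional
per-call read-depth matrix. Dosage is counted against the ALT allele
throughout; wherever an allele frequency $p$ appears below it is the ALT
frequency, and MAF is $\min(p, 1-p)$. VCF ingestion (via `vcfR`) keeps
only biallelic single-base SNP records and counts the rest; the writer
produces plain VCF 4.2 so that a write/read round trip reproduces every
dosage code and coordinate exactly. Final-report ingestion maps vendor
allele pairs against the locus definitions on a single strand dialect:
letters matching neither allele raise an error listing the offending rows,
because silently recoding a strand flip would corrupt every downstream
frequency.

## The QC cascade

The marker-selection pipeline is a sequence of per-locus filters, each
returning a `stage_report` whose counts must reconcile
($n_{in} = n_{out} + \sum \text{dropped by reason}$):

| stage | rule | boundary reading |
|---|---|---|
| WGS candidates | MAF > 0.3, missingness < 0.5, then ≥ 1.2 Mbp spacing | both bounds strict |
| chip candidates | MAF > 0.1, no missing data | strict; any `NA` drops |
| GBS validation | sample call rate ≥ 0.5 first; then MAF ≥ 0.1, HWE $p$ ≥ 0.005, mean depth > 10, missingness < 0.15 | "at least 0.1" is inclusive; depth strict |
| chip evaluation | sample call rate ≥ 0.9, locus call rate ≥ 0.9, duplicate removal, monomorphic removal | call-rate bounds inclusive at 0.9 |

Threshold strictness follows the literal wording of each criterion; the
boundary cases (MAF exactly 0.3, missingness exactly 0.5, HWE $p$ = 0.004,
mean depth exactly 10, call rate 0.89) are pinned by tests. Two genuinely
open choices were settled as follows. The *depth* criterion is read as the
mean depth across called genotypes at a locus, since per-call depth
thresholds belong to the upstream variant caller, which is out of scope.
*Spacing* uses a greedy left-to-right scan per chromosome (keep the first
locus, then every locus at least 1.2 Mbp beyond the last kept one);
chromosomes are independent, and the scan requires input grouped by
chromosome with non-decreasing positions. Greedy thinning is not
MAF-aware; that matches a pipeline whose spacing criterion is purely
positional. When duplicates are removed, the surviving member of a pair is
the one with the higher call rate, ties broken lexicographically by id — a
deterministic rule where the procedure itself only says "removed".

The Hardy–Weinberg test is the exact conditional test (the
Wigginton–Cutler–Abecasis algorithm): conditioning on the observed allele
counts, the two-sided $p$ sums the probabilities of all heterozygote
counts no more probable than the observed one, with no mid-$p$ correction.
One-sided variants (heterozygote deficit or excess) are available behind a
flag because it is unknowable from a bare threshold whether the original
filter was one- or two-tailed; two-sided is the de-facto default of the
tools that popularised the test. The implementation is checked against a
brute-force enumeration oracle on every genotype table with $n \le 20$.

## Diversity and differentiation estimators

*Observed heterozygosity* is the heterozygote fraction among called
genotypes. *Gene diversity* uses Nei's unbiased within-population
estimator
$$H_S = \frac{n}{n-1}\Bigl(1 - p^2 - q^2 - \frac{H_O}{2n}\Bigr),$$
algebraically $2pq\,\frac{n}{n-1} - \frac{H_O}{2(n-1)}$. The *individual
inbreeding coefficient* is the homozygosity-excess moment estimator
$F = (O_{hom} - E_{hom})/(L - E_{hom})$ with the $2N/(2N-1)$ small-sample
correction inside $E_{hom}$, computed against whole-cohort frequencies and
averaged per population. *Allelic richness* is rarefied to $g$ gene
copies, $A_R = \sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$, with $g$ the
minimum called gene copies across populations at the locus; loci with
$g < 2$ are excluded from the average. Per-population averages *include*
loci monomorphic within that population (contributing $H_O = H_S = 0$,
$A_R = 1$), with the monomorphic count reported separately —
population-level summaries then remain comparable across herds genotyped
on the same panel.

$F_{IS}$ is the ratio of sums $1 - \sum_l H_{O,l} / \sum_l H_{S,l}$ over
loci with defined $H_S$; its confidence interval is the 2.5/97.5
percentile interval of the statistic over 1000 bootstrap resamples of loci
(loci, not individuals, because the statistic is a loci-average for a
fixed cohort). Under random-mating simulations the point estimate is
centred on 0 and the 95% interval covers 0 at the nominal rate (checked
over 100 seeds with a binomial tolerance).

Pairwise $F_{ST}$ is the Weir–Cockerham (1984) two-population $\theta$,
with the standard variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals) accumulated
as a ratio of sums across loci; loci with fewer than two called genotypes
in either population, or a zero total component, are skipped. The
estimator variant actually used by any given published table is often
unrecoverable; $\theta$ is stated explicitly here, and a Nei/G~ST~-style
$1 - \sum H_S / \sum H_T$ variant is exposed via `method = "nei"` for
sensitivity analysis — for two demes it is systematically smaller than
$\theta$ (roughly half, at moderate divergence), which is why the two are
never mixed in one table. Validation compares $\theta$ on Balding–Nichols
simulations against a truth-frequency oracle: the large-sample limit of
$\theta$ evaluated directly on the simulator's known population
frequencies, $\sum_l s_l^2 \big/ \sum_l (\bar p_l \bar q_l + s_l^2/2)$
with $s^2 = (p_1-p_2)^2/2$.

## PCA

Missing calls are imputed with the locus mean dosage, loci are centred by
$2\hat p$ and, by default, scaled by $\sqrt{2\hat p \hat q}$ (the common
variance standardization for genotype PCA; raw centring is available via
`scale = FALSE`). Fixed loci are dropped, the samples × samples covariance
of the standardized matrix is eigendecomposed, and coordinates are
eigenvectors scaled by the square roots of their eigenvalues. Because an
eigenvector's sign is arbitrary, the largest-magnitude loading of each
component is made positive, so repeated runs and sample permutations give
reproducible output (up to that convention, coordinates are
permutation-invariant; the trace identity $\sum \lambda_i$ = total
standardized variance is enforced to 1e-8 relative in tests).

## Identity and parentage

Duplicate detection uses pairwise discordance over shared called
autosomal loci; pairs below 1% discordance are flagged and merged into
connected components, since a re-genotyped animal can appear more than
twice. Pairs with no shared called loci are undefined and never flagged.

Non-exclusion probabilities are computed by exhaustive enumeration over
genotype configurations under HWE at each locus: the probability two
random animals share a genotype (identity), that a random candidate
shares an allele with a random offspring (first parent), that a random
candidate is Mendelian-compatible as the second parent given the true
first parent (second parent), and that a random pair could jointly
produce the offspring (parent pair). Enumeration, rather than transcribed
closed forms, is the implementation because it is auditable against the
model definition; the closed-form polynomials (derived independently by
symbolic enumeration) serve as the test oracle, with agreement to 1e-12.
Combined panel values are products across loci accumulated in log10, so
quantities of order $10^{-300}$ survive; cohort ALT frequencies from
called genotypes feed the calculation.

Parentage assignment replaces likelihood-based pedigree reconstruction
with opposing-homozygote exclusion: a candidate passes iff its
opposing-homozygote count against the offspring is at most
$\lceil 2 \varepsilon L \rceil$ for error rate $\varepsilon$ (the factor 2
because either member of the pair can carry the error), and the final
call is the unique passer with the minimal count — ties are reported as
ambiguous rather than broken. The likelihood machinery this replaces
resolves multigeneration pedigrees; for the dam–calf verification this
package targets, exclusion is sufficient and fully transparent. At the
panel's scale (734 loci, $\varepsilon = 0.01$, threshold 15), a true dam
accumulates ~4 opposing homozygotes from error while an unrelated animal
at informative frequencies accumulates ~50, so the two distributions are
far apart; a binomial-quantile threshold is available behind a flag. A
within-herd MAF > 0.3 subset helper mirrors the practice of restricting
to highly informative loci inside a single herd.

## The simulator, and what passing tests do and do not show

The simulator generates the statistical structure the analyses assume:
ancestral ALT frequencies uniform on (0.1, 0.5) by default (a designed
panel is ascertained for common variants, which is why the lower bound is
the panel's own MAF criterion), per-population frequencies from the
Balding–Nichols model (Beta with parameter $F_k$, chosen because it maps
one knob onto realized differentiation: two populations simulated at
$F$ give $\theta$ concentrating near $F$), founder genotypes with optional
inbreeding $f$ ($P(\text{het}) = 2pq(1-f)$), Mendelian offspring, a
symmetric error model (an erroneous call becomes one of the other two
codes uniformly — the simplest model consistent with a single scalar
error rate; it is not an allele-dropout model), independent missingness,
and mitochondrial haplotypes copied from bison-Clade-I / bison-Clade-II /
cattle templates with optional heterozygous "NUMT" noise. Default cohort
shape is ten herds with the sampled sizes of a real bison survey
(48–272 animals, 734 SNPs), divergence parameters spanning the observed
$F_{ST}$ range, 1% error and 2% missingness.

What the simulator deliberately omits: linkage disequilibrium (loci are
independent, so spacing filters are exercised only positionally),
ascertainment drift between discovery and production cohorts, batch and
plate effects, allele-dropout error structure, and real NUMT biology.
Passing the validation suite therefore demonstrates estimator correctness
under the stated generative model — not robustness to every artifact of
production chip data. Conversely, the rule-based components (QC
thresholds, exclusion logic, mtDNA rules) are exact and carry over
unchanged.

The mitochondrial diagnostic panel shipped as `default_mt_panel()` is
synthetic: the identities and alleles of the real 13 diagnostic sites
live in prior mitogenome literature and must be supplied as an
`mt_panel_def` when analysing real data. The NUMT screen's boundary is
read inclusively (heterozygous across ≥ 90% of called samples removes the
locus), with a strict-inequality switch, and heterozygosity is measured
among called samples.

## Problem sizes and numerical choices

The validation suite simulates at the panel's natural scale — 700–734
loci, 60–250 animals per cohort, 20–100 seeds per calibration claim,
1000-replicate bootstraps — which keeps the full suite under a minute of
simulation-heavy work while leaving Monte-Carlo tolerances (3 standard
errors, or a binomial band for coverage) meaningful. Degenerate inputs are
contracts, not warnings: empty matrices, candidate-free assignments,
all-missing loci, $g > N$ rarefaction and $p \in \{0,1\}$ non-exclusion
all raise errors naming the violated precondition. Ties are always
resolved by a documented deterministic rule (lexicographic ids for
duplicate survivors, ambiguity for tied parentage passers, +1 bp shifts
for simulated position collisions).

## Known limitations

Multi-allelic markers are out of scope throughout (the panel is biallelic
by construction); hierarchical F-statistics, $F_{ST}$ confidence
intervals, sibship reconstruction and admixture models are not
implemented; and the final-report reader supports a single strand
dialect, failing loudly rather than attempting strand inference.
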