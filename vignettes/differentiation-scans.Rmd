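---
title: "Derived allele frequency differentiation scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derived allele frequency differentiation scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dafscan)
```

## The statistic and its assumptions

`dafscan` screens biallelic SNPs for strong allele-frequency
differentiation between two population groups. The statistic is the
absolute difference of pooled derived allele frequencies,
$\Delta\mathrm{DAF} = |\,\mathrm{DAF}_A - \mathrm{DAF}_B\,|$, computed
per SNP after polarizing the reference/alternate alleles into
ancestral/derived states. The screen is an outlier ranking, not a
hypothesis test: no sampling distribution is assumed and no
multiple-testing correction is applied. Its power and false-positive
behaviour are therefore characterized empirically, against simulated
data with known truth (below).

Polarization is annotation-first: a SNP's `AA` INFO tag wins whenever it
names one of the site's two alleles. Ensembl-style qualifiers after a
`|` are stripped, and lower-case (low-confidence) calls are accepted by
default (`accept_lowercase` turns this off). Sites without a usable tag
fall back to a primate outgroup consensus, operationalized strictly: the
majority allele among non-missing primate alleles must be supported by
at least two species (`min_species`), be a strict majority, and match
one of the site's alleles; ties, single-species support and third
alleles leave the site unassigned. Unassigned SNPs are excluded from the
scan but reported with a reason, so the variant accounting always sums.
The strictness errs toward dropping sites over fabricating ancestral
states; `min_species` is exposed because the right floor depends on how
many outgroup species the user's table carries.

## Group pooling

Group frequencies pool allele counts, not population frequencies:
$\mathrm{DAF}_g = \sum_p \mathrm{dAC}_p / \sum_p \mathrm{AN}_p$. Count
weighting equals the derived frequency of the pooled sample and keeps
populations with few called alleles from dominating. Because public
per-population counts differ greatly in size (the non-African group
spans five populations of very different sizes), the unweighted mean of
population frequencies is also available (`weighting = "mean"`) as a
sensitivity mode; on the default simulated data, where every population
has equal `AN`, the two pooling modes coincide.

## Outlier selection

Fixed mode takes the supplied cutoff (default 0.20) as the threshold;
percentile mode takes the inclusive nearest-rank empirical percentile of
the observed $\Delta$DAF values. Selection is inclusive
(`delta_daf >= threshold`), so ties at the threshold are all selected —
in percentile mode the selected fraction can therefore exceed the
nominal tail by at most $1/N$ plus ties. Histograms use right-open bins
with a closed last bin so that 1.0 is counted; default bin widths are
0.05 for $\Delta$DAF and 0.10 for per-group DAF distributions, both
configurable.

## Consequence severity

The most severe consequence per variant is ranked against an embedded,
versioned copy of the Ensembl ordered consequence list (41 Sequence
Ontology terms, most severe first, each with an impact class). Embedding
the table keeps runs reproducible offline; the version string is written
into output headers, and an unknown term raises an error naming the term
so a table-version mismatch is caught rather than silently mis-ranked.
Outliers survive the filter when their most severe term is
`missense_variant` or any HIGH-impact term.

## F_ST estimators

The per-site F_ST between two populations is computed from derived
allele counts with either the Hudson estimator,
$$\hat F_{ST} = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2) + p_2(1-p_1)},$$
with $n$ the number of called alleles, or the Weir–Cockerham
two-population variance-components estimator $a/(a+b+c)$. Since the
pipeline works from allele counts rather than genotypes, the
heterozygote frequency in the Weir–Cockerham components is taken at its
Hardy–Weinberg expectation $h_i = 2p_i(1-p_i)$. Weir–Cockerham is the
default (it is the common default of population-genetics toolchains) and
the estimator name is always recorded in output, because the two differ
at small or unbalanced sample sizes; on balanced samples of 1,000
alleles they agree within 0.02. Negative estimates are reported as-is
and flagged, never clamped; sites monomorphic in both populations for
the same allele are undefined.

## LD and window selection

$r^2 = D^2 / [p_A(1-p_A)p_B(1-p_B)]$ with $D = p_{AB} - p_A p_B$ is
computed from phased haplotypes only; an EM-based genotype mode is out
of scope, so input VCFs for haplotype work must carry phased `|`
genotypes. Monomorphic columns give an undefined $r^2$.

Windows around a focal SNP are bounded by LD: scanning outward on each
flank, the boundary is the outermost site with $r^2 > 0.2$ against the
focal SNP (configurable `r2_max`); if no flanking site exceeds the
bound, the window is the focal site alone. The rule is stated over the
whole flank rather than stopping at the first low-LD site, because LD
profiles are noisy and a single interstitial low-$r^2$ site should not
truncate an otherwise linked region. Fixed kb-sized windows are
available as presets (`window_kb`) for comparability with analyses that
chose window sizes in base pairs.

## Median-joining networks

Haplotypes over the window are collapsed into distinct bit strings with
per-population counts, then connected by the epsilon-relaxed minimum
spanning network: distinct Hamming weights are processed in increasing
order, and a link of weight $d$ is kept when its endpoints are not yet
connected by kept links of weight $\le d-1-\varepsilon$. With
$\varepsilon = 0$ (the default of median-joining software, exposed as a
parameter) this is the union of all minimum spanning trees. Median
vectors — for binary states, the site-wise majority of a triple, which
minimizes the summed Hamming distance to the triple — are added for
every node with two network neighbours whose majority string is not yet
present, and the construction repeats until closed (a cap of 10 cycles
guards pathological inputs and is logged if hit). Finally, obsolete
medians (degree $\le 2$ whose removal does not lengthen the minimum
spanning tree of the remaining nodes) are pruned to a fixed point.

Adding *all* triple medians rather than only cost-minimal ones is a
deliberate choice: on every tested small instance it makes the network
embed a minimum Steiner (most parsimonious) tree of the observed
haplotypes, which is the property the tests verify against an exhaustive
enumeration oracle; a cost-greedy variant was observed to miss required
medians on some instances. The price is more median nodes on reticulate
data, which matters for display but not for the embedded-tree property.
Node order is canonicalized lexicographically, so construction is
deterministic and permutation-stable; exports (GraphML, DOT, node table)
are byte-identical across runs on identical input. Only binary
ancestral/derived states are supported — windows come from biallelic
SNPs by construction.

## The synthetic generator

The generator emulates a two-group comparison in the Balding–Nichols
model: each site draws an ancestral derived-allele frequency
$p \sim U(0.05, 0.95)$, and every population drifts independently with
$\mathrm{freq} \sim \mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$,
whose mean is $p$ and variance $F\,p(1-p)$. Spiked loci instead centre
the two groups at $0.5 \mp \Delta p/2$ and drift populations around
their group mean, keeping the true between-group difference
interpretable. Observed counts are binomial draws of $2n$ alleles per
population, written as a gnomAD-style sites-only VCF with `AA` tags on a
configurable fraction of sites (default 0.8) and a primate table
covering the rest; indel and multiallelic decoys exercise the SNP
filter. The ancestral allele lands on ref or alt with equal probability
so both polarization orientations are exercised.

The default configuration — one group-a population against five group-b
populations, 500 diploids each, 10,000 sites at $F = 0.01$, 100 loci
spiked at $\Delta p = 0.5$ — was chosen once as a realistic desk-scale
analogue of a large two-group comparison: $F \approx 0.01$ matches
drift between closely related human populations within a continent-scale
group, 1,000 alleles per population gives binomial noise of roughly
$\pm 0.05$, and a 1% spike fraction keeps the outlier tail sparse. Under
these conditions the 0.20 cutoff recovers $\ge 95\%$ of spiked loci with
$\le 1\%$ null false positives (the tests assert both), and the
empirical 99th percentile of null $\Delta$DAF lands near the fixed
cutoff, consistent with treating 0.20 as an extreme-tail criterion.

What the generator does **not** emulate: recombination-driven LD decay
(haplotype columns are independent unless the simple copy-with-mutation
block mode is enabled, which creates a rectangular LD block rather than
a realistic decay curve), ascertainment bias, sequencing or genotyping
error, population substructure within groups beyond Balding–Nichols
drift, and real gene annotation. Passing tests therefore demonstrate the
statistical machinery under a clean generative model, not performance on
real cohort data.

## Degenerate inputs and numerical conventions

Sites with `AN = 0` in a population carry an undefined frequency and
contribute nothing to pooled counts; records where an entire group has
no called alleles are dropped with a reason. `AA` tags naming a third
allele fall through to the primate consensus (with a logged note) rather
than erroring. Multiallelic records are dropped whole and counted
separately from indels — splitting them would make single-derived-allele
polarization ambiguous — and the conservation identity
`total = retained + indels + multiallelic` is asserted on every run.
Percentiles use the inclusive nearest-rank definition. All simulation
randomness flows from the single seed in the configuration; emitted VCFs
embed the seed in their headers, and reports carry no timestamps, so
identical configurations give byte-identical outputs.

## Problem sizes used by the tests and drivers

The bundled analyses run at the default study scale (10,000 sites, six
populations of 500 diploids; seconds on one core). Oracle-equivalence
checks run 1,000 random small instances against brute-force formula
implementations; network-optimality checks enumerate exhaustive Steiner
trees for up to four observed haplotypes over up to six sites, and
median-vector minimality is checked exhaustively up to length 12.

## Known limitations

Chromosome labels are matched by exact string equality after optional
`chr`-prefix stripping; haplotype windows assume a single chromosome.
Multiallelic sites are not decomposed. The Weir–Cockerham estimator uses
Hardy–Weinberg heterozygosity because genotype-level heterozygote counts
are not retained. Median-joining networks can grow many median nodes on
highly reticulate data; for display-oriented use, larger `epsilon`
values and smaller windows are advisable.
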