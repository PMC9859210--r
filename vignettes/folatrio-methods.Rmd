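---
title: "Methods: family-based gene-folate interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based gene-folate interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folatrio)
```

## The design and the model

folatrio analyses case-parent trio studies of congenital heart defects
in which the exposure of interest is maternal periconceptional folic
acid supplementation, a family-level binary. Association is inferred
from transmission distortion within families, not from a case-control
contrast, which makes the fetal-effect estimates robust to population
stratification.

At a biallelic SNP, write $m, f, c \in \{0, 1, 2\}$ for the maternal,
paternal and child counts of the risk (minor) allele. Only 15 ordered
triples $(m, f, c)$ are compatible with Mendelian transmission; these
cells, cross-classified by exposure stratum, are the sufficient
statistic. Within a stratum, the expected count in cell $(m, f, c)$ is
modelled log-linearly as

$$\mu_{mfc} = e^{\gamma_{S(m,f)}}\; T(c \mid m, f)\;
  e^{\beta_f c + \beta_m m},$$

where $S(m,f)$ indexes the six unordered parental mating types (whose
parameters $\gamma_s$ absorb the population mating-type frequencies and
the ascertainment constant), $T$ is the Mendelian transmission
probability, and $e^{\beta_f}$, $e^{\beta_m}$ are the per-allele fetal
and maternal relative risks. This is the classical
Weinberg–Umbach extension of the transmission log-linear model: the
maternal effect is identified by the asymmetry between $m$ and $f$
across the ordered cells of a mating type, and no control families are
required. A codominant coding (dosage indicators instead of the linear
terms) is available where per-allele multiplicativity is in doubt.

Fitting is by Poisson regression of the 15 cell counts on the
mating-type factor and the genetic design, with $\log T$ as offset —
the Poisson and multinomial maximum-likelihood estimates coincide
because the $\gamma_s$ saturate the totals. Control trios are excluded
from the default likelihood; an option lets complete control trios
inform the mating-type parameters only (hybrid design), never the
genetic effects.

### Incomplete families

Dyads and singletons (a substantial fraction of real trio studies)
enter through an EM algorithm: the E-step distributes each incomplete
family over the complete cells compatible with its observed members in
proportion to the current $\mu$, the M-step refits the Poisson
regression on the completed counts. Missingness is assumed MCAR per
family member. The observed-data log-likelihood — complete cells plus
the aggregated probability of each compatibility set — is evaluated at
every iteration and asserted non-decreasing; convergence is declared
when it moves by less than `em_tol` ($10^{-8}$ by default, at most 500
iterations). With no incomplete family the EM reduces exactly to the
complete-data fit, and a family whose compatibility set is a single
cell is algebraically identical to a complete trio; both identities are
enforced in the test suite at $10^{-10}$.

Standard errors come from the numerically differentiated observed-data
log-likelihood (central differences, step $10^{-5}$), with the
multinomial scale redundancy removed by fixing the first mating-type
parameter at zero. This choice is simpler than Louis' identity and is
directly checkable against the complete-data Poisson information; the
two agree when nothing is missing.

### The interaction test

The exposure-stratified fits yield $\hat\beta^{(0)}$ (unexposed) and
$\hat\beta^{(1)}$ (exposed). The primary interaction statistic is the
Wald contrast
$z = (\hat\beta^{(0)} - \hat\beta^{(1)})/\sqrt{SE_0^2 + SE_1^2}$ per
genetic parameter, because published per-stratum RR/CI columns can be
recombined into exactly this contrast. A likelihood-ratio test
comparing the joint model with stratum-specific genetic effects against
shared effects (df = number of genetic parameters) is computed as a
cross-check; the two agree closely away from boundary cases. Flagged
stratum fits (non-convergence, separation, singular information) mark
the result unreliable rather than dropping the variant.

## Two-phase meta-analysis and BFDP

Phase estimates are combined by fixed-effect inverse-variance
meta-analysis on the log-RR scale. When only printed RR and 95% CI are
available, the SE is recovered as
$(\log \mathrm{CI}_{hi} - \log \mathrm{CI}_{lo})/(2 z_{0.975})$; this
bridge makes published meta columns recomputable from their own phase
columns, which the acceptance script exploits.

Noteworthiness is ranked by the Bayesian false-discovery probability.
With estimate variance $V$ and a normal prior with variance $W$ on the
log-RR under the alternative, the approximate Bayes factor in favour of
the null is
$\mathrm{ABF}_{01} = \sqrt{(V+W)/V}\, \exp\!\big(-z^2 W / (2(V+W))\big)$
and $\mathrm{BFDP} = \mathrm{ABF}_{01}\mathrm{PO}_0 /
(\mathrm{ABF}_{01}\mathrm{PO}_0 + 1)$. The prior is not recoverable
from published summary tables, so the package defaults are stated
explicitly and attached to every output: prior association probability
$\pi_1 = 0.05$ and prior SD $\log(1.5)/1.96$ (95% of alternative mass
on RR between $1/1.5$ and $1.5$). An association is flagged when
$p_{meta} < 0.05$ **and** $\mathrm{BFDP}_{meta} < 0.8$; combining
phases shrinks $V$, so two individually unremarkable same-sign phases
can become noteworthy after meta-analysis.

## De novo enrichment

A de novo candidate is a high-confidence Mendelian violation: both
parents homozygous reference, child heterozygous, passing configurable
genotype-quality, depth, parental-alt-read and population-frequency
filters (defaults GQ ≥ 20, DP ≥ 10, 0 parental alt reads, AF < 1%;
published pipelines rarely print their exact values, and the defaults
make no claim to reproduce any particular candidate count). The
regional null rate $p_0$ is the per-trio probability of at least one
true event in the targeted regions, $1 - \prod_b (1 - \mu_b)$ over
per-base rates, evaluated with `log1p`/`expm1`.

Enrichment is the exact upper binomial tail
$P(X \ge k),\, X \sim \mathrm{Bin}(n_{trios}, p_0)$, accumulated in log
space (log-sum-exp) so that magnitudes of order $10^{-67}$ retain full
relative accuracy; `stats::pbinom` serves as an independent oracle in
the tests. This convention treats trios as Bernoulli units — $k$ counts
mutation-carrying trios — which conflates mutations with trios when a
trio carries several; the package reproduces the convention as used in
practice and documents it here.

## Rare-variant region tests

Within each region, variants are restricted to founder MAF < 5%
(computed from parents only, avoiding transmission-induced bias in the
filter; strictly below the threshold).

*Burden TDT.* Over all (case family × retained variant) pairs with a
heterozygous parent, transmissions $T$ and non-transmissions $NT$ of
the minor allele are counted; $z = (T - NT)/\sqrt{T + NT}$, with an
exact two-sided binomial p for $T + NT \le 100$ and a normal
approximation beyond. This is one canonical member of the RV-TDT
family; published implementations differ in detail, so region p-values
from restricted data are not reproduction targets.

*Family-based kernel test.* Per variant the within-family score is
$S_j = \sum_{fam} (c_j - E[c_j \mid m_j, f_j])$, and
$Q = \sum_j w_j^2 S_j^2$ with Beta(1, 25)-density weights at the
founder MAF (the SKAT default, upweighting the rarest variants). The
null distribution is a scaled chi-square with mean and variance matched
to the exact conditional transmission moments (Satterthwaite); each
heterozygous parent contributes variance 1/4 and fourth cumulant
$-1/8$. Because only heterozygous parents transmit stochastically, the
within-family permutation null is exactly $S_j^* =
\mathrm{Bin}(n_{het,j}, 1/2) - n_{het,j}/2$, which the permutation
implementation draws directly; the permutation p is reported alongside
and is authoritative whenever the two disagree by more than a factor of
two. Satterthwaite was chosen over the exact chi-square mixture for
simplicity; with tens of independent rare variants the two are
indistinguishable at test scale, as the permutation cross-check
verifies.

The region scan applies the Bonferroni level $0.05/n_{regions}$
($0.0038$ at 13 regions).

## The simulator

`simulate_trios()` emulates the study conditions: parental genotypes
under HWE at the configured allele frequency, children by Mendelian
transmission, exposure assigned per family independently of genotype
(the model's gene-environment independence assumption), and case
ascertainment by rejection sampling — a pregnancy is retained as a case
with probability equal to its penetrance
$f_0 \cdot RR_f^c \cdot RR_m^m$ for its stratum. Rejection sampling is
exact under any penetrance without distributional algebra; penetrances
above 1 are rejected at configuration time.

Defaults reproduce the replication-phase composition: 154 supplemented
and 99 unsupplemented case families, 40 control families, allele
frequency 0.3, fetal per-allele RR 1.41 (unexposed) and 0.74 (exposed)
— the lead-SNP effect sizes — with null maternal effects. The baseline
risk defaults to 0.05, a realistic congenital-defect-scale figure that
keeps every penetrance below 1 at these effect sizes; under
case-only ascertainment the estimates do not depend on it, it only
scales the rejection rate. Member-level missingness (creating dyads and
singletons), per-call missingness, random genotype perturbations and
de novo injections are separate, seeded operators that record ground
truth for detector validation.

`simulate_rare_region()` draws founder rare variants at MAFs in
[0.005, 0.045) and distorts transmission at causal variants: a
heterozygous parent transmits the minor allele with probability
$\mathrm{logit}^{-1}(e_j)$, default effect $\log 2$, with same-signed
or mixed directions. This emulates the ascertainment-induced
transmission distortion directly rather than simulating penetrance,
which is the quantity the family-based tests actually consume.

What the simulator does **not** emulate: linkage disequilibrium between
common SNPs, population admixture, genotyping-error structure beyond
MCAR/uniform perturbation, and read-level noise. Passing tests
therefore validate the statistical machinery under the stated
design, not robustness to those real-data features.

## Numerical and design choices

- Multiallelic VCF records are split into biallelic records, dosages
  recoded against each alternate allele; half-missing genotypes are
  missing. Coordinates are 1-based inclusive; BED input is converted
  from 0-based half-open.
- A missing INFO annotation skips the corresponding hard-filter
  criterion (rank-sum annotations are only emitted when computable);
  hard-filter inequalities are strict.
- QC order: Mendelian masking first (the whole trio's genotypes at the
  offending site are set to missing), then the 5% Mendel-rate caps (per
  SNP and per family, independent switches, both testing `rate >=
  cap`), then the 95% SNP and 70% sample call-rate floors — masking
  changes call rates, so it must precede them.
- The two-sided Fisher convention is the sum of all tables, under the
  hypergeometric null with fixed margins, no more probable than the
  observed one (the common software default, consistent with published
  demographic tables at 2 decimal places).
- Ties in minor-allele determination break toward the alternate
  allele. Mendelian-inconsistent trios reaching the tabulator (QC
  should have masked them) are excluded with a warning.
- Separation in a stratum fit is flagged at $|\hat\beta| > 10$; flagged
  fits propagate an `unreliable` marker instead of numbers silently.

## Validation problem sizes

The test suite validates parameter recovery with 100 replicates of
10,000 unexposed trios at true fetal RR 1.41 (95% CI coverage ≥
93/100); type-I error of the interaction LRT and of the burden TDT
with 2,000 null replicates each (rejection in [0.04, 0.06] at
$\alpha = 0.05$). The LRT calibration runs at 500 trios per stratum:
its chi-square reference is an asymptotic statement, and with twelve
nuisance mating-type parameters the LRT is mildly anticonservative at
the study's own stratum sizes, as is typical for likelihood-ratio
tests at small n — a property of the test, not of the implementation,
which is verified against an independent optimizer. The suite further
checks the log-linear MLE against a brute-force
profile-likelihood grid (step $10^{-3}$, agreement $2 \times 10^{-3}$);
the Mendelian checker against the exhaustive 27-triple enumeration; the
BFDP against numerical quadrature ($10^{-6}$); the binomial tail
against the reference distribution function ($10^{-6}$ relative); and
the kernel moment p against 50,000 permutations (3 Monte-Carlo SEs)
across 20 regions. These sizes were chosen so each check has sharp
statistical resolution while the whole suite stays desk-scale.

## Known limitations

- The log-linear model accommodates a single binary family-level
  exposure; general covariates do not fit this likelihood.
- Autosomal biallelic variants only; no X-linked or parent-of-origin
  (imprinting) models.
- MCAR missingness is assumed by the EM; informative missingness would
  bias incomplete-family contributions.
- The BFDP prior is a package default, not an estimate; conclusions
  near the 0.8 threshold move with the prior, so every output records
  the prior used.
- Published region-level p-values computed on restricted individual
  data are not reproducible by construction; the package validates its
  tests by simulation and oracle equivalence instead.
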