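---
title: "Methods: factorial epistasis mapping with chromosome substitution lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial epistasis mapping with chromosome substitution lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cslmap)
```

# The design: a complete factorial of whole chromosomes

A chromosome substitution line (CSL) is a homozygous line whose genome is a
mosaic of intact, non-recombinant chromosomes from two parents — here the
Arabidopsis accessions Col and Ler. Because each of the $n$ chromosomes comes
from one of two parents, the complete panel has exactly $2^n$ genotypes
($32$ for $n = 5$), and growing the whole panel turns quantitative genetics
into a *balanced full-factorial experiment*: every chromosome is present in
each parental state in exactly half the panel, every chromosome pair in all
four joint states in a quarter of it, and so on. That balance is what gives
CSL panels their power to detect not just chromosome main effects but two-
and three-way interchromosomal epistasis.

`enumerate_panel()` generates the panel in a fixed lexicographic order
(chromosome 1 as the most significant digit, Ler before Col), and
`classify_panel()` partitions it into the two parental lines, the ten
single-substitution lines (sCSLs, five per recurrent background) and the
twenty multi-substitution lines. The two parental genotypes are ordinary
panel members throughout; nothing down-weights them.

```{r}
panel <- enumerate_panel(5)
table(classify_panel(panel)$label)
```

# The effect model

All generation and analysis revolves around one linear decomposition of a
plant's phenotype. With $x_{ik} = 0$ when chromosome $k$ of genotype $i$ is
Ler and $1$ when it is Col,

$$
y_{ir} = \mu + \sum_k a_k x_{ik} + \sum_{k<l} b_{kl} x_{ik} x_{il}
       + \sum_{k<l<m} c_{klm} x_{ik} x_{il} x_{im} + \varepsilon_{ir},
\qquad \varepsilon_{ir} \sim N(0, \sigma_e^2).
$$

The 0/1 dummy coding (rather than $\pm\tfrac12$ effect coding) is kept
deliberately: $\mu$ is then the all-Ler parental mean and each coefficient is
the phenotypic consequence of substituting Col material into a Ler context,
which is how substitution effects are naturally reported. The same
`design_matrix()` serves the simulator and every fitted model, so interaction
columns are *exact* elementwise products of their parent main-effect columns
and the marginality structure is true by construction. On the complete
balanced panel the order-3 design matrix ($1+5+10+10 = 26$ columns) has full
column rank, so all terms up to three-way are estimable; four- and five-way
terms are not modelled (with 12 replicates the panel cannot resolve them, and
intra-chromosomal epistasis is invisible to CSLs by design).

# What the simulators emulate

**Breeding (`dh_panel`, `ril_panel`, `nil_panel`).** Reverse breeding
suppresses crossovers in the F1, so gametes carry intact parental
chromosomes; each doubled haploid (DH) is an i.i.d. uniform draw from the
$2^n$ panel. Panel-completion logistics are then a coupon-collector problem,
and `completeness_probability()` gives the exact inclusion–exclusion answer
$\sum_j (-1)^j \binom{N}{j}(1-j/N)^{n_\text{lines}}$, $N = 2^n$, against
which the simulator is tested. Rather than asserting a fixed "lines needed"
target, the package reports this probability curve (about 18% at 96 lines
and 56% at 128 for $n=5$ — in practice missing genotypes are completed by
directed crosses, which is also how the real panel was finished).

Recombinant meiosis uses the Haldane model: per chromosome a Poisson number
of crossovers in the map length, uniform positions, no interference. Haldane
was chosen because every derived quantity then has a closed form to test
against; Kosambi recombination fractions are available as an option for
RIL generation (`map_fun = "kosambi"`). RIL genotypes are *not* produced by
simulating eight selfing generations: the marker-to-marker process is a
Markov chain with the standard selfing-RIL expansion $R = 2c/(1+2c)$ applied
to the Haldane fraction $c$, which has the same marginal map expansion at a
fraction of the cost. The interpolation used by the linkage scan composes
adjacent-interval switch probabilities, so predictor dosages are exactly
consistent with this generator. NIL panels are DH offspring of an sCSL
backcross: only the substituted chromosome segregates and recombines. All
recombinants are kept (no marker-assisted selection step), and introgression
boundaries are reported both at flanking markers and at interval midpoints,
since marker data cannot distinguish positions in between.

The default genetic map is Arabidopsis-like — five chromosomes of 120, 90,
95, 100 and 110 cM with markers every 5 cM (roughly 2.5 Mbp at the assumed
0.5 Mbp/cM) — a choice fixed once, since the real study's map is not part of
the package.

**Phenotypes (`make_layout`, `spatial_surface`, `simulate_experiment`).**
The reference trial mirrors the study conditions: the 32 CSLs in twelve
replicates alongside 100 RILs in three replicates, on a 12 × 60 grid divided
into three 12 × 20 randomised complete blocks (four CSL replicates and one
RIL replicate per block; 684 of 720 positions planted). A plant's value is
its genotypic value plus a block effect, a smooth spatial offset and
Gaussian noise. The surface is a sum of a few low-frequency 2-D cosines with
random phases plus independent row and column offsets, centred and rescaled
so its standard deviation equals the configured amplitude exactly — enough
structure for the adjustment stage to have something real to remove, while
remaining low-frequency enough that a low-degree polynomial basis can
represent it.

Default trait scales are fixed study conditions chosen once to resemble the
organism: short-day flowering time around 70 days with chromosome effects of
2–8 days and $\sigma_e = 2$ days, and main stem length around 150–300 mm
dominated by chromosome 2 (the *ERECTA* chromosome) with $\sigma_e = 20$ mm,
including a three-way interaction among chromosomes 1, 2 and 5. Residual
noise is Gaussian and homoscedastic — the same assumption the analysis
models make; heavy-tailed errors, outlier plants, germination-date
corrections and multi-trait genetic correlations are deliberately not
emulated. Passing tests therefore demonstrate correctness of the machinery
under the stated model, not robustness to the full messiness of field data.

# Spatial adjustment

The adjustment stage is a conventional REML mixed model, not a P-spline
re-implementation: fixed overall mean, population and block effects plus a
degree-3 tensor-product polynomial surface in (row, column); random row,
random column and random genotype-within-population effects, with a separate
genetic variance per population (CSL vs RIL, or the reciprocal NIL panels) —
the analogue of a genotype-by-population variance decomposition. The
rationale: the pipeline needs *a* principled, testable spatial correction;
exact equivalence with any particular spline smoother is neither attainable
from a verbal description nor needed for the questions the package answers.
Sum-to-zero contrasts for block and population keep the fitted environmental
part essentially centred, so corrected values stay on the raw scale.

Two outputs feed downstream, mirroring how such trials are analysed:
plant-level corrected values (raw minus the fitted environmental part) go
into the CSL epistasis decomposition — individual values are preferred over
genotype means there to preserve residual degrees of freedom — while
shrunken genotype means (population mean plus genotype BLUP) go into the
RIL/NIL linkage scans. Block is a fixed term for all experiments.

Numerical edge case: with essentially zero within-genotype variance the REML
residual variance sits on the boundary and the mixed model is skipped;
corrected values are returned equal to raw values with moment-based variance
components. Variance estimation quality is checked by simulation (median
relative bias of genetic and residual variances under 15% at the reference
trial size).

# The staged backward-elimination cascade

Selection proceeds in three stages on plant-level corrected values:

1. **Three-way terms.** Starting from the full order-3 model, repeatedly
   drop the least significant three-way term (partial F-test) until all
   survivors have $p \le \alpha_3 = 5\times10^{-5}$ — a threshold this small
   because it doubles as a multiple-testing correction over the ten
   candidate terms.
2. **Two-way terms**, at the same threshold, with one crucial asymmetry:
   pairs nested under a surviving three-way term are *protected* — retained
   unconditionally and never tested. This is the marginality principle; the
   protect-unconditionally reading was chosen over test-then-restore because
   only it guarantees that the reported p-values of tested terms are not
   conditioned on temporarily removing terms the final model must contain.
3. **Main effects** not protected by any selected interaction are pruned the
   same way, and the final model is tested against the intercept-only model
   (overall F). The fit reports coefficients with 95% CIs, $R^2$ of the
   final and of the main-effects-only model (their ordering is structural:
   the final model nests the mains), and model-predicted class means with
   delta-method CIs for each selected interaction — the data behind
   interaction effect plots.

The drop rule is a per-term partial F-test by default because α levels are
what the procedure is specified by; an information-criterion variant
(`criterion = "aic"`, a likelihood-ratio drop rule with its penalty set at
the $\chi^2_1$ quantile for the same α) is provided since stepwise-AIC
implementations are common in this literature, and the two agree whenever
signal and noise are well separated. Elimination ties are broken
deterministically (largest p, then smallest |t|, then term name), so a rerun
is bit-identical. Calibration is verified by simulation at the reference
conditions: under a main-effects-only truth the cascade selects a spurious
three-way term in well under 0.5% of runs, while an injected
$c_{klm} = 4\sigma_e$ is recovered as exactly the right term set in over 95%
of runs; on small panels the stage-wise procedure provably matches
brute-force all-subsets selection under the same per-term rule.

Two companion analyses reuse the same engine: per-background sCSL models
(main effects of five substitutions against one recurrent parent) and the
chromosome × background model on both parents plus all ten sCSLs,
$y = \mu + \sum_k a_k x_k + b z + \sum_k c_k x_k z + \varepsilon$ with $z$
the background indicator, interactions eliminated at
$\alpha = 1\times10^{-3}$ (five candidate terms). Degrees of freedom always
come from the plant-level fit; genotype-level means can be fed through the
same interface (`value_col`) for sensitivity analyses.

# Linkage mapping in the comparison populations

The RIL scan is Haley–Knott-style regression composite interval mapping
with the stated mechanics honoured exactly — a 5 cM evaluation grid (the
union of marker positions and a 5 cM walk, so dosages are exactly 0/1 at
markers), expected allele dosages from flanking markers under the RIL
Markov model, cofactors excluded within a 50 cM window of the tested
position, QTLs at least 30 cM apart, iterated scan→cofactor rounds until the
QTL set stabilises, and support intervals as the drop-2 region of the
$-\log_{10}(p)$ profile, linearly interpolated to bp where the map carries
physical positions (nearest-marker bp beyond the ends). "Minimum cofactor
proximity" is read as the standard CIM exclusion window around the tested
position; the alternative reading (minimum spacing between cofactors) was
considered and not adopted.

Genome-wide significance uses the Li–Ji effective number of tests: per
chromosome, each eigenvalue $\lambda$ of the marker correlation matrix
contributes $I(\lambda \ge 1) + (\lambda - \lfloor\lambda\rfloor)$;
chromosome contributions are summed (a whole-genome-matrix option exists and
is identical for block-diagonal correlation) and the per-test level is the
Šidák correction $1-(1-\alpha)^{1/M_\text{eff}}$. Simulation shows the
realised genome-wide error at markers ~5 cM apart runs slightly above the
nominal 5% (about 7% across panel draws) — a documented mild liberality of
eigenvalue-based corrections at moderate inter-marker correlation, accepted
here because the method, not a replacement for it, is the object of study.

NIL fine-mapping is per-marker regression of the phenotype on the local
introgression genotype within each reciprocal background, with a
per-chromosome Li–Ji correction inside each panel, drop-2 support intervals
around the strongest marker, and a heatmap-ready effect/significance table;
monomorphic markers are flagged and skipped, and opposite-sign
background-specific effects propagate to opposite-sign estimates.

# Problem sizes, determinism, limitations

The test suite and the analysis scripts run everything at the sizes the
design itself prescribes (32 × 12 CSL plants, 100 × 3 RILs, 12 × 60 grid);
Monte-Carlo checks use 200–2000 replicates per claim and three-binomial-SD
tolerances, with null-calibration suites at 500 replicates. All randomness
flows through R's global generator, so a seed fixes every panel, layout and
phenotype byte-for-byte; `run_pipeline()` snapshots its configuration and
seed next to its outputs.

Known limitations, all deliberate: no cytoplasmic (inducer-line) background
effects; no aneuploidy, transgene-escape or semi-sterility emulation; no
kinship correction or multi-trait scans in the linkage stage; no exact
numerical correspondence with any specific spline-based spatial software;
and real-data trait values are outside the package's scope — its claims are
about the correctness and calibration of the machinery under its own
generative model.
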