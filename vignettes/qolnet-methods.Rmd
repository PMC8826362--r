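---
title: "Methods: regularized partial-correlation networks for quality-of-life scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized partial-correlation networks for quality-of-life scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`qolnet` estimates Gaussian graphical models (GGMs) over questionnaire
scale scores measured at two visits. In a GGM, nodes are scales (EORTC
QLQ-C30/BR23 functional and symptom scales, the global health/QoL scale
`gQoL`, and a 13-item depression sum score) and an edge between two nodes
is their *partial correlation* — the association left after conditioning
on every other node,
$w_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$
for precision matrix $\Theta$. Estimation is by the graphical LASSO: the
L1-penalised Gaussian log-likelihood
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\neq j}|\Theta_{ij}|$
is maximised by block coordinate descent (diagonal unpenalised), and the
penalty $\lambda$ is chosen by minimising the extended Bayesian
information criterion
$\mathrm{EBIC} = -n\,[\log\det\Theta - \mathrm{tr}(S\Theta)]
 + E\log n + 4\gamma E\log p$,
with $E$ the number of edges and $\gamma = 0.5$, the conventional value
that prefers sparser, more interpretable networks. The penalty path is
log-spaced over 100 points from $\lambda_{\max}$ (the largest absolute
off-diagonal of $S$, above which the graph is empty) down to
$0.01\,\lambda_{\max}$; both the length and the ratio are configuration
keys since the conventional defaults are not sacred. Partial correlations
are reported from the penalised precision without refitting, matching the
common practice of reporting *regularized* partial correlations. A known
consequence, visible in our simulations, is that under strong dependence
the EBIC minimum sits at small penalties and the selected networks are
fairly dense (60–70% of possible edges) — the same density regime reported
for real quality-of-life networks of this size.

Because several single-item scales take fewer than 7 distinct values, the
input matrix $S$ mixes coefficient types by variable type: Pearson for
continuous–continuous pairs, polyserial for continuous–ordinal, polychoric
for ordinal–ordinal, with "ordinal" decided by the strict `< 7` distinct
observed values rule. The polychoric/polyserial estimators are two-step:
thresholds are fixed at normal quantiles of the marginal proportions, then
the latent correlation maximises the bivariate-normal likelihood over
$(-0.999, 0.999)$ (scalar optimisation, tolerance $10^{-6}$; boundary
estimates are clamped with a warning). Full joint maximum likelihood would
change estimates negligibly at $n \approx 500$ and costs considerably
more. Pairwise mixed estimates need not form a positive semidefinite
matrix; repair is by eigenvalue clipping at $10^{-8}$ followed by
rescaling to unit diagonal. Tests compare this against the Higham
alternating-projections solution (`Matrix::nearPD`); for the mild
indefiniteness seen in practice the two agree to a few hundredths. Zero
cells get no continuity correction by default (configurable), keeping the
likelihood unmodified unless tables are sparse.

## Preprocessing

Symptom-type scales are reversed to higher-is-better orientation about
their range maximum (pivot 100 for the 0–100 scales, 39 for the depression
sum), so all correlations in the network share a sign convention.
Missing scale scores are imputed by the longitudinal *copyMean* rule:
linear interpolation within subject, corrected by the shape of the
population mean trajectory. For a gap between observations at visits $a$
and $b$, the imputed value at $t$ is the subject's interpolation plus
$\bar{x}(t) - \mathrm{interp}(\bar{x}; a, b)(t)$; leading/trailing gaps
anchored at the nearest observed visit $a$ get
$x(a) + \bar{x}(t) - \bar{x}(a)$. With only two visits every gap reduces
to the leading/trailing rule, but the interior rule is implemented and
tested for longer follow-up. Population means use observed values only, so
the rule is idempotent. Three deliberate choices: the order is
reverse-then-impute (the rules commute up to the pivot constant, so this
is a convention); imputed values are clipped to the declared range
(configurable — the shift rule is unbounded); and imputed values on
ordinal scales are snapped to the nearest attainable level, so imputation
cannot silently promote a 4-level scale past the 7-level rule. A subject
missing a scale at every visit falls back to the population mean
trajectory rather than erroring, since upstream exclusion only removes
subjects with fewer than two participations overall.

Node selection follows the univariate screen: Spearman correlation of each
scale with `gQoL` per visit, two-sided p-values from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df, Benjamini–Hochberg
adjustment within each visit's family, and selection of scales whose mean
|rho| across the two visits *strictly* exceeds 0.3. Averaging uses
absolute values before the mean; on data where all screening correlations
are positive (as in the published table this reproduces) signed and
absolute averaging coincide. On the published 23-scale table the rule
selects 14 scales — a 15-node network with 105 potential edges.

## Centralities, communities

Node importance uses strength (sum of absolute incident weights),
closeness (inverse of summed shortest-path distances, with an edge's
length $1/|w|$ — the field-standard convention for correlation-weighted
networks; unreachable nodes give closeness 0 so every node keeps a rank),
and betweenness (geodesic counts, Brandes convention with ties split
fractionally, since an integer count is ambiguous under tied geodesics).
Each index is also z-standardised across nodes; a degenerate
constant index yields z-scores of 0. Community structure is sought by
three modularity-maximising algorithms on the absolute-weight graph —
exact maximisation, simulated-annealing Potts search (spinglass, run per
connected component, seeded for determinism), and 4-step walktrap — and
the partition with the highest weighted Newman modularity
$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{k_ik_j}{2m}\right)
\delta(c_i, c_j)$ is returned, with $Q < 0.3$ flagged as weak structure.
Absolute weights are used because modularity is defined for non-negative
weights while estimated networks contain (few, small) negative edges;
signed variants are a possible extension.

## Resampling and comparison

Stability follows the case-dropping bootstrap: drop a fraction $\pi$ of
subjects (both visits of a subject travel together), re-estimate, and
correlate the resampled edge-weight and centrality vectors with the
full-sample ones (Pearson on the full vectors, zeros included). The
CS-coefficient is the largest $\pi$ on the grid (default
$0.05, 0.10, \ldots, 0.75$; the grid is a config key) at which at least
95% of replicates stay above correlation 0.7; at least 0.25 is the
conventional floor for interpretation and 0.5 is preferred. Accuracy uses
nonparametric bootstrap (resampling subjects with replacement): 2.5/97.5%
quantile intervals per edge, and pairwise difference tests that call two
edges (or node strengths) different when the 95% interval of their
bootstrap difference excludes zero — deliberately uncorrected for
multiplicity, as is conventional for these descriptive tests. Replicates
whose re-estimation fails are dropped and counted, erroring beyond 5%.

The two visit networks are compared by a paired permutation test: each
permutation independently swaps, with probability 1/2 per subject, the
subject's two score vectors, and both networks are re-estimated with the
identical pipeline. Test statistics are network structure $M$ (maximum
absolute edge difference), global strength difference (absolute difference
of summed absolute edge weights), per-edge and per-node-strength absolute
differences; p-values use the add-one convention
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so they are never
exactly zero. The per-subject Bernoulli swap is the standard dependent
variant of this test; like the original it has not been formally validated
for dependent data, which the package documents rather than hides. The
companion outputs are the Spearman correlation between the two networks'
edge-weight vectors and the difference network $|w^{(2)}| - |w^{(1)}|$
(positive = association grew), exported with the conventional display
rules: |weight| > 0.05 for networks, |difference| > 0.04.

## The synthetic cohort generator

Since the underlying patient-level trial data are not public, validation
runs on a generator with known ground truth. A sparse symmetric
positive-definite precision matrix is built either randomly
(`make_precision_spec`: support uniform over node pairs, partial
correlation magnitudes uniform on 0.10–0.35 — bracketing the published
edge-weight range — 85% positive, eigenvalue-shift to SPD) or from an
explicit edge list (`precision_spec_from_edges`).
`default_precision_spec()` is a hand-specified 15-node structure mimicking
the published topology: a mental-health cluster
(depression–insomnia–emotional functioning–body image–future perspective),
a physical-functioning/fatigue axis, a pain/arm-symptoms pair, and `gQoL`
as a hub. Its edge values take the published strongest edge weights where
those are reported (e.g. insomnia–depression 0.33, physical
functioning–fatigue 0.30, future perspective–body image 0.36) and are
otherwise set so the implied marginal correlations with `gQoL` reproduce
the published screening table's rank order with a stable (rather than
knife-edge) selection outcome.

Latent vectors are drawn from the Gaussian with covariance
$\Sigma \propto \Theta^{-1}$; the two visits share a per-coordinate latent
correlation `subject_corr` (default 0.5 — the source study does not report
test–retest correlations, and 0.5 is a typical one-year stability for
QoL scales; it is a free parameter). Continuous margins are affine maps of
the latent normal clipped to the reporting range, with the affine
parameters moment-matched so the *censored* margin hits the target
mean/SD (for heavily skewed scales like social functioning, naive clipping
would otherwise shrink the SD by ~1 point). Ordinal margins cut the latent
normal at equal-probability thresholds into equispaced reporting values;
this keeps ground-truth rank correlations analytically available at the
cost of only approximating skewed discrete margins. Missingness is MCAR at
the cell level (~4%, the published rate), except that a subject is never
missing a scale at both visits. Every subject has a deterministic child
RNG stream, so enlarging the cohort never changes earlier subjects.

What the generator does *not* emulate: intervention arms, informative
dropout (MAR/MNAR), item-level response processes, floor/ceiling clumping
beyond what censoring induces, and non-Gaussian latent dependence. Passing
tests therefore certify the estimation machinery under a faithful but
idealised latent-Gaussian world, not the full messiness of trial data.

## Numerical choices and problem sizes

The glasso core runs in C++ with warm starts along the penalty path;
convergence is declared when a full sweep moves the working covariance by
less than `tol` times the mean absolute off-diagonal of $S$
(`tol = 1e-7` by default, satisfying the KKT conditions to well below
$10^{-4}$; resampling-heavy simulations relax it to `1e-5`, a config
key). EBIC ties resolve to the sparser model. The EBIC sample size $n$ is
the number of subjects even over polychoric inputs — the standard, if
approximate, practice. Degenerate inputs are handled explicitly: an
all-zero correlation matrix yields the empty network, an empty network
yields zero centralities everywhere (and modularity is an error, since
$2m = 0$), and constant columns are rejected when classifying variables.

Simulation-based checks use sizes chosen to make their Monte-Carlo error
small relative to the tolerance they assert: margin checks at
$n = 50{,}000$, latent-correlation checks at $n = 100{,}000$, support
recovery averaged over 20 cohorts of $n = 487$, permutation-test
calibration with 200 Monte-Carlo repetitions of 250 permutations at
$n = 487$ on Pearson inputs with a 15-point penalty path, and stability
runs at $B = 200$ replicates per drop proportion. The analysis scripts use
$B = 250$ bootstraps and 1000 permutations; the conventional full settings
($B = 1000$, 5000 permutations) are the package defaults and scale
linearly in time.

## Known limitations

Regularized partial correlations are biased toward zero and EBIC model
selection over the penalised likelihood is density-biased under strong
dependence, so edge *support* should be read together with the bootstrap
CIs. The polychoric path assumes an underlying bivariate normal per pair;
ordinal scales with strongly skewed margins weaken that assumption. The
paired permutation test exchanges whole visits within subject and so tests
exchangeability of visits, not any parametric null. Community detection on
absolute weights discards sign information. None of the cross-sectional
networks support causal claims; they are hypothesis-generating summaries
of conditional association.
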