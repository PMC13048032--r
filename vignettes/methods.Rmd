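---
title: "Models and methods behind sscpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sscpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic fixtures do and do not demonstrate.

## 1. Structures and contact maps

A `protein_structure` holds one chain's structured residues with all heavy
(non-hydrogen) atoms. Parsing keeps the highest-occupancy alternate
conformer, maps common non-standard residues (MSE→M and similar), and drops
residues missing backbone atoms, with a warning. Residues are indexed
1..L internally; original author numbering is retained for reporting.

Two residues are in contact when their closest heavy atoms are nearer than
4.5 Å (`contact_cutoff`). The same definition feeds two map flavors:

* `enm` — all contacts; the spring network of the elastic models and the
  neighbor set of the mutation force;
* `stability` — contacts with sequence separation |i−j| ≤ 2 removed
  (`min_seq_separation` = 3): short-range contacts form in essentially every
  compact conformation and cancel out of native-versus-misfolded free-energy
  differences.

## 2. Elastic networks and normal modes

Both network variants share the contact spring energy
$V=\tfrac{K}{2}\sum_{ij\in\text{contacts}}[\hat r_{ij}\cdot(\delta r_{i'}-\delta r_{j'})]^2$
with a uniform force constant $K$ on every contact.

* **Cartesian (ANM).** Degrees of freedom are the 3L Cα coordinates; springs
  act along Cα pair directions of the contact map; masses are per-residue
  heavy-atom masses. The six rigid-body modes are removed; more than six
  numerically zero modes are reported as a disconnected-network error. Note
  that a Cα pair-spring network built on 4.5 Å closest-atom contacts alone
  can be legitimately rank-deficient (hinge motions cost no energy); for
  well-conditioned Cartesian networks pass a wider `cutoff` to
  `build_contact_map()`, as Cα-only elastic models conventionally do.
* **Torsional (TNM).** Degrees of freedom are the backbone φ/ψ torsions
  (first φ and last ψ excluded: 2L−2 for one chain); ω and side-chain
  torsions are frozen. The torsion→Cartesian Jacobian moves all heavy atoms
  rigidly downstream of each rotated bond; rigid-body content is removed by
  mass-weighted Eckart projection before the generalized eigenproblem
  $V\theta=\omega^2 T\theta$ is solved through $T^{-1/2}$. A quadratic
  torsional penalty $\kappa_\psi K\sum_a(\Delta\theta_a)^2$ with
  $\kappa_\psi=0.2$ applies to *all* retained torsions and keeps the
  spectrum strictly positive.

Masses are normalized so the chain's total mass is 1, and modes obey
$\sum_i m_i v^\alpha_i v^\beta_i=\delta_{\alpha\beta}$; the mass-weighted
mean-square deformation of any response is then a plain sum of squared mode
amplitudes, and the thermal profile is $\sum_\alpha\omega_\alpha^{-2}$.

The linear response inverts the Hessian *in the mass-weighted metric*. The
test suite's independent oracle therefore inverts
$M^{-1/2}(M^{-1/2}HM^{-1/2})^{+}M^{-1/2}$ explicitly; the Euclidean
Moore–Penrose pseudo-inverse differs whenever the force carries net torque.

## 3. The mutation force and its response

Mutation $(a,m,b)$ pushes every contact neighbor $k$ of site $m$ along
$(\vec r_{m'}-\vec r_{k'})/|r|^{1+g}$ with magnitude
$K R_0^g\,[W_\text{size}\,\Delta s+W_\text{stab}\,\Delta U+W_\text{dist}\,\Delta d]$,
and the mutated site takes minus the sum (zero total force). Defaults:
$g=2$, $R_0=3.25$ Å, $W_\text{size}=3.05$, $W_\text{stab}=2.39$,
$W_\text{dist}=15.6$ (shipped fitted values; `fit_weights()` re-fits the
weight *direction* on user data by maximizing the Pearson correlation of
mutation-only predicted versus observed RMSD — the correlation is invariant
to the overall scale, so weights are reported with unit norm). Kernel
distances are floored at 2.5 Å: synthetic fixtures can contain closer
approaches than curated crystal structures and the kernel must not blow up.

Predicted per-mutation RMSD and harmonic energy follow the mode sums in the
README. RMSD is invariant to $K$ (the $K$ in the force cancels the $K$ in
$\omega^2$); ΔE carries one power of $K$ and is reported at the reference
$K=1$. The full mutant mean-square deviation decomposes into mutation, null
(thermal) and cross terms; the cross sign $\sigma_p$ is fitted from an
observed MSD with a documented tie-break (+1 at equality). Conformational
changes whose harmonic barrier is below half the null expectation at the
same MSD are flagged as likely functional (`functional_change_filter`,
ratio 1 by convention for a zero change).

Wild-type entries of the L×20 effect tables are the stationary-weighted
average of the 19 mutations into the wild-type residue (uniform global
frequencies inside the average, so the entry depends only on the structural
channel and its Λ); at Λ=0 it is the arithmetic mean.

## 4. Folding stability

$\Delta G = G_\text{nat}-G_\text{nonnative}$ with
$G_\text{nonnative}=-\log(e^{-G_\text{misf}}+e^{-G_U})$ (log-sum-exp
guarded), $G_U=-L S_U$, and the REM misfolded ensemble
$G_\text{misf}=\langle E\rangle-\tfrac12\mathrm{var}(E)-L S_C$, clamped at
$\langle E\rangle-\sqrt{2 L S_C\,\mathrm{var}(E)}$ below the REM freezing
point (flagged `frozen`). Disabling the misfold channel gives the exact
hydrophilic limit $\Delta G=G_\text{nat}+L S_U$.

Decoy statistics come from a library of compact contact maps. The mean uses
the reduced parameterization $\langle C_{ij}\rangle=a(L)f(|i-j|)$, with
$f$ pooled over the library and $a(L)$ matching the library's contacts per
residue (fitted through the origin, which interpolates across lengths). The
variance is assembled from three moment classes — same-pair
$(\bar C_{ij}-\bar C_{ij}^2)U_{ij}^2$, shared-site contact-number
covariances with per-site mean contact energies, and pair-versus-total
covariances — all computed from the *empirical* mean matrix of leading
L×L submatrices of the library maps, cached per length. A degenerate library
of identical maps therefore yields exactly zero variance. The three-class
assembly double-counts overlapping covariance terms by construction; the
exact alternative (`variance = "empirical"`, moments of the actual decoy
energies) is available and is what the Boltzmann-sum oracle tests exercise
tightly, while the moment assembly is checked against it at a looser,
documented tolerance.

`delta_delta_g()` updates only the cached sums touching the mutated site
(native row, misfold mean row, variance rows) and agrees with a full
recomputation to 1e−10; the shared-site covariance update involves one
quadratic form in the cached covariance matrix, so the worst-case cost is
O(L²) with a small constant, not O(L) — still far below re-deriving the
statistics.

Shipped parameter tables are deliberately labelled *synthetic*: the contact
energies are hydrophobicity products (Kyte–Doolittle based), the optimal
distances are heavy-atom-count radii sums, both plain TSV and replaceable
via `read_pair_table()`. $S_U=0.2$ and $S_C=0.03$ ($k_BT$ per residue) were
chosen once so that greedily designed sequences and most members of
model-sampled families are predicted stable — the regime real families are
in and the regime the pipeline's own retention filters presume. No test
depends on these numeric values; only limits and oracle identities are
asserted.

## 5. Site profiles and the selection-parameter fit

Each model's stationary distribution is
$P_i(a)\propto P_\text{glob}(a)\exp(\Lambda_\text{stab}\varphi^\text{stab}_i+\Lambda_\text{str}\varphi^\text{str}_i)$
with the channels of Table: GLOB (none), MF/WT (stability), DE/RMSD
(structure), and the four combinations. Frequencies are floored at
ε=0.001 *and renormalized* so that floored entries sit exactly at ε and rows
sum to one (the flooring makes the distribution non-analytic in Λ; the
renormalization is this package's documented choice). The mean-field
stability fitness iterates the self-consistency at Λ=1 with damping 0.5,
tolerance 1e−6 on the maximum frequency change and a 500-sweep cap; the
native channel uses exponential (Boltzmann) averages per contact — exact on
a two-site system — while the misfold mean is updated per (site, amino acid)
and the misfold variance and freezing test are evaluated once per sweep at
the mean-field composition (a second-order effect).

Global frequencies solve the +F-style matching condition iteratively
(damped fixed point, per-amino-acid residual below 1e−8). The selection
parameters minimize the symmetric KL divergence between model and observed
site frequencies (the log-likelihood criterion is available behind
`criterion = "LL"`) plus the ridge penalty $R\Lambda^2$; one-parameter
models use a coarse grid then Brent refinement, two-parameter models a
coarse 2-D grid then cyclic coordinate refinement — deterministic
throughout. The ridge weight is chosen where the specific heat
$C_V=\partial\mathrm{KL}/\partial R$ (central finite differences on a
log-spaced grid, boundary maxima warned) peaks, refined by quadratic
interpolation in log R, with Λ refit at the chosen R. Because the
structural channel's wild-type entries depend on Λ_str, those entries are
re-evaluated inside every objective evaluation.

Ridge estimates are intentionally biased toward zero; recovery tests
therefore validate the unpenalized (R = 0) estimator against the generating
parameters, while penalized fits are only required to satisfy the model
contracts (floor, normalization, detailed balance).

## 6. Site-specific substitution models

$Q_i(a,b)=E_i(a,b)P_i(b)$ with three binary options: HB (Halpern–Bruno
fixation factor on a global exchangeability), FL (global exchangeability
rescaled so the site-averaged flux of every pair matches the empirical
model's flux; the noHB variant needs $1/Z_i^2$ in the denominator, which
the flux-sum identity fixes), rate0/rate1 (per-site rate normalized to one,
with the model-predicted rate kept as a scale factor under rate1). The HB
factor is evaluated on the *floored* stationary distribution
($\tilde\varphi_i=\log(P_i/P_\text{glob})$, Z=1): raw fitness differences of
tens of $k_BT$ would overflow the fixation factor and produce absurd rates
for floored amino acids, while the floored form is bounded and keeps
detailed balance against the distribution the phylogenetic models actually
use. The equal-fitness limit is handled analytically
(`x/expm1(x)` with a series switch below 1e−9).

Empirical models (JTT, LG, WAG) are taken from phangorn's model data at run
time or parsed from PAML-dialect `.dat` files. The tree-free approximate
pair likelihood is evaluated at its closed-form optimal divergence
$t=\sum_a(N(a)-N(a,a))/(-\sum_a N(a,a)P_aE_{aa})$,
$E_{aa}=-\sum_{b\neq a}E_{ab}P_b$; with no identical pairs the optimum
diverges and is capped at t = 5 (documented). Pair counts default to each
sequence against the best-matching structure-bearing sequence; all-pairs
pooling is configurable.

## 7. Phylogenetic toolkit

Felsenstein pruning under per-site reversible models uses symmetrized
eigendecompositions cached per site, per-node rescaling against underflow,
gap-as-missing leaves, and batches alignment columns that share a model
(`site_map`). Branch lengths are optimized cyclically with Brent steps on
[0, 10], tolerance 1e−8, at most 50 sweeps. `RegMLaME = −loglik + μ Σ t_b`;
μ can be fitted as the least-squares slope of log-likelihood on tree length
over a tree collection.

Tree comparison matches branches by canonical bipartition (terminal branches
by label; the two root edges of a rooted binary tree merge). Unmatched
branches enter the least-squares fits with zero length on the missing side —
unscalable error mass. K fits one scale; its "normalized" value is the RMSE
divided by the root of the summed squared reference lengths (a convention —
the literature leaves it unspecified). K2 fits two scales with an alternating
assignment seeded from the single-scale residual split; user-supplied branch
classes (the function-conservation reading) are accepted; the single-scale
solution is always a candidate, so K2 ≤ K holds by construction, and classes
with too few branches fall back to K with a warning. The normalized RF
distance counts the symmetric difference of non-trivial splits over 2(n−3).

## 8. Synthetic fixtures: what they emulate, what they do not

`make_backbone()` builds ideal-geometry helices from torsions (NeRF chain
construction) and compact helix bundles from an explicit Cα trace on a grid
of antiparallel helix axes joined by arc loops, lightly relaxed against
clashes and dressed with backbone atoms from local frames. Bundles reach
contact numbers of roughly 2–12 at L≈50, which is what the contact-number
trend tests need. `make_decoy_library()` randomizes the bundle recipe;
`design_sequence()` greedily minimizes ΔΔG with a composition penalty so
scaffolds carry foldable, diverse sequences; `sample_msa()` draws columns
i.i.d. from stationary profiles or evolves them along a tree with the fitted
site models (matrix exponentials via the symmetrized eigendecomposition).

Synthetic families are sampled at (Λ_stab, Λ_str) = (2, 0.5) — strong
stability selection and moderate structural selection — with 30–100
sequences, and the generator uses the same Λ-dependent wild-type-entry
convention as the fitted structural channel, making pipeline fits clean
recovery problems. What passing tests show: the estimators recover known
parameters under the model's own assumptions, the analytic identities hold,
and the qualitative contact-number trends emerge from the mechanics alone.
What they do not show: agreement with real mutant structures (the
experimental mutant-pair correlations need external crystallographic data),
realism of the synthetic energy tables, or model adequacy on real families —
on real data the model is misspecified by construction and recovery
guarantees do not transfer.

Problem sizes throughout the suite and the acceptance script were chosen at
desk scale: fixtures of 8–60 residues, families of 30–100 sequences,
500 columns per site for the Λ-recovery simulation and 1000 sites for
branch-length recovery.

## 9. Known limitations

* Single chains only; inter-chain contacts, NMR ensembles beyond the first
  model, and mmCIF input are out of scope.
* The mean-field misfold variance is sweep-level, not per-amino-acid.
* The moment-assembled REM variance double-counts overlapping covariance
  classes; use `variance = "empirical"` when the decoy library is small
  enough to enumerate.
* The approximate pair likelihood ignores tree topology by design; it ranks
  models, it does not replace the pruning likelihood.
* Tree-topology search is not provided — the package evaluates and compares
  given topologies; partition exports feed external ML engines.
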