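---
title: "Stability of consumer-producer-resource communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability of consumer-producer-resource communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeed)
```

## The model

Microbial taxa interact largely through the abiotic resources they consume
and — via crossfeeding — produce, rather than through direct pairwise
effects. `crossfeed` models $N_R$ resources $R_i$ and $N_S$ consumers
$S_j$ with mass-action dynamics

$$
\dot R_i = \rho_i - \eta_i R_i - R_i \sum_j C_{ij} S_j + \sum_j P_{ij} S_j,
\qquad
\dot S_i = \epsilon S_i \sum_j C^T_{ij} R_j - S_i \sum_j P^T_{ij} - \mu_i S_i.
$$

Here $C_{ij} \ge 0$ is the rate at which consumer $j$ takes up resource
$i$ (per unit consumer, per unit resource, per time), $P_{ij} \ge 0$ the
rate at which consumer $j$ produces resource $i$ (per unit consumer per
time), $\rho$ the abiotic influx, $\mu$ the consumer mortality,
$\epsilon > 0$ the dimensionless conversion efficiency, and $\eta \ge 0$
an optional leaching/outflow rate. Matrices are stored with rows =
resources and columns = consumers; time and density units are arbitrary
(only shapes are checked). With $P = 0$ this is pure competition for
substitutable resources. Two modeling commitments are worth making
explicit:

* uptake is linear (no Monod/Hill saturation, no colimitation) — the
  mass-action idealization is the baseline on which further kinetic
  complexity would be layered;
* the production cost term $-S_i \sum_j P^T_{ij}$ is deliberately
  independent of resource levels and carries no $\epsilon$: production is
  a resource-independent drain on biomass (leakage, or mortality
  recycling), exactly as the equilibrium theory assumes.

Leaching defaults to zero — consumption is assumed fast relative to
outflow — but is a first-class parameter because the stability results
are unchanged by it (the Jacobian only gains $-\eta_i$ on its resource
diagonal).

## Equilibria, forward and inverse

Interior equilibria are linear-algebraic:

$$
R^* = (C^T)^{-1}\tfrac{1}{\epsilon}(P^T \mathbf{1} + \mu), \qquad
S^* = [\,\mathrm{diag}(R^*) C - P\,]^{-1} \rho .
$$

`competitive_equilibrium()` and `crossfeeding_equilibrium()` solve these
for square $C$; an equilibrium is *feasible* when every entry of both
vectors is strictly positive. The inverse problem
(`rates_from_densities()`) is the more remarkable direction: with
$P = 0$,

$$
\mu = \epsilon C^T R^*, \qquad \rho = \mathrm{diag}(R^*)\, C S^*
$$

are automatically positive for *any* positive target densities, so every
feasible point can be made an equilibrium by an appropriate environment.
With $P \neq 0$ that guarantee disappears — the package reports (with a
warning object) when requested densities are not attainable with positive
rates. For the uniform specialist case ($C = cI$, $R^* = r\mathbf{1}$,
$S^* = s\mathbf{1}$) the attainability constraints are explicit:
$cr\epsilon > \sum_j P^T_{ij}$ (column sums) and $cr > \sum_j P_{ij}$
(row sums), evaluated by `specialist_feasibility()`.

Numerical choices: a consumption matrix with condition number above
$10^{12}$ is treated as singular (the degenerate cases this excludes —
redundant resources, identical consumers — are biologically trivial);
forward solving is restricted to square $C$, while the inverse design
supports $N_R \ge N_S$; feasibility means strict positivity with no
tolerance.

## Stability

The Jacobian at a state $(R, S)$ has the exact block form

$$
J = \begin{pmatrix}
-\mathrm{diag}(CS) - \mathrm{diag}(\eta) & P - \mathrm{diag}(R)\,C \\
\epsilon\,\mathrm{diag}(S)\,C^T & \mathrm{diag}(\epsilon C^T R - P^T\mathbf{1} - \mu)
\end{pmatrix},
$$

assembled by `community_jacobian()` and validated in the test suite
against central finite differences of the right-hand side (including
$P \neq 0$ and $\eta \neq 0$). At an interior equilibrium the bottom-right
block vanishes; for an extirpated consumer its diagonal entry is the
invasion fitness $[\epsilon C^T R^* - \mu]_j$ (`invasion_fitness()`),
whose sign decides invasibility of the boundary equilibrium.

The central result the package operationalizes: **with no production,
every feasible equilibrium is locally stable**, for any nonnegative $C$
of full column rank with $N_S \le N_R$ (`rank_condition()`). The proof
reduces candidate eigenvalues $\lambda$ with $\mathrm{Re}\,\lambda \ge 0$
to the positive definiteness of the Hermitian part of
$\sqrt{D_1} C^T D_2 C \sqrt{D_1}$ with $D_1 = \epsilon\,\mathrm{diag}(S^*)$
and $D_2 = [-\mathrm{diag}(CS^*) - \lambda I]^{-1}(-\mathrm{diag}(R^*))$;
`hermitian_certificate()` exposes that certificate as an executable
predicate, and the suite samples it across random systems and random
$\lambda$ in the closed right half-plane.

`jacobian_spectrum()` reports all eigenvalues sorted by descending real
part and a verdict with a tolerance band: *stable* when
$\max \mathrm{Re}\,\lambda < -10^{-10}$, *marginal* within
$\pm 10^{-10}$. The band exists because these spectra characteristically
pile real eigenvalues up against zero (the "dragonfly" shape: imaginary
wings of oscillatory modes plus a dense band of slow real modes), so a
strict sign test would be numerically fragile.

### Crossfeeding and reciprocity

With production, stability is no longer guaranteed. The tractable case is
the uniform specialist community (`specialist_community()`): each Jacobian
eigenvalue pair is indexed by an eigenvalue $\gamma$ of $P$ through

$$
\lambda = -\tfrac{cs}{2} \pm \tfrac12\sqrt{(cs)^2 - 4\epsilon cs(cr - \gamma)},
$$

computed by `specialist_lambdas()` (both branches, always). Stability per
$\gamma$ is exactly $\epsilon(\mathrm{Im}\,\gamma)^2 < cs(cr -
\mathrm{Re}\,\gamma)$ (`gamma_condition()`). Two corollaries become
predicates:

* `production_bound()` — the sufficient (not necessary) row-wise bound
  $(\sum_{j\ne i} P_{ij})^2 < \tfrac{cs}{\epsilon}(cr - P_{ii} -
  \tfrac{cs}{4\epsilon})$;
* `gershgorin_symmetric_check()` — for symmetric (reciprocal) $P$ all
  $\gamma$ are real and Gershgorin bounds them by row sums, so
  $cr > \sum_j P_{ij}$ — the same inequality that makes the equilibrium
  feasible — already implies stability. Feasibility plus reciprocity is
  enough.

Asymmetric production, by contrast, admits complex $\gamma$, and the
quadratic mapping converts imaginary parts of $\gamma$ into positive real
parts of $\lambda$ once $\epsilon(\mathrm{Im}\,\gamma)^2$ outruns
$cs(cr - \mathrm{Re}\,\gamma)$. The destabilized regime is therefore most
accessible at small consumer abundance $s$ (which shrinks the right-hand
side) and larger $\epsilon$; the test suite demonstrates unstable feasible
instances at $c = r = 1$, $s = 0.1$, $\epsilon = 2$, and in pooled
ensembles at $\epsilon = 5$. These parameter choices are demonstration
conditions, not generator defaults.

## Structural stability

For fixed preferences, which environments ($\mu$, $\rho$) sustain
feasible coexistence? The admissible $\mu$ vectors form the cone spanned
by the consumer preference columns, and their relative measure is

$$
V_\mu = 2\frac{\sqrt{\det M_\mu}}{\pi^{n/2}}
\int_{\mathbb{R}^n_+} e^{-\langle \xi, M_\mu \xi\rangle}\,d\xi,
$$

with $M_\mu$ the Gram matrix of the *normalized* preference columns
(`gram_mu()`); $V_\rho$ is the same construction on the columns of
$\mathrm{diag}(R^*)C$ (`gram_rho()`) and inherits a dependence on the
chosen mortality rates through $R^*$, so only $V_\mu$ has a
matrix-intrinsic value. The normalization convention makes $V = 1/4$ for
orthogonal preferences at $n = 3$ (the positive octant is $1/8$ of the
sphere, doubled by the leading factor 2). `feasibility_volume()` offers
three routes:

* `gaussian_mc` — the identity $V = 2\,\Pr[\,\mathcal N(0, M^{-1})
  \in \mathbb{R}^n_+\,]$, an exact restatement of the orthant integral,
  sampled via the eigendecomposition of $M$;
* `cone_mc` — a geometric oracle: twice the fraction of uniformly random
  unit directions falling inside the cone (Cholesky basis);
* `lhuilier3` — at $n = 3$ the cone subtends a spherical triangle whose
  sides are the pairwise angles; L'Huilier's theorem gives the excess in
  closed form, $V = E/2\pi$, exactly.

The default $10^6$ Monte Carlo samples give roughly 2% relative error
near $V \approx 0.04$, enough to resolve three significant figures; the
seed is a mandatory argument so every estimate is reproducible.

Similarity intuition holds only in the symmetric special case: for the
equal-angle family (common cosine $a$), $\det M = (1-a)^{n-1}(1+(n-1)a)$
(`equal_angle_det()`) is monotone, so uniformly less similar consumers
always enjoy a larger volume. It fails in general:
`example_preference_matrices()` builds the worked three-species pair in
which the angle between consumers 1 and 3 *increases* from
$0.304\pi$ to $0.444\pi$ (the other two angles fixed at $\pi/4$ and
$0.196\pi$) yet $V_\mu$ *drops* from $\approx 0.0417$ to
$\approx 0.008$ — structural stability is a property of the whole
preference geometry, not of pairwise overlaps.

```{r volumes}
m <- example_preference_matrices()
round(attr(pairwise_angles(m$initial), "pi_multiples"), 3)
feasibility_volume(gram_mu(m$initial), method = "lhuilier3")
feasibility_volume(gram_mu(m$shifted), method = "lhuilier3")
```

## Ensembles: what the generators emulate

`ensemble_config()` + `pooled_spectrum()` reproduce the pooled
eigenvalue-density procedure: fix a preference structure, repeatedly draw
equilibrium densities uniformly, design rates so each draw is an interior
equilibrium, and pool the Jacobian spectra. Structures cover the
specialist-to-generalist gradient with either i.i.d. ("random") or
smoothly ordered off-diagonal preferences; the ordered kernel is a
Gaussian in circular resource distance (the narrative constraint is only
"a smooth curve away from the preferred resource", so the kernel family
is a package choice and is pluggable). Densities default to
$U(0.1, 1)$ rather than $U(0, 1)$: bounding away from zero keeps
$\mathrm{diag}(R^*)$ well conditioned without changing the character of
the spectra, and the bounds are configurable. Production matrices are
drawn i.i.d. uniform (optionally symmetrized) and rescaled by a single
scalar — preserving symmetry and relative structure — into the specialist
feasibility constraints; density draws that still violate them are
rejected, so every pooled draw is a genuinely feasible equilibrium.

What the generators do *not* emulate: saturating uptake, resource
colimitation, demographic noise, extinction-recolonization dynamics, or
empirical preference structure estimated from data. Green ensemble tests
therefore certify the linear-algebraic theory under the stated sampling
conditions, not the behavior of any real microbiome.

Problem sizes used by the test suite were chosen to exercise the claims
across the relevant range while staying light: the headline
stability property runs 200 square systems at $N \in \{2,\dots,30\}$
plus 60 rectangular ones, the reciprocity property 500 symmetric-$P$
specialist systems at $N \le 20$, oracle cross-checks run at
$10^2$–$10^3$ draws, and Monte Carlo volumes use $2\times10^5$ samples in
unit tests and $10^6$ in the acceptance checks.

## Known limitations

* Forward equilibrium solving requires square, well-conditioned $C$;
  underdetermined ($N_R > N_S$) forward problems are out of scope (the
  inverse design handles them).
* The model has a unique interior equilibrium, so there is no
  continuation/bifurcation machinery.
* Global stability is not addressed — all verdicts are local
  (linearization) statements.
* The spectral *density* (the dragonfly shape) is reported and plotted
  but never asserted; no analytic description of it is attempted.
* For symmetric $P$ the leading eigenvalue appears bounded away from zero
  by a gap related to consumer abundances; the package logs the observed
  gap but, absent a formula, asserts only its sign.
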