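---
title: "Model embeddability for symmetric group-based substitution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model embeddability for symmetric group-based substitution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbembed)
```

## The model

A group-based substitution model identifies the states of a Markov chain
with the elements of a finite abelian group $\mathcal{G}$ (for DNA,
$\mathbb{Z}_2 \times \mathbb{Z}_2$ with A $=(0,0)$, T $=(0,1)$,
C $=(1,0)$, G $=(1,1)$; for the eight-letter hachimoji alphabet,
$\mathbb{Z}_2^3$ with A, C, T, G, P, Z, S, B in lexicographic order).
Rates and transition probabilities depend on states only through their
difference:
$$Q_{g,h} = \psi(h-g), \qquad P_{g,h} = f(h-g),$$
where $\psi$ sums to zero and is non-negative off the identity, and $f$
is a probability vector. A labeling function $L$ — represented here as a
partition of $\mathcal{G}$ — constrains entries further:
$\psi(g)=\psi(h)$ whenever $L(g)=L(h)$. All labelings considered are
*symmetric* ($L(g)=L(-g)$), so the matrices are real symmetric with real
spectra. The classical examples are CFN, Jukes–Cantor, K2P and K3P; the
hachimoji 7-, 3- and 1-parameter models are their eight-state analogues.

Every such matrix is diagonalized by the character table $K$ of
$\mathcal{G}$ (the discrete Fourier transform), with eigenvalues
$\check{v}(g) = \sum_h \hat g(h) v(h)$. The package therefore does all
exponentials and logarithms coordinate-wise in the Fourier basis:
$P = K\,\mathrm{diag}(e^{\check\psi})\,K^{-1}$. A dense
scaling-and-squaring exponential exists in the test suite only, as an
independent oracle.

## G-compatible labelings

Exponentiation preserves the labeling pattern exactly when the DFT
preserves the equality pattern of the label vector (*G-compatibility*):
for every pair $L(g)=L(h)$ the block-aggregated rows $g$ and $h$ of $K$
must agree. A necessary condition is that the identity forms its own
block. `enumerate_labelings()` generates all set partitions by
restricted growth strings, pruning non-symmetric and
non-zero-isolated partitions during generation, and filters by the
aggregated-row test (tolerance $10^{-9}$ on complex sums; group orders
here are tiny, so conditioning is benign).

Two deliberate interpretation choices:

* **"Up to isomorphism" means up to label renaming.** The published
  tables of symmetric G-compatible labelings list *partitions* — the
  quotient of labeling functions by renaming of the label set. They are
  not quotiented by group automorphisms: automorphic copies appear as
  separate rows. The enumeration here reproduces those tables row for
  row (counts 1, 1, 2, 3, 2, 2, 2, 3, 5, 12 for the ten groups of order
  up to eight). An automorphism-orbit dedup is still available
  (`up_to_automorphism = TRUE`) but is *not* the table's convention —
  it would merge, e.g., the coordinate-swapped copies on
  $\mathbb{Z}_2^3$ down to 5 classes.
* **Compatibility is tied to the state identification.** An
  automorphism acts on characters through its adjoint, so the image of
  a compatible partition under an automorphism need not be compatible:
  on $\mathbb{Z}_2\times\mathbb{Z}_4$ there are automorphic partition
  pairs with exactly one compatible member. This mirrors the
  familiar K2P subtlety that only the pairing $\{(0,1),(1,0)\}$ is
  compatible once A, T, C, G are fixed to the canonical tuples. The
  preset registry (`model_preset()`) exists to shield users from this
  ordering pitfall.

## The embeddability criterion

A model Markov matrix $P$ with eigenvalues $\lambda$ is the exponential
of a model rate matrix iff

1. $\lambda_0 = 1$ (checked to $10^{-8}$; row-stochasticity already
   forces this up to rounding),
2. $\lambda_g > 0$ for all $g$,
3. $\lambda_g = \lambda_h$ whenever $L(g) = L(h)$, and
4. $\prod_h \lambda_h^{\mathrm{Re}(K_{g,h})} \ge 1$ for every nonzero
   $g$.

`check_embeddable()` evaluates (4) in the log domain,
$\sum_h \mathrm{Re}(K_{g,h}) \log\lambda_h \ge 0$, which is numerically
stable and exactly equivalent for positive spectra. The slack of the
constraint at $g$ equals $|\mathcal{G}|\,\psi(g)$ of the candidate
generator, so a verdict of embeddable comes with the unique generator
(the principal logarithm, computed in the Fourier basis), and the
matrix lies on the boundary of the embeddable set precisely when some
slack vanishes — equivalently some off-identity rate is zero.
Constraints for $g$ and $-g$ coincide and are reported once per
$\{g,-g\}$ class.

Numerical conventions, chosen once: slack $\ge -10^{-9}$ counts as
satisfied and $|\text{slack}| \le 10^{-9}$ as active; an eigenvalue
within $10^{-9}$ of zero (or below) fails the strict positivity (2) —
the criterion itself is silent about floating-point ties, so the
package resolves them by this documented tolerance. A matrix whose
entries do not follow the claimed labeling is a *structural error*, not
a non-embeddable verdict: it is not a matrix of the claimed model at
all (the distinction matters because the exponential of a rate matrix
with a non-compatible labeling follows a strictly finer induced
labeling).

## Volumes of matrix sets

For a preset model, four nested sets are measured in the free
eigenvalue coordinates (one coordinate per nonzero labeling block,
ordered by block size and then minimal element; for the hachimoji
3-parameter model this is the conventional $(x, y, z)$):

* $\Delta$ — all model Markov matrices ($f = K^{-1}\lambda \ge 0$),
* $\Delta_+$ — positive spectra,
* $\Delta_{dd}$ — diagonally dominant matrices ($f(0) \ge 1/2$): the
  no-change probability dominates, which guarantees an identifiable
  generator,
* $\Delta_{me}$ — the model-embeddable matrices.

The first three are polytopes. `exact_volume()` computes their volumes
exactly: vertices are enumerated by solving every $d$-subset of
halfspace boundaries in exact rational arithmetic (a floating-point
prescreen skips singular and infeasible subsets; every kept vertex is
re-verified exactly), and the volume is assembled by the
divergence-theorem pyramid decomposition over one vertex, recursing on
facets after eliminating one coordinate; the elimination factors cancel
so every intermediate is rational. The rational layer stores integer
numerators and denominators in doubles with gcd reduction and a
$2^{51}$ overflow guard — amply safe for the $\pm 1$-scale Fourier
coefficients involved. The 7-dimensional positive-spectrum region of
the hachimoji 7-parameter model (15 halfspaces,
$\binom{15}{7} = 6435$ candidate vertex subsets) takes a few seconds.

$\Delta_{me}$ is semialgebraic. For the hachimoji 3-parameter model it
admits the explicit description $0 < x \le 1$, $0 < y \le \sqrt x$,
$0 < z \le (x y^2)^{1/4}$, and `h3p_me_volume()` integrates the
$z$-extent by nested adaptive quadrature (default absolute tolerance
$10^{-7}$), optionally intersected with the diagonal-dominance
halfspace $x + 2y + 4z \ge 3$. The unconstrained case has the closed
form $\int_0^1 \frac{2}{3}x\,dx = \frac13$, kept in the test suite as
an independent oracle. For the 7-parameter model no closed form is
attempted (the region is a 7-dimensional semialgebraic set);
`mc_volume()` estimates it by hit-and-miss Monte Carlo over the unit
box $(0,1]^7$ — embeddability forces $0 < \lambda_g \le 1$, so the hit
fraction *is* the absolute volume. This reconstructs the reference
computation's (unstated) sampling setup; it is recorded here as an
assumption, validated by reproducing the published estimates at
$n = 10^6$ within Monte Carlo error. Every hit maps back to a genuine
stochastic matrix (the exponential of a model rate matrix is
automatically stochastic), a property the tests verify empirically.

Monte Carlo results carry the binomial standard error
$\sqrt{p(1-p)/n}$ scaled by the box volume, plus the sample count and
seed. Randomness uses R's Mersenne–Twister via `set.seed()` with the
seed recorded in every result object; a counter-based generator was
considered and rejected since base R does not provide one and
reproducibility is fully determined by `(n, seed, chunk order)` as
implemented.

## The fixture generator

`generate_fixtures()` draws study-condition test matrices per preset:
off-identity block rates iid uniform on $(0, 1)$ (the default
`rate_max = 1` keeps spectra well inside $(0, 1]$, giving informative
interior positives), exponentiated in the Fourier basis. Boundary
fixtures set one block rate exactly to zero — by the slack identity
this makes exactly that product inequality active. Non-embeddable
fixtures rejection-sample block-wise uniform probability vectors until
a closed-form condition fails (each fixture records the violated
constraint); non-Markov fixtures perturb a single entry of a valid
matrix. What the generator emulates is the geometry of the model
itself, not data: it produces exact model matrices, so passing tests
certify the decision procedure and volume machinery, not robustness to
sampling noise in transition-matrix *estimates* from finite sequence
data, which is out of scope for this tool.

## Problem sizes and limitations

The test suite works at the scale the methods are meant for: groups of
order up to 12, a thousand random matrices per preset for the
criterion-vs-oracle equivalence, $5\times10^2$ round-trip draws per
preset at $10^{-9}$, and $10^6$ Monte Carlo points per volume estimate.
Matrix files are written with 12 significant digits; boundary
classification through a file round trip is therefore meaningful only
to about $10^{-7}$, and the tests use a matching tolerance there.

Known limitations: only symmetric labelings (real spectra) are
supported — non-symmetric labelings and complex spectra are rejected,
as are non-abelian groups; the exact volume engine is guarded to
dimension 8 and integer halfspace data; classical (model-free)
embeddability of arbitrary stochastic matrices is out of scope — a
matrix can be embeddable in the classical sense yet have no generator
within the model, and this package decides only the model-specific
question.
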