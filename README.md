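# gbembed

Model-specific Markov embedding tests for symmetric group-based
phylogenetic substitution models, with exact and Monte Carlo volumes of
the embeddable set.

## The problem

Continuous-time substitution models assume a transition matrix of the
form *P* = exp(*Q*) for a rate matrix *Q*. For *group-based* models —
CFN, Jukes–Cantor, K2P, K3P for DNA, and their eight-state hachimoji
analogues H1P, H3P, H7P for synthetic genetic alphabets — the states
are elements of a finite abelian group 𝒢 and both *Q* and *P* are group
convolutions, Q<sub>g,h</sub> = ψ(h−g), P<sub>g,h</sub> = f(h−g),
further constrained by a symmetric labeling function *L* (entries with
the same label of the state difference are equal). The *model
embedding* question is: given such a Markov matrix *P*, does a rate
matrix *Q* with **the same model structure** exist with *P* = exp(*Q*)?
This is strictly stronger than classical embeddability and decides
whether observed transition frequencies are consistent with a
homogeneous continuous-time process *of the model*.

Because every model matrix is diagonalized by the character table *K*
of 𝒢 (the discrete Fourier transform), the answer depends only on the
eigenvalue vector λ of *P*: writing Re(K) for the real part of the
character table, *P* is model embeddable iff

* λ₀ = 1, λ<sub>g</sub> > 0 for all g, λ constant on labeling blocks, and
* ∏<sub>h</sub> λ<sub>h</sub><sup>Re(K<sub>g,h</sub>)</sup> ≥ 1 for every
  nonzero g (evaluated in the log domain:
  Σ<sub>h</sub> Re(K<sub>g,h</sub>) log λ<sub>h</sub> ≥ 0).

On success the unique in-model generator is the principal logarithm,
recovered coordinate-wise in the Fourier basis. The package also
enumerates the symmetric *G-compatible* labelings (the ones whose
pattern survives exponentiation) for any small abelian group, and
measures how large the embeddable set Δ<sub>me</sub> is inside the
model's Markov matrices Δ, the positive-spectrum set Δ₊ and the
diagonally dominant set Δ<sub>dd</sub> — exactly (rational vertex
enumeration and pyramid decomposition) for the polytopal sets, by
quadrature or hit-and-miss Monte Carlo for the semialgebraic ones.

## Worked example

The 7-state model on Z₇ with rates ψ(±1) = ψ(±2) = 0.125,
ψ(±3) = 0.25:

```r
library(gbembed)
G   <- parse_group("Z7")
psi <- c(-1, 0.125, 0.125, 0.25, 0.25, 0.125, 0.125)
P   <- markov_matrix(expm_via_dft(rate_vector(G, psi)))
round(P[1:3, 1:4], 6)
#>          0        1        2        3
#> 0 0.413050 0.085855 0.083415 0.124205
#> 1 0.085855 0.413050 0.085855 0.083415
#> 2 0.083415 0.085855 0.413050 0.085855
```

Note f(1) = 0.085855 ≠ 0.083415 = f(2): the exponential does *not*
respect the 3-block labeling {0}|{1,2,5,6}|{3,4} used to build ψ (that
labeling is not G-compatible — `is_compatible()` returns `FALSE`), but
it does respect the finer pair labeling, under which the matrix is
embeddable and the generator is recovered exactly:

```r
L <- parse_labeling(G, "{0}|{1,6}|{2,5}|{3,4}")
rep <- check_embeddable(P, group = G, labeling = L)
rep
#> <embeddability report: embeddable>
#> product-inequality slacks:
#>   1,6              0.875
#>   2,5              0.875
#>   3,4              1.75
rep$generator$psi
#> [1] -1.000  0.125  0.125  0.250  0.250  0.125  0.125
```

The slacks are |𝒢|·ψ(g) of the generator: a slack of zero would put *P*
on the boundary of the embeddable set. Volumes for the hachimoji
3-parameter model:

```r
exact_volume(eigen_region("H3P", "delta_plus"))
#> <volume 7/16 = 0.4375 (exact)>
h3p_me_volume("me_and_dd")
#> <volume 0.13673251 (quadrature)>
```

A thin command-line wrapper lives at
`system.file("scripts", "gbembed.R", package = "gbembed")` with
subcommands `dft`, `labelings`, `structure`, `check`, `generator`,
`volume`, `fixtures`; `check` exits 0 for embeddable and 3 otherwise,
so it can gate shell pipelines.

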