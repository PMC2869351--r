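# semirigid

Optimal identification of semi-rigid domains in macromolecules from
conformational ensembles.

Proteins and other large molecules typically move as a handful of nearly
rigid units — domains — connected by hinges and flexible linkers. Given an
ensemble of conformations of the same molecule (MD trajectory frames, NMR
models, or several crystal structures), `semirigid` finds the partition of
atoms into M domains that is *optimal* in a precise sense: it minimizes the
distance deviations left inside the domains. The package is aimed at
structural bioinformaticians and simulators who want a reference-free,
parameter-light coarse-graining of their ensembles, with an error measure
that says exactly how rigid the resulting domains are.

## Method

1. **Distance-deviation matrix.** For each atom pair, the ensemble average
   of the deviation of the inter-atomic distance d_ij(t) from its mean:

       D_ij = ⟨ |d_ij(t) − ⟨d_ij⟩| ⟩        (absolute mode, nm)

   (or the distance variance in squared mode). D is symmetric, zero on
   rigid blocks, and — being built from internal coordinates only —
   invariant under per-frame rigid motion: no superposition, no reference
   structure. The mean row value of D is a per-atom flexibility profile.

2. **Constrained quadratic optimization.** Fuzzy memberships p_ik (each
   atom's row on the probability simplex) minimize the clustering error

       E = Σ_k p_kᵀ D p_k

   — the deviation mass neglected by treating domains as rigid. The
   relaxation makes the problem continuous, yet optima are vertex (0/1)
   assignments in practice, so a hard partition falls out. The solver is
   projected gradient descent with exact per-row simplex projection plus
   an exact vertex-polish (row-wise coordinate descent and pairwise
   exchanges); the block structure of the Hessian is exploited so only D
   itself is ever stored.

3. **Choosing M.** E(M) decreases monotonically (successive-restart warm
   starts make this true by construction); the normalized error E_N — the
   average deviation between an atom and its domain co-members, in nm —
   is compared with a user bound ε (default 0.1 nm) to pick the smallest
   adequate M automatically.

A brute-force enumerator over hard assignments provides exact global
optima on small instances and is used throughout the tests to certify the
solver. A synthetic generator (articulated rigid bodies + noise) supplies
ground-truth ensembles. See `vignettes/semirigid-methods.Rmd` for the full
account.

## Worked example

```r
library(semirigid)

# six rigid bodies joined by five hinges, 200 noisy frames, known truth
gt <- generate_hinged_ensemble(preset_ala5_like())
D  <- deviation_matrix(gt$ensemble)          # 22 x 22, absolute mode, nm

series <- solve_series(D, M_max = 8, restarts = 10, seed = 0)
round(vapply(series, function(r) r$E, 0), 3)
#> [1] 16.077  4.440  2.506  1.512  1.101  0.694  0.580  0.469
round(vapply(series, function(r) r$E_N, 0), 4)
#> [1] 0.0348 0.0202 0.0179 0.0153 0.0134 0.0116 0.0118 0.0120

series[[6]]$assignment
#> [1] 1 1 1 2 2 2 2 3 3 3 3 4 4 4 4 5 5 5 5 6 6 6
same_partition(series[[6]]$assignment, gt$labels)
#> [1] TRUE

sel <- select_num_domains(D, epsilon = 0.012, seed = 0)
sel$n_domains
#> [1] 6
```

The error series drops steeply while genuine bodies are being separated
(E falls from 16.1 nm at M = 1 to 0.69 nm at M = 6) and flattens once only
intra-body noise remains; the M = 6 assignment reproduces the generator's
ground truth exactly, and the automatic selector picks M = 6 for an ε
between the M = 5 and M = 6 normalized errors (here 0.012 nm).

From the shell, the same pipeline runs as:

```sh
Rscript inst/scripts/semirigid-cli.R --pdb ensemble.pdb --auto-eps 0.1 \
        --seed 0 --out results/myrun
```

writing the deviation matrix (CSV), flexibility profile (CSV), per-M JSON
report, a domain-colored PDB (domain label in the B-factor column,
scaled flexibility in occupancy) and a log.

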