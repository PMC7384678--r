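---
title: "Coupled graph-regularized factorization of drug-disease and drug-target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled graph-regularized factorization of drug-disease and drug-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Drug repositioning asks which existing drugs might treat which diseases;
drug-target prediction asks which proteins a drug binds. Both are
link-prediction problems on a bipartite network with one drug layer, and both
obey guilt-by-association: similar drugs tend to treat similar diseases and
bind similar targets. `anchornmf` treats the two networks as one coupled
system. Each domain $i \in \{1,2\}$ contributes a binary interaction matrix
$X^{(i)}$ ($n_i$ drugs $\times$ $m_i$ diseases or targets) approximated by
non-negative factors $U^{(i)} V^{(i)\top}$ of rank $r_i$, and the domains are
tied together through the drugs they share.

The fitted objective has four terms:

1. **One-class weighted reconstruction.**
   $\sum_i \lVert W^{(i)} \odot (X^{(i)} - U^{(i)}V^{(i)\top})\rVert_F^2$,
   where $W^{(i)}$ is 1 on observed interactions and $w \in [0,1)$ elsewhere.
   Absent edges are unlabeled pairs, not confirmed negatives, so they are
   down-weighted rather than trusted. Because the weights enter squared, the
   update rules involve $w^2$; the implementation derives every term from
   $W^{\odot 2}$ consistently.
2. **Cross-network consistency.**
   $\beta \lVert S U^{(1)} (S U^{(1)})^\top - U^{(2)} U^{(2)\top}\rVert_F^2$,
   with $S$ the sparse $n_2 \times n_1$ one-to-one anchor mapping (at most a
   single 1 per row and per column). Matching the *Gram matrices* of the
   anchored drug factors — rather than the factors themselves — makes the
   penalty invariant to how each domain happens to rotate or order its latent
   dimensions, and lets the two domains use different ranks.
3. **Within-network smoothness.** Graph-Laplacian traces
   $\alpha \sum_i (\mathrm{tr}(U^{(i)\top} L_u^{(i)} U^{(i)}) +
   \mathrm{tr}(V^{(i)\top} L_v^{(i)} V^{(i)}))$ pull entities that the
   similarity matrices call similar toward nearby latent profiles.
4. **Sparsity.** An elementwise $\ell_1$ penalty
   $\gamma \sum_i (\lVert U^{(i)}\rVert_1 + \lVert V^{(i)}\rVert_1)$.

Predicted association scores are simply $\tilde X^{(i)} = U^{(i)}V^{(i)\top}$;
ranking and masking of training positives is left to the evaluator or to
`rank_candidates()`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `r1`, `r2` | 90, 70 | factor ranks; clamped to $\max(1, \lfloor 0.1\,\min(n_i,m_i)\rfloor)$ with a warning when the data is smaller, following the rank heuristic that trades accuracy against running time |
| `alpha` | 0.01 | smoothness weight (dimensionless; scales with the similarity magnitudes) |
| `beta` | 0.01 | cross-network coupling strength |
| `gamma` | 0.01 | $\ell_1$ weight |
| `w` | 0.3 | confidence of unobserved entries |
| `delta` | 1e-6 | convergence tolerance on the objective change |
| `max_iter` | 500 | sweep budget |

All four penalties are dimensionless trade-off weights; 0.01 is the regime in
which the coupled model is robust on real-scale collections, and sensitivity
there is low across two orders of magnitude.

## Numerical choices

* **Initialization.** Strictly positive uniform entries scaled by
  $\sqrt{\bar X_i / r_i}$ so the initial reconstruction matches the data
  scale. Strict positivity matters: multiplicative updates cannot revive an
  exact zero, so a zero seeded by accident would be locked forever. Each
  domain draws from its own seed derived from `params$seed`, which is what
  makes the decoupled special case exactly reproducible.
* **Update order.** $U^{(1)}, U^{(2)}, V^{(1)}, V^{(2)}$ within a sweep,
  fixed for reproducibility.
* **Division guard.** $\varepsilon = 10^{-12}$ is added to every update
  denominator, after the $0.5\gamma$ shift. This leaves fixed points intact
  to numerical precision.
* **Monotonicity safeguard.** The plain multiplicative ratio step is the
  exact negative/positive split of the halved gradient, so its fixed points
  coincide with the stationarity conditions. For the *quartic*
  cross-consistency term, however, the plain step can overshoot when `beta`
  is large (at `beta = 1` we observed sweeps that increase the objective
  many-fold; this mirrors the known behavior of plain ratio updates for
  symmetric-NMF-type terms). The fit loop therefore evaluates the objective
  after each sweep and, if it rose, retries the sweep with damped updates
  $u \leftarrow u\,(1 - \lambda + \lambda\,\mathrm{ratio})$, halving
  $\lambda$ until the objective is non-increasing. Damping preserves
  non-negativity and fixed points, and is inert in the default
  `beta = 0.01` regime — there the results are bit-identical to the plain
  rule.
* **Convergence.** The loop stops when $|J(t{+}1) - J(t)| \le \delta$
  (absolute, the conventional rule) or after `max_iter` sweeps. Because the
  objective's scale is data-dependent, a relative criterion is available via
  `convergence = "relative"`. Empirically the objective *flattens* within
  ~100 sweeps on desk-scale problems while the absolute change keeps decaying
  polynomially (about $5\times 10^{-2}$ at sweep 100, $10^{-2}$ at sweep 250
  on the default generator), so with $\delta = 10^{-6}$ the absolute rule is
  a statement about deep numerical convergence, not about usable fits;
  `max_iter` is the practical stop.
* **The anchor Gram product** $S^\top S$ is constant across iterations and
  cached once before the loop.
* **Ties in rankings** are broken by candidate identifier (stable across
  platforms); AUPR uses the untied descending-score step curve
  (average-precision style) because trapezoidal interpolation inflates the
  area.

## Degenerate and edge inputs

Empty anchor sets are valid (the model decays to two independent
factorizations, exactly so at `beta = 0` — tested to $10^{-10}$). Drugs or
diseases with no observed interactions are retained; their factor rows are
determined only by the smoothness and coupling terms, and columns with no
observations have a flat reconstruction objective, so their factor rows may
collapse to zero under the $\ell_1$ pull — this is expected. Similarity
matrices are symmetrized as $(A + A^\top)/2$ on ingestion (silently up to
asymmetry $10^{-6}$, with a warning beyond), negatives and non-finite entries
are rejected. The self-similarity diagonal is kept and contributes to the
degrees by default (`include_diagonal = TRUE`); zeroing it first is a switch,
since either convention appears in practice and the difference is a constant
shift of the Laplacian spectrum. Unbounded similarity scales (semantic
disease similarities are information-content based and have no upper bound)
are used as provided, with an optional max-normalization flag; no
thresholding or sparsification is applied.

## What the synthetic generator emulates

`synthetic_spec()` / `simulate_problem()` produce a coupled problem with
planted structure: non-negative latent factors (exponential entries, heavy
tailed so a few strong associations dominate, as in real interaction data);
interactions as the *top-quantile binarization* of $U V^\top$, which realizes
the requested density exactly and keeps the planted low-rank signal
recoverable at desk scale (i.i.d. Bernoulli thresholding would drown it);
anchored drugs carrying identical identifiers in both domains and sharing
their factor rows up to a small perturbation (`perturb_sd = 0.05`);
similarities as cosine kernels over *noise-corrupted* copies of the latent
features (`similarity_noise_sd = 0.5`). The corruption is deliberate:
chemical fingerprints, sequence scores and semantic similarities are weak
proxies for interaction-relevant features. A generator whose similarity
matrices are kernels of the true factors hands the decoupled model the whole
answer through the smoothness term, and no experiment run on it can detect
cross-network transfer.

Default sizes are 100×80 (drug-disease) and 80×60 (drug-target) with 40
anchored drugs (overlap 0.5), densities 0.08, rank 6 and a 1% label-flip
rate — small enough that every experiment in the test suite and acceptance
script runs in seconds to minutes on one core, large enough that held-out
metrics are stable.

What it does **not** emulate: the marginal distributions of real similarity
scores (only their boundedness), unbounded semantic scales, systematic
study bias in which pairs get measured, and drugs whose mechanisms genuinely
differ between domains. Passing the recovery tests therefore demonstrates
the machinery is correct and that coupling transfers signal *when shared
structure exists*; it does not certify performance on any particular real
collection.

## Evaluation protocol

Three five-fold cross-validation scenarios, each repeated independently with
fresh partitions and averaged: **pair prediction** (known positives split
into folds; held-out positives become weight-$w$ unknowns during training;
an equal number of never-observed pairs is sampled as test negatives, and
metrics are computed on the balanced test set), and the two cold-start
scenarios **new drug** and **new disease/target** (entities partitioned;
all interactions of held-out entities removed from training). While one
domain is evaluated, the other domain's network is kept whole — that is the
coupling's entire point. In the cold-start scenarios precision@k is computed
per held-out entity and averaged (that is how a ranked list would be consumed
for a new drug), while AUROC/AUPR are pooled over the held-out entities'
pairs; in the pair scenario all metrics are pooled over the fold's balanced
test set.

The transfer-benefit experiment (`transfer_benefit()`) is deliberately a
cold-start design: it masks all domain-1 interactions of 10 randomly chosen
anchored drugs and compares held-out AUROC between a coupled (`beta = 0.01`)
and a decoupled (`beta = 0`) fit on identical data and initializations,
paired over 10 generator seeds with a sign test. Random pair-level masking
leaves every drug with most of its training signal, and both arms saturate;
cold starts isolate exactly the pathway the cross-network term provides.

Enrichment of top-ranked predictions against a reference set uses the
upper-tail hypergeometric probability $P(X \ge k)$, evaluated in log space
(`stats::phyper(..., log.p = TRUE)`) because relevant p-values sit far below
double underflow of the summed point masses.

## Known limitations

* Scores are bilinear in the latent factors; genuinely non-linear
  interaction structure is out of reach by design.
* The coupling matches Gram matrices, so it transfers *relational* structure
  among anchored drugs; a domain-2-only drug with no anchored neighbors
  gains nothing.
* Dense intra-layer similarity matrices put an $O(n^2)$ floor on memory and
  per-sweep cost; the implementation targets desk-scale problems (thousands
  of entities), not millions.
* With an absolute convergence tolerance the reported `converged` flag is
  conservative; use the relative criterion or the objective trace
  (`tidy(fit)`, `autoplot(fit)`) to judge practical convergence.
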