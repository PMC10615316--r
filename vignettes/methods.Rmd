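---
title: "Methods: identifiable and interpretable discovery of rational ODE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifiable and interpretable discovery of rational ODE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sindysio)
```

## The model class and its assumptions

`sindysio` works with deterministic reaction-rate models

$$\dot x = f(x, p), \qquad y = g(x, p), \qquad x(0) = x_0,$$

where every component of $f$ is a ratio of polynomials in the states with
parameter coefficients. This covers mass-action networks and the standard
saturating rate laws (Michaelis–Menten/Monod, Hill, saturating feedback).
Throughout the package the system is assumed **fully observed**
($y = x$); partially observed systems are out of scope (see Limitations).

Each right-hand side can be combined over a common denominator, giving the
implicit form $\dot x_i\,D_i(x) = N_i(x)$. `to_rational_form()` performs
this normalization exactly (denominator constant term scaled to 1 when
present, otherwise the graded-lexicographic leading coefficient). The
maximum total degrees of $N$ and $D$ in the states decide how rich a
discovery library must be.

## Stage 1 — implicit sparse regression

For a target state $x_i$ and degree $d$, the candidate library contains all
monomials in the states of total degree $\le d$ followed by the same
monomials multiplied by $\dot x_i$ — $2\binom{n+d}{d}$ terms. Every library
term containing the derivative is an admissible left-hand side
$\theta_j$; regressing it on the remaining terms,
$\theta_j = \Theta(X,\dot X\mid\theta_j)\,\xi_j$, turns the implicit
problem $\dot x D(x) = N(x)$ into a family of ordinary sparse regressions.

*Sequentially thresholded least squares (STLSQ)* alternates a least-squares
fit on the active columns with hard thresholding of coefficients below
$\lambda$, until the active set stabilizes. Choices that matter:

* **Column scaling.** Library columns are normalized to unit root mean
  square before thresholding and coefficients rescaled afterwards, so a
  single $\lambda$ is comparable across monomial degrees.
* **Threshold grid.** A sparsity penalty weight is never optimized
  directly; the $\ell_0$ trade-off is realized by sweeping 20
  logarithmically spaced thresholds in $[10^{-4}, 1]$ and selecting on a
  validation set.
* **Selection.** Each assembled candidate $\dot x = N(x)/D(x)$ is scored by
  its mean squared derivative residual on held-out validation data and by
  its complexity $k$ (active coefficients including the left-hand-side
  denominator terms); the AIC $m\log(\mathrm{RSS}/m) + 2k$ is minimized,
  with ties broken by lower complexity, then lower error (AICc is available
  via `small_sample = TRUE`). The residual mean square is floored at
  $(10^{-9}\,\mathrm{sd}(\dot x))^2$: on noiseless data many candidates
  agree with the data to within round-off, and without a floor the
  logarithm would amplify meaningless $10^{-28}$-level differences and
  could prefer a padded model over the sparsest exact one.
* **Degeneracy guard.** Candidates whose denominator approaches zero along
  the training trajectories are discarded before scoring.

The selected per-state fits are *presented* the way such candidate models
are conventionally reported: the denominator is factored into irreducible
factors (a derivative-quotient heuristic, complete for products of factors
linear in some variable), the polynomial quotient is extracted by
multivariate division, the remainder is partial-fractioned across the
factors, and every coefficient slot — quotient monomials, rational-term
numerators, and each factor's denominator coefficients — receives a fresh
parameter $p_1, p_2, \dots$ This presentation is what makes the
overparameterization of the raw fit visible to the identifiability stage
(each rational term can be rescaled freely, so its coefficients are
individually unidentifiable).

## Stage 2 — structural identifiability and observability

Parameters are treated as constant states: $\tilde x = (x, p)$ with
$\dot p = 0$. The observability–identifiability matrix stacks gradients of
iterated Lie derivatives of the output,

$$OI(\tilde x) = \frac{\partial}{\partial\tilde x}
\big(g,\; L_{\tilde f}g,\; L_{\tilde f}^2 g,\; \dots\big),$$

and the model is FISPO iff the generic rank equals $n + n_p$. The package
decides ranks **exactly**:

* The matrix is specialized at random integer points (components drawn
  from $2..97$, redrawn if a denominator vanishes) and its rank computed by
  Gaussian elimination **modulo the prime $2\,097\,143 < 2^{21}$**, so all
  products of residues are exact in double precision. A rank obtained this
  way lower-bounds the generic rank and equals it except on a vanishing set
  of unlucky points; three independent specializations are used
  (`n_trials = 3`) and the maximum taken. There is no floating-point rank
  tolerance anywhere.
* Rather than expanding Lie derivatives symbolically (which blows up
  exponentially with the order), the rows at a specialization point are
  obtained from truncated power series: if $z(t)$ solves the augmented
  system with $z(0) = \tilde x_0$ and $S(t) = \partial z/\partial
  \tilde x_0$ solves the sensitivity equation $\dot S = (\partial\tilde
  f/\partial \tilde x)(z)\,S$, then the order-$i$ block of $OI(\tilde x_0)$
  equals $i!\,[t^i]\big(\partial g/\partial\tilde x(z(t))\,S(t)\big)$,
  because the gradient of the $i$-th output derivative with respect to the
  initial augmented state *is* the gradient of the $i$-th Lie derivative.
  Series coefficients are propagated in the same modular arithmetic. This
  keeps the largest packaged analysis (a 36-dimensional augmented
  candidate model) below a second.
* The Lie-derivative order is increased until the rank is unchanged over
  two consecutive orders, full rank is reached, or the theoretical bound
  $n_{\tilde x} - 1$ is hit. A fully symbolic `lie_derivative_rows()` is
  also provided (used in the tests to cross-check the series route) with an
  expression-size budget that flags truncation instead of hanging.
* Individual parameters and states are classified by a column-deletion
  test: a variable is structurally unidentifiable (unobservable) iff
  deleting its column leaves the generic rank unchanged. The test is the
  standard choice; the rank criterion itself only certifies *local*
  identifiability.

## Stage 3 — symmetry detection and breaking

Rank deficiencies in this model class come from one-parameter Lie groups
acting on the parameters while leaving the output invariant. With all
states observed, output invariance forces the state components of any
generator to vanish, and compatibility with the dynamics reduces to the
linear determining equations

$$\sum_j \frac{\partial f_i}{\partial p_j}\,\eta_j(p) = 0
\quad\text{identically in } (x, p).$$

The search ansatz takes each component $\eta_j$ as a univariate polynomial
in its own parameter of degree $\le 2$, which represents exactly the three
canonical families — translations ($\eta = c$), scalings ($\eta = c\,p$)
and Möbius transforms ($\eta = c\,p^2$) — and, empirically, every symmetry
occurring in the six case studies. After clearing denominators the
determining equations become an exact rational linear system in the ansatz
coefficients; its nullspace (computed by exact fraction arithmetic, basis
vectors scaled to coprime integers) is the symmetry space. The package
deliberately reports an **unresolved deficiency** if the nullspace dimension
falls short of the rank deficiency, rather than guessing outside the
ansatz.

Breaking a symmetry fixes the group parameter so that a chosen pivot
parameter reaches a constant (0 for translations, 1 for scalings and
Möbius) and renames the other affected parameters to composites
($\gamma^* = \gamma/\alpha$, $a_3^* = a_3 - a_1$, …). The pivot is
arbitrary in principle; the automatic rule prefers, for scalings, an
affected parameter multiplying the lowest-order monomial of a denominator
(this yields the conventional "denominator constant = 1" normal forms) and
otherwise the lowest declaration index. `autorepar()` alternates
classification and single-symmetry breaking — symmetry bases can change
after a substitution — and terminates because each break removes one
unknown parameter.

## Stage 4 — reformulation against a kinetic dictionary

A FISPO model need not be interpretable: rational terms may appear in
algebraically rearranged forms. The reformulation stage rewrites each state
as a polynomial part plus proper rational terms over the irreducible
denominator factors, then annotates each rational term $A/F$ with a
dictionary entry:

1. directly, when $A/F$ already matches a pattern (structural unification
   on the normalized form: equal monomial supports, wildcard constants read
   off the coefficients); or
2. after **re-splitting**: for a dictionary numerator monomial $m$, the
   decomposition $A/F = c\,m/F + q$ with polynomial $q$ exists precisely
   when $F \mid (A - c\,m)$ for some constant $c$, a condition read off the
   proportionality of the reduction remainders of $A$ and $m$ modulo $F$ —
   and *invariant* under the division variant used to obtain $A$. This is
   the step that rewrites, e.g., a reciprocal saturation
   $c/(1+Kx)$ into saturating feedback $c'x^2/(1+Kx)$ plus mass action.

When several re-splittings are admissible (always the case for univariate
linear denominators), the **highest-degree dictionary numerator** is
preferred, ties broken by dictionary order; this reproduces the canonical
saturating-feedback and Monod forms. A term matching the dictionary as-is
is never re-split (re-splitting strictly adds terms). The default
dictionary is data (`inst/extdata/kinetics.json`), user-replaceable.

Two arithmetic routes share one code path: models carrying fitted numeric
coefficients use double-precision arithmetic with a relative tolerance of
$10^{-8}$ for zero tests (fitted values satisfy the required cancellations
only up to round-off), while purely symbolic models use exact
rational-function coefficients and tolerance 0. Equivalence of the result
with its input is verified — symbolically where possible, otherwise by
evaluation at random points — and FISPO is re-checked, with `autorepar()`
re-entered if the rewrite ever broke it.

One presentation freedom deserves note: a Hill term can be written as
activation ($c\,x^n/(1+Kx^n)$) or as its complement, repression plus a
constant; both are dictionary members and mechanistically sensible, and the
as-is-first policy keeps whichever form the candidate model delivered. The
packaged competence-circuit benchmark therefore reports its ComK
autoregulation as a repression term plus constant — the algebraic
complement of the activation form, equal as a function.

## The synthetic-data generator

`training_data()` simulates the ground-truth model with a stiff-capable
adaptive integrator (`deSolve::lsoda`, tolerances $10^{-10}$) from an
ensemble of initial conditions (the nominal $x_0$ plus multiplicative
jitter of $\pm 40\%$, fixed seed) and evaluates derivatives **exactly** by
applying the right-hand side at the sampled states. The ensemble matters:
a single trajectory of a low-dimensional dissipative system explores too
thin a subset of state space, and monomial columns become collinear on it.
Validation data use a $\times 1.25$ perturbation of $x_0$ — conditions
disjoint from training. Per case the defaults are 8 trajectories of 60
samples (Lorenz: one chaotic trajectory of 250 samples; the glycolytic
model: 6 × 80), horizons of 8–12 time units, and the smallest library
degree that embeds the ground truth's rational form (2, 3, 6, 2, 3 and 5
for the six cases in registry order).

`corrupt()` adds zero-mean Gaussian noise scaled per state by the state's
standard deviation and recomputes derivatives by central differences (or a
moving-average smoother) — the standard noise model in this literature.
**What passing the noiseless benchmarks shows:** that the pipeline's
algebra — structure recovery, rank analysis, symmetry breaking,
reformulation — is correct at regular parameter points. It does *not*
establish robustness to realistic measurement noise, non-exact derivative
estimation, unmodelled dynamics, or partial observation; those require the
noise options and are deliberately not part of the acceptance surface.

Ground-truth parameter values are regular order-one points chosen once so
that all states vary and denominators stay away from zero (the Lorenz case
uses the classical chaotic triple $(10, 28, 8/3)$). The glycolytic
fixture transcribes its published seven-pool equation structure verbatim —
including one reused coefficient symbol in the fourth equation — and that
printed structure is not consistent with the original oscillator's
parameter table, so its values are likewise order-one stability-tuned
choices. Every value is recorded in the fixture files; all
structure-recovery claims are parameter-point-free in the sense that they
hold at any regular point.

## Numerical choices, degenerate inputs, tie-breaks

* Exact rational coefficients are stored as reduced integer fractions in
  doubles with an overflow guard at $2^{52}$; fitted doubles entering
  symbolic contexts are rationalized by continued fractions (relative
  tolerance $10^{-11}$), which snaps OLS output such as
  $0.6666666666663$ to $2/3$.
* Rational-function normalization cancels exact divisibility, common
  monomial content, and (factor-wise, via the heuristic factorizer) common
  irreducible factors — the last being what keeps iterated quotient-rule
  denominators at their minimal power in Lie-derivative computations.
* STLSQ on a rank-deficient active set zeroes the aliased columns and
  warns; an all-eliminated active set returns a flagged all-zero fit, not
  an error. An implicit fit whose derivative coefficient vanishes
  identically cannot be solved for $\dot x$ and is dropped with an error.
* Partial-fraction numerator supports are the monomials not divisible by
  the factor's leading monomial; if the linear system for a presentation is
  inconsistent the unfactored single-term presentation is used instead.
* AIC ties are resolved by complexity, then residual; equal presentations
  arising from different thresholds are deduplicated by support and
  coefficients.

## Limitations

* Partially observed systems: the symmetry ansatz exploits full
  observation; with unobserved states the package still computes ranks and
  classifications, but `autorepar()` may report unresolved deficiencies.
* Only local (not global) structural identifiability is certified.
* The factorization heuristic is complete for denominators that are
  products of factors linear in some variable — the shapes arising from
  the supported rate laws — not for general multivariate polynomials.
* Generators outside the per-parameter polynomial family (e.g. symmetries
  mixing several parameters nonlinearly in one component) are not searched.
* The discovery stage assumes exact or low-noise derivatives; heavy noise
  requires external smoothing beyond the bundled options.
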