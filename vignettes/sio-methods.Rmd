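---
title: "Structural identifiability and observability analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural identifiability and observability analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odesio)
```

## The question the package answers

Given a nonlinear ODE model
$\dot x = f(x, u, \theta)$, $y = h(x, u, \theta)$ with $n$ states,
$p$ unknown parameters, known inputs $u$ and $m$ measured outputs, we ask
whether each parameter is *structurally locally identifiable* (SLI) —
uniquely determined, near almost every parameter vector, by perfect
input/output data on a finite horizon — and whether each state is
*observable* from those same data.  Parameters are constant states, so
both questions reduce to observability of the augmented state
$\tilde x = (x, \theta)$ with dynamics $\tilde f = (f, 0)$.  A model in
which every parameter is SLI and every state observable has *full input,
state and parameter observability* (FISPO).  These are properties of the
equations and the measurement choice alone; no data are consumed
anywhere in the package.

Augmented components are ordered states-then-parameters throughout; every
per-column classification refers to this fixed order.

## Engine 1: Lie derivatives and the rank condition

The observability–identifiability matrix stacks the Jacobians of the
outputs and their Lie derivatives along $\tilde f$,

$$OI(\tilde x) = \begin{bmatrix}
\partial h/\partial \tilde x\\
\partial (L_f h)/\partial \tilde x\\
\vdots
\end{bmatrix},
\qquad
L_f h = \frac{\partial h}{\partial \tilde x}\tilde f
      + \sum_{j\ge 0} \frac{\partial h}{\partial u^{(j)}} u^{(j+1)},$$

and generic rank $n+p$ certifies FISPO.  When the rank is deficient,
each augmented component is classified by deleting its column and
recomputing the rank: a drop marks the component as determinable (SLI /
observable), no drop marks it free (SU / unobservable).  Note that the
number of free columns usually exceeds the rank deficiency: one shared
continuous symmetry (for instance the scaling
$x_2 \to c\,x_2,\ b_{12} \to b_{12}/c,\ b_{22} \to b_{22}/c$ of a
two-species Lotka–Volterra model measured through $x_1$) makes several
columns simultaneously free while costing a single rank.

$n+p-1$ derivative orders always suffice, but for most models the rank
stabilizes much earlier, so by default orders are added only until one
more order fails to increase the generic rank.  This early stop is
validated against the second engine, which never truncates.

Inputs are assumed generically smooth unless the model declares a finite
number of nonzero derivatives (`input_derivatives`; `0` means a constant
input).  The derivative symbols $u', u'', \dots$ enter the Lie calculus
explicitly and are specialized like any other symbol.

## Engine 2: probabilistic algebraic observability

The default engine avoids symbolic Lie derivatives entirely.  It
specializes $\theta$, the initial conditions and the input coefficients
at random field elements, solves the augmented ODE together with its
variational system
$\dot X = (\partial \tilde f/\partial \tilde x)\,X$, $X(0) = I$, as a
power series in $t$ truncated at order $n+p+1$, and stacks the series
coefficients of $\partial y/\partial \tilde x(0) = (\partial h/\partial
\tilde x)\,X(t)$ into a coefficient Jacobian with one column per
augmented component.  Its rank equals the generic OI rank, and the
*transcendence degree* $(n+p) - \mathrm{rank}$ is zero exactly for
algebraically observable (FISPO) models.  Free components are located by
the same column-removal rule as in the first engine, which makes the two
engines comparable row by row — an equivalence the test suite asserts on
every zoo configuration with $n+p \le 12$ and on random linear systems.

The series coefficients satisfy the ODE recurrence exactly and this is
asserted on every solve.  Each input is specialized as a random
polynomial in $t$ whose degree is the input's nonzero-derivative count
(degree $n+p$ for a generic smooth input).

## Exact arithmetic, and why a prime field

Ranks are never computed in floating point: there is no tolerance to
tune, and a tolerance wrongly chosen would silently flip
classifications.  All evaluation happens in $\mathrm{GF}(p)$ with
$p = 2^{31}-1$, where products of residues fit exactly in 64-bit
integers.  Random specializations are drawn uniformly from $[2, 2^{20}]$
— bounded away from 0 and 1 so that, e.g., interaction monomials that
vanish at the origin are not trivially annihilated.  Rank at a random
point can only *under*estimate the generic rank, and only on a
measure-zero locus, so each rank is the maximum over `trials = 2`
independent specializations; specializations that hit a pole of a
rational expression (division by zero in the field) are redrawn, with an
error only after five failures.  A second prime (2147483629,
`field = "modular2"`) provides an independent field for cross-checks: a
wrong classification would require the same minor to vanish modulo both
primes at independent random points.

Arbitrary-precision rational arithmetic would be an alternative working
field; it is not used because the probabilistic guarantees are identical
while modular coefficients stay bounded, which is what makes the
largest zoo models (n+p = 48, series order 49) run in about a second.
All field kernels (DAG evaluation on scalars and on truncated power
series, the sensitivity recursion, Gaussian elimination) are implemented
in C++.

Symbolically, every expression lives in one hash-consed DAG restricted
to rational-function arithmetic (`+ - * / ^` with integer exponents and
exact rational literals).  Forward-mode differentiation on the DAG with
memoization keeps repeated subexpressions shared, which is what makes
Lie-derivative towers tractable where naive expression trees grow
exponentially.

## The model zoo and its study conditions

The zoo reproduces five families of microbial community models at the
dimensions used in the reference classification study; the expected
classifications for all 157 concrete (model, dimension, measurement)
configurations are encoded in `inst/extdata/expectations.tsv` and
regenerable from the shorthand expansion rules (`zoo_expectations()`).

* **gLV** (`glv_model(n)`, n = 2, 3): $\dot x_i = r_i x_i + \sum_j
  b_{ij} x_i x_j$, one growth rate per species and one directed
  interaction rate per ordered pair.  Measurement configurations: all
  states, every single state, every pair (n = 3), and the relative
  measures RM, $y_i = x_i / \sum_j x_j$.
* **cLV** (`clv_model(n, input)`): the compositional counterpart after
  the additive log-ratio transform, reduced by
  $\pi_n = 1 - \sum_{i<n}\pi_i$.  Only the reduced (barred) parameters
  are treated as unknowns, because the reduction makes the original gLV
  parameters non-recoverable by construction; the interaction index j
  keeps its full range 1..n with $\pi_n$ substituted (the alternative,
  truncating j at n−1, is an equivalent reparameterization).  The
  optional measured perturbation enters as one generic smooth input.
* **QSMI** (`qsmi_model(n, nm)`): quadratic consumer-resource kinetics
  with species and metabolite dilution, constant metabolite influx and
  by-product production $\phi_{ilj} x_i m_l$.  The consumption term
  $k_{ij} x_i m_j$ and the diagonal by-product term $\phi_{ijj} x_i m_j$
  contribute the same monomial, so those pairs can never be separated —
  a structural fact the tests assert on every configuration.
* **MSMI** (`msmi_model(n, nm, reading)`): the Monod-kinetics variant.
  The compact printed form of this family admits two readings, and the
  package implements both.  Under the default `reading = "product"` the
  half-saturation acts on the species–metabolite product
  ($V_{ij} m_j/(K_{ij} + m_j x_i)$ in the growth term,
  $V^*_{ij} x_i m_j/(K^*_{ij} + x_i m_j)$ in the consumption term, with
  the by-product denominators sharing the $K^*$ family), which makes
  consumption and diagonal by-product terms the same functional form —
  the Monod analogue of the QSMI degeneracy — and reproduces the
  reference classifications in full.  `reading = "classic"` uses
  textbook denominators $K + m$; it removes that degeneracy and makes
  the fully measured model FISPO, which contradicts the reference table,
  so it is kept only as a documented alternative.  A further switch
  replaces the shared by-product constants by an independent family
  (`shared_byproduct_K = FALSE`); sharing is the default because only
  the shared inventory matches the reference parameter sets.
  Reproduction reports record both switches.
* **PC** (`pc_model(scaled)`): the phage cocktail therapy model with
  sensitive/resistant bacteria, their phages and the immune response.
  The phage injection rates are dosing quantities, known to the
  experimenter, and enter as exact rational known constants; they are
  set to the distinct nonzero values 1/10 and 1/5 (any generic distinct
  pair serves — equal values would introduce an artificial
  strain-exchange symmetry the application does not have).  In the
  scaled variant the term printed as $\omega x_5^3$ is implemented as
  $\omega x_5$, matching the structure of the parallel $x_3$ equation
  (the cube is a typographical artefact).  Similarly the growth rate
  printed once as $r_i$ in the original model is the single rate $r$.

## What the oracles do and do not show

Two ground-truth sources are independent of both engines.  Random linear
systems $\dot x = Ax$, $y = Cx$ (small integer entries, sparsity 0.5,
measured states selected by the seed, $n \le 8$ to keep exact Kalman
ranks instant) are classified by the Kalman rank condition; both engines
must match rank and per-state status on 100 of 100 fixtures.
Symmetry fixtures are nonlinear models whose SU sets are certified by an
explicit transformation, and the tests also verify the transformation
itself: applying it to a specialized trajectory leaves the output series
coefficients unchanged, while a non-symmetry perturbation does not.

These checks validate the machinery, not real-data performance: the
whole analysis is *structural*.  A parameter classified SLI can still be
practically unidentifiable from noisy, sparse data, and the analysis is
local — distinct parameter vectors producing identical outputs at finite
distance are not excluded.  Unknown (unmeasured) inputs, initial
conditions treated separately from states, global identifiability and
symmetry-group reconstruction are out of scope.

## Reproducibility and problem sizes

Every analysis flows from one integer seed; per-row seeds of a table
reproduction are derived from the master seed, and all random draws are
logged in the result's evidence for replay.  JSON reports carry no
volatile fields (runtimes are printed but kept out of the files), so
identical invocations are byte-identical, and classifications are
invariant across seeds — the acceptance script measures this by
repeating all 157 configurations under an independent seed.  The seed
robustness guard is the `trials` maximum plus the two-prime cross-check;
no automatic tie-break across seeds is performed, since a disagreement
has never been observed and would surface in the determinism checks.

Typical single-CPU runtimes: any gLV/cLV/QSMI configuration well under a
second; the largest MSMI model (3 species, 2 metabolites, n+p = 48)
about a second per specialization with the algebraic engine; a full
five-table reproduction under a minute; the test suite about two
minutes.  The Lie engine is exercised where its symbolic cost is
reasonable (n+p ≤ 12 and all linear fixtures); the algebraic engine is
the default everywhere.
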