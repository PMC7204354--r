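---
title: "Diagnostic reasoning over uncertain causality graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic reasoning over uncertain causality graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ducg)
```

## The model

A dynamic uncertain causality graph represents diagnostic knowledge as a
DAG over four variable kinds. Root causes (**B**) carry prior state
probabilities; observables (**X**) are effects; logic gates (**G**)
combine inputs through sum-of-products state expressions, with state 0 the
remnant (complement); default causes (**D**) are single-state,
always-occurring stand-ins for "something else caused this observable".
State 0 of a B or X variable is the normal state.

The causal mechanism is *per arc*, not per family as in a Bayesian
network's conditional probability table. An arc `V_i -> X_n` holds a
weight `r_{n;i} >= 0` and a matrix of causal-function probabilities
`a_{n,k;i,j}`: the probability that the parent, in state `j`, drives the
child into state `k`. Each matrix column, when fully specified, sums to 1
over child states. The child's distribution is the `r`-weighted mixture of
its parents' columns. Because each mechanism is independent, removing a
parent from consideration does not invalidate the remaining parameters —
the weights simply renormalize over the parents that remain. That
decoupling of structure and parameters is what makes evidence-driven
simplification sound, and it is the property the whole engine is built
around.

Unknown parameters (`NA` in R, `null` in the JSON format) are first-class:
they mean "not elicited", and they are distinct from an explicit 0, which
is hard structural knowledge ("this parent state cannot cause that child
state"). Inference never reads an unknown silently; if a value is actually
needed the evaluation stops with a missing-parameter error naming it
(e.g. `a4,1;8,0`).

## The reasoning pipeline

`diagnose()` runs three stages, each separately exported.

**1. Simplification, tracking, pruning** (`simplify_graph()`,
`track_causality()`, `build_hypothesis_space()`). Each abnormal
observation is traced upstream through viable links. A link is viable if
the entry for the required child state and the parent state is not an
explicit zero, the parent state does not contradict an observation, and
the parent itself is grounded — recursively reaching the candidate root
cause or a default cause. Abnormality is never attributed to a parent's
normal state: state-0 columns are not consulted when explaining an
abnormal event. (Normal-state literals *inside gate products* are
conditions, not causes; unobserved ones expand over all parent states.)
A B-state event becomes a candidate only if (a) every abnormal observation
is grounded in its context, (b) at least one observation reaches the B
event itself rather than only a default cause, and (c) the in-context
symbolic expansion of the evidence retains at least one term. Condition
(c) goes beyond per-observation reachability: two individually viable
chains can force contradictory states on a shared ancestor, and such a
candidate cannot jointly explain the evidence. The check is symbolic and
needs no parameter values.

**2. Weighted logic event expansion** (`expand_event()`,
`expand_evidence_product()`). Within a context, an abnormal event expands
as the weighted sum over kept parents and admissible parent states of
causal-function events times the parent event, recursively down to B/D
events. Weights are the context-renormalized `r'_{n;i}/r'_n`, kept as
exact rationals (reduced integer fractions whenever the `r` weights are
integers, which covers every model in this package; non-integer weights
fall back to floating ratios). The whole evidence product is expanded
jointly in one term set: each term carries its pending literals and the
state assignment implied by its events, every literal is expanded at most
once per term (idempotence), a term whose events disagree about any
variable's state vanishes (exclusion), gate products contradicting an
observation vanish, and gate sums are reduced by absorption
(`X + XY = X`). Expanding jointly rather than multiplying per-observation
expansions is what keeps repeated traversals of shared ancestors from
deflating coefficients, and it makes the product of an expression with
itself the expression again — the expression-level idempotence that the
calculus requires. `expr_multiply()` exposes the same product semantics
for standalone expressions, including conditional absorption: a factor
that merely re-expands a child event a term already explains through a
different cause is absorbed whole.

**3. Probabilistic reasoning** (`eval_expression()`,
`compute_state_probabilities()`, `ranked_independent_probabilities()`).
An expression evaluates to the sum over terms of coefficient times the
product of its `a` and `b` parameters (default causes contribute 1);
additivity is exact because weights across parents sum to one, so no
inclusion–exclusion is applied. Per candidate context, `zeta` is the
in-context prior probability of the evidence and `h` the ratio
`Pr{H E}/Pr{E}` (1 whenever the hypothesis is the context's sole root
cause, as every term then contains it). Reported state probabilities are
normalized as `h_k zeta_k / sum(h zeta)`. When all per-context `h` are 1
this is exactly the zeta-weighted normalization; writing it over the sum
of `h zeta` (rather than the sum of `zeta` alone) keeps the reported
probabilities summing to 1 even in the rare case of a term set not
containing the hypothesis (evidence fully covered by default causes).
Probabilities are reported at full precision and rounded to 3 decimals
only in printed reports; candidate order (and any tie) is deterministic,
sorted by variable index.

### Exclusive categories, concurrency, composition

Category sets declare domain constraints among root causes: members of one
*exclusive* set cannot co-occur (`B_{i,1} B_{i',1} = 0`); members of the
*concurrent* set, and members of different categories, may. When an
exclusive category retains several candidates, they are merged into a
dummy basic variable (`build_dbv()`): state `s` of the DBV stands for
candidate `s`, inherits its causal columns (explicit zeros and unknowns
preserved; a candidate with no arc to a child contributes an explicit-zero
column), merges arc weights as the sum over candidates with nonzero
mechanisms, and puts the candidate priors on states `1..m` with the
remainder on state 0. Exclusion thereby becomes the inherent exclusion
between states of one variable, and ordinary state ranking resolves the
category (ties break toward the lower variable index). The surviving
candidates — at most one per exclusive category, plus all concurrent and
uncategorized ones — compose into the *maximal* conjunction: exploring
every possible outcome before ruling any basic event out means the
ultimate hypothesis is never a proper subset of what the evidence
supports. As the unique element of the final hypothesis space its
normalized state probability is reported as 1; the discriminating numbers
are the ranked independent probabilities, computed for each constituent on
its *individual* tracking graph and normalized to sum to 1. Models with no
declared categories (like the worked example) skip composition: their
candidates are alternative hypotheses ranked by `h`.

## The oracle

`enumerate_joint()` is an independent brute-force reference: it enumerates
the full joint under the generative reading of the weighted expansion
(roots from priors, gates deterministic, observables from the weighted
mixture over all parents) and `posterior_b_states()` conditions on the
complete evidence by summation. It shares no code with the symbolic
engine, and the test suite requires agreement to 1e-9 on a subclass of
models where the two semantics provably coincide: a single root cause (so
no context ever prunes a parent and renormalization is the identity),
full parameterization, inert normal states (state-0 columns
`(1, 0, ...)`), and abnormal-only evidence. Outside that subclass the two
differ by design: the engine excludes observed-normal findings from the
evidence product (they still prune), while the oracle conditions on them —
the worked example fixes this reading, since its evidence list contains
only abnormal states while normal findings elsewhere still discriminate.
For exclusive categories the oracle's `exclusive = "merge"` option treats
each category as one multinomial choice (prior `b_i` for exactly member
`i`, the remainder for none), which is the prior semantics the DBV
construction encodes; conditioning independent priors on "not both" would
instead introduce `(1 - b_j)` factors that no category-merging engine can
reproduce.

## The synthetic generator

`generate_model()` draws random valid models for property testing: B
variables first, each X picking 1–3 parents among earlier variables (the
first X from the B pool, so every observable is causally connected to a
root), optional two-input gates with randomly partitioned state
expressions, causal columns from a clamped exponential simplex (entries
at least ~0.05 after normalization, so no accidental explicit zeros),
priors with 0.85–0.95 normal mass, and all weights 1. With
`unknown_fraction` set, unknowns are placed only where abnormal-evidence
reasoning never looks (state-0 columns, state-0 prior entries), keeping
every generated problem solvable. `generate_evidence()` forward-samples
the model until a joint assignment with the requested number of abnormal
observables appears, guaranteeing positive evidence probability. Both are
pure functions of their seed.

The generator emulates the *structure* of diagnostic knowledge bases —
sparse typed DAGs, small priors, per-arc mechanisms — not real clinical
data: there is no measurement noise, no correlated elicitation error, no
missing-not-at-random observation process. Passing tests therefore show
the calculus is implemented exactly, not that any particular clinical
model is well calibrated.

Problem sizes used in the test suite were chosen to keep exhaustive
enumeration exact and fast: oracle-equivalence models have at most 8
variables with at most 3 states (a few thousand joint assignments; 100
models run in seconds), the autonormalization sweep uses 50 seeds, and the
Monte-Carlo cross-check uses 1e5 forward samples against a binomial
3-sigma band.

## The demonstration model

`bppv_demo_model()` is a ~30-variable model for subtype differentiation of
benign paroxysmal positional vertigo, using the published variable
identities (canal subtypes, etiologies, mechanisms, atypical forms; shared
vertigo symptomatology; demographic findings driven by default causes;
positional-test findings whose explicit-zero columns differentiate
canals). Its parameters are invented placeholders — the clinical model's
parameters were never published (its own reported size is inconsistent
between sources) — and the model says so in its metadata. Tests assert
only structural outcomes on it: candidate sets, hypothesis composition,
and normalization of the ranked probabilities. The two demonstration
evidence sets produce a three-part and a four-part composed hypothesis
respectively, mirroring the published case structure.

## Numerical and design choices

- **Rational coefficients.** Expansion coefficients are exact reduced
  fractions over doubles (exact below 2^53); only final evaluation is
  floating point. Hand-rolled because no installed package provides exact
  rationals; ~40 lines.
- **Explicit zero vs unknown.** Zeros prune (eliminate parent states and
  arcs); unknowns keep chains viable and fail loudly only if actually
  evaluated. The self-reliance tests pin this down by blanking every value
  outside the worked example's expansions and requiring bit-identical
  results.
- **Degenerate inputs.** All-normal evidence yields an explanatory
  empty-space status, not an error; evidence impossible under every
  hypothesis raises a degenerate-evidence condition; oversized enumeration
  requests raise a size error before allocating.
- **Gate remnants.** State 0 of a gate is computed by complement
  enumeration over input assignments (bounded at 4096 combinations);
  nonzero gate states with overlapping expressions are rejected during
  enumeration, and gate sums are absorption-reduced before branching.
- **Known limitations.** No general negation/complement of causal chains
  (only gate remnants and prior remainders); no incremental evidence
  updates (each call is stateless); the oracle does not scale past
  exhaustive enumeration; and dynamic (temporal) aspects of the model
  family are out of scope — models are static DAGs and cycles are
  rejected.
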