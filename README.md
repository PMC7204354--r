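# ducg

Differential diagnostic reasoning with dynamic uncertain causality graphs
(DUCG) — a probabilistic causal graphical model in which every child–parent
causality is represented independently, so that diagnostic inference can
prune, expand and evaluate only the part of the knowledge base the observed
evidence touches, and remains exact under incomplete parameterization.

The package is for people building or studying knowledge-based diagnostic
systems (clinical differential diagnosis, fault diagnosis) who want a
self-contained, inspectable engine: models are plain JSON, every reasoning
step has an exported function, every probabilistic claim can be rechecked
against an exhaustive brute-force oracle, and every result can be traced
back to a symbolic expression in the field's own notation.

## The model and its calculus

A DUCG is a DAG over four variable kinds: **B** (root causes with prior
state probabilities `b_{i,j}`), **X** (observable effects), **G** (logic
gates whose states are sum-of-products expressions over their inputs;
state 0 is the remnant), and **D** (always-occurring default causes).
State 0 of a B/X variable is normal. An arc `V_i -> X_n` carries a
causal-intensity weight `r_{n;i}` and a causal-function matrix with entries
`a_{n,k;i,j} = Pr{A_{n,k;i,j}}`, the probability that parent state `j`
causes child state `k`; `-` (unknown) is distinct from an explicit 0.

Diagnosis proceeds in three steps:

1. **Simplification and causality tracking.** Every abnormal observation is
   traced upstream; a B-state event survives as a candidate hypothesis
   `H_k` only if it can reach all abnormal evidence (default causes may
   cover findings on their own). Within each candidate's context, arc
   weights renormalize over the kept parents: `r'_n = sum of r over kept
   parents`.
2. **Weighted logic event expansion.** Each evidence event expands as
   `X_{n,k} = sum_i (r'_{n;i}/r'_n) sum_j A_{n,k;i,j} V_{i,j}`, recursively
   down to B/D events, under idempotence (`V V = V`), exclusion
   (`V_{i,j} V_{i,j'} = 0`), absorption, and the gate substitutions. The
   evidence product `E = prod_n X_{n,k}` becomes an exact symbolic
   sum-of-products with rational coefficients.
3. **Probabilistic reasoning.** Per context, `zeta_k = Pr{E}` and
   `h_k = Pr{H_k E}/Pr{E}`; the reported state probabilities are
   `h_k zeta_k / sum_k h_k zeta_k`. Mutually exclusive candidates are
   merged into a dummy basic variable (DBV) whose states inherit the
   candidates' columns and priors; concurrent candidates compose into the
   maximal conjunction, with per-constituent **ranked independent
   probabilities** computed on each constituent's individual tracking
   graph and normalized to 1.

## Worked example

The package ships a fully parameterized example graph (two root causes,
nine observables, one logic gate, one default cause) and its seven-finding
evidence set:

```r
library(ducg)
model    <- figure1_model()            # or load_model("inst/extdata/figure1.json")
evidence <- worked_example_evidence()  # X3=1 X5=1 X7=2 X8=1 X9=1 X10=2 X11=2

res <- diagnose(model, evidence)
print(res)
#> <ducg_diagnosis> status: ok
#>   hypothesis state probabilities:
#>     B1,1: h = 0.679 (zeta = 0.00100777)
#>     B2,1: h = 0.321 (zeta = 0.000475891)
```

Both root causes can independently explain all seven findings (B2's state 2
is pruned by an explicit-zero causal entry), and the engine weighs them by
the prior probability of the evidence in each causality context: `zeta` is
0.0010077696 for B1,1 and 0.0004758912 for B2,1, giving final state
probabilities 0.679 and 0.321. The symbolic expansions behind these numbers
are inspectable:

```r
ctx <- track_causality(model, evidence, "B2,1")
expand_evidence_product(evidence, ctx)
#> <ducg_expression> 2 term(s)
#>   1/2 A3,1;7,2 A4,1;8,1 A5,1;4,1 A6,1;8,1 A7,2;8,1 A8,1;2,1 A9,1;6,1 A10,2;10D A11,2;12,1 B2,1
#>   1/2 A3,1;7,2 A5,1;2,1 A6,1;8,1 A7,2;8,1 A8,1;2,1 A9,1;6,1 A10,2;10D A11,2;12,1 B2,1
```

The `1/2` coefficients come from context renormalization: X5 keeps two
parents in B2's context, so each explanation carries weight 1/2.

A larger demonstration model for vertigo-subtype differentiation
(`bppv_demo_model()`, placeholder parameters) shows exclusive categories,
concurrent composition and ranked independent probabilities:

```r
r1 <- diagnose(bppv_demo_model(), bppv_demo_evidence(1))
print(r1$composed)
#> <ducg_hypothesis> B24,1 * B28,1 * B30,1
sum(r1$ranked)
#> [1] 1
```

A command-line interface wraps the same functions:

```sh
inst/exec/ducg diagnose --model inst/extdata/figure1.json \
    --evidence inst/extdata/figure1_evidence.json --report report.json
```

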