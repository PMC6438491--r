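# lcident

Statistical identifiability of latent class models, and its resolution by
intervention data.

## The problem

A binary two-class latent class model explains the association between two
manifest binary items — fear *F* and loathing *L* — through a hidden class
indicator *D* (depression) that renders them conditionally independent:

P(D, F, L) = P(D) · P(F | D) · P(L | D),

with parameters δ = P(D=1), φⱼ = P(F=1 | D=j), λⱼ = P(L=1 | D=j). The
observable cell probabilities are the two-component mixture

θⱼₖ = δ φ₁ʲ(1−φ₁)¹⁻ʲ λ₁ᵏ(1−λ₁)¹⁻ᵏ + (1−δ) φ₀ʲ(1−φ₀)¹⁻ʲ λ₀ᵏ(1−λ₀)¹⁻ᵏ.

Observationally the model is **unidentifiable**: the four cell frequencies
carry 3 independent numbers against 5 parameters, so a 2-dimensional family
of parameter tuples fits any attainable table exactly, maximum likelihood
has no unique solution, and Bayesian estimates retain a prior dependence
that no amount of further observational data removes.

A **stochastic intervention** on the latent node — a treatment that shifts
the prevalence to δ′ = P′(D=1) while leaving the conditionals φⱼ, λⱼ intact
— adds 3 more frequencies for 1 more parameter. The combined six-equation
moment system θⱼₖ = rⱼₖ, θ′ⱼₖ = r′ⱼₖ determines all six parameters uniquely
up to the label swap (δ, φ₀, φ₁, λ₀, λ₁, δ′) ↦ (1−δ, φ₁, φ₀, λ₁, λ₀, 1−δ′);
the qualitative assumption that the treatment *lowers* the prevalence
(δ′ < δ) picks the canonical branch. This package implements the forward
model, two-regime simulation, the moment-system solver with its
degrees-of-freedom and feasibility diagnostics, grid-based Bayesian
posteriors that exhibit (and, with intervention data, lose) prior
dependence, hyperprior estimation through a δ′–δ coupling, and a minimal
discrete causal-network layer with intervention surgery and structure
discrimination. It is aimed at methodologists studying identifiability and
at teaching the use of intervention data in latent variable modelling.

## Worked example

Simulate a treatment study under the standard conditions (δ = 0.6 → δ′ =
0.3, φ = (0.2, 0.7), λ = (0.1, 0.8)), then recover the parameters from the
two frequency tables alone:

```r
library(lcident)

gen <- lca_params(0.6, 0.2, 0.7, 0.1, 0.8)
reg <- intervention_regime(0.3, "reduced")
ds  <- simulate_intervention_study(gen, reg, 10000, 10000, seed = 1)
pre  <- compute_frequencies(ds, "pre")
post <- compute_frequencies(ds, "post")
pre
#> Observed frequencies (pre regime, t = 10000):
#>    r00    r01    r10    r11
#> 0.3233 0.1751 0.1573 0.3443

solve_moment_system(pre, post, direction = "reduced")
#> Moment-system solution set: status = identified_pair, residual = 2.78e-17
#>   branch 1: delta = 0.601652, phi = (0.206267, 0.697137), lambda = (0.0909963, 0.803043), delta' = 0.302795
#>   branch 2: delta = 0.398348, phi = (0.697137, 0.206267), lambda = (0.803043, 0.0909963), delta' = 0.697205
```

Branch 1 recovers the generator to within sampling error (about 0.006 at
n = 10⁴ per regime); branch 2 is its label-swap mirror image — the residual
indeterminacy the direction assumption resolves. The dimension accounting
behind the story:

```r
dof_analysis(gen)
#> Degrees-of-freedom report
#>   parameters: 5, constraints: 3
#>   Jacobian rank: 3, solution dimension: 2

dof_analysis(gen, reg)
#> Degrees-of-freedom report
#>   parameters: 6, constraints: 6
#>   Jacobian rank: 6, solution dimension: 0
```

Observationally two degrees of freedom remain (`solution_manifold()`
returns members of that family); with intervention data the solution set is
zero-dimensional. See the vignette
(`vignettes/identification-methods.Rmd`) for the solver internals, the
Bayesian prior-dependence contrast, and the causal-structure
discrimination layer.

A command-line interface over the same functions ships at
`inst/cli/lcident.R` (subcommands `simulate`, `identify`, `dof`, `bayes`,
`intervene`, `discriminate`, `demo`).

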