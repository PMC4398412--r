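---
title: "A Naming-Game model of creole emergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Naming-Game model of creole emergence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creolegame)
```

## The model

`creolegame` simulates how a contact language (a creole, C) can emerge and
spread in a colonial plantation ecology hosting three groups: Europeans
(*Eu*), who speak the lexifier E and never change language; Mulattos /
Free Colored (*M*), who start with E; and Bozal slaves (*B*), who start
with a coarse-grained African substrate language A. Group sizes are fixed
for a run; there is no population turnover.

The dynamics is a Naming-Game variant over *language repertoires* rather
than words. Each agent holds a non-empty subset of {E, A, C}. At each step
two distinct agents are drawn uniformly at random and assigned Speaker and
Hearer roles, under a segregated contact topology:

* Europeans only ever speak (they cannot be hearers); a draw of two
  Europeans is discarded and redrawn without counting a step.
* A European--Bozal pair actually interacts only with probability
  $\varepsilon$ (the segregation parameter); otherwise the step is a
  counted null step.
* Between two non-Europeans, roles are assigned by fair coin.

The Speaker utters one language chosen uniformly from her repertoire.
If the Hearer lacks it, she *learns* it (adds it to her repertoire). If
she has it, the exchange *succeeds* -- always for E and C, but only with
probability $\delta$ for A, which models in an average way that the Bozal
population was societally multilingual and two slaves often shared no
actual common language. On success both repertoires collapse to the
uttered language. After the interaction, a Hearer whose repertoire
contains both A and E (with or without C) replaces it, with probability
$\gamma$, by the new hybrid language: {C}. This creolization rule is the
model's core: $\gamma$ coarse-grains all the restructuring processes by
which bilingual speakers produce a new vernacular.

Languages here have no internal structure (no lexicon or grammar); the
model operates at the population level, asking *which* language wins, not
what it looks like.

### What the model predicts

Two demographic coordinates summarize a territory:
$x = N_M/(N_M+N_B)$ (the Mulatto share of the Black population) and
$y = (N_M+N_B)/N$ (the Black share of the total population). Sweeping
this plane at fixed $(\gamma, \delta, \varepsilon)$ shows a sharp
transition: above a curve $y^*(x)$ the creole C comes to dominate the
M+B population; below it the European language E does. The substrate A
never wins anywhere -- fractionalization ($\delta$ small) prevents it
from spreading. Because only $\varepsilon$ shifts the curve appreciably,
the band swept by $\varepsilon \in [0.05, 0.07]$ forms an uncertainty
*stripe*; census tables projected into the plane can then be classified
as creole-predicted (above), no-creole-predicted (below) or uncertain
(inside).

## Parameters

| parameter | meaning | default |
|---|---|---|
| `gamma` | probability an A+E hearer creolizes to {C} | 0.8 |
| `delta` | probability an A-to-A exchange succeeds | 0.1 |
| `epsilon` | probability a drawn Eu--B pair interacts | 0.06 |
| `dominance_threshold` | tail-averaged fraction needed to "dominate" | 0.8 |
| `max_interactions_per_agent` | run length per M+B agent | 2000 |
| `tail_window_fraction` | final fraction of the run that is averaged | 0.1 |

All probabilities are per-event Bernoulli draws; there is no persistent
pairwise structure (e.g. no fixed intelligibility graph among Bozals --
`delta` is redrawn each exchange). The defaults are the reference
parameterization used throughout: creolization is likely once bilinguals
exist, A-exchanges almost always fail, and Europe--Bozal contact is rare.

## Termination and the asymptotic summary

The all-E configuration is absorbing: once A and C are extinct nothing
can change, and the run exits early. The all-C configuration is *not*
absorbing, because Europeans keep injecting E into hearers; the dynamics
instead hovers near all-C as a quasi-stationary state. "Asymptotic"
fractions are therefore measured as time-averages over the final 10% of a
run of 2000 interactions per M+B agent, which at the population sizes
used here is far past the transient for both regimes.

Fractions weight a multilingual agent $1/|\text{repertoire}|$ per
language held, so they sum to one; near quasi-stationarity almost all
agents are monolingual and the weighting choice is immaterial. A language
*dominates* a run when its tail-averaged fraction exceeds
`dominance_threshold` (default 0.8).

Two deliberately exposed rule variants cover readings the verbal rules
leave open; both default to the literal reading and both are honoured by
the exact oracle so that equivalence tests stay meaningful:

* `creolize_only_on_change`: by default the creolization draw happens
  after *every* interaction the hearer takes part in, including failed
  A-exchanges; the strict variant only fires after her repertoire
  changed.
* `eps_null_advances_time`: by default an $\varepsilon$-rejected Eu--B
  draw is a counted null step; the alternative redraws instead, which
  rescales time but not the asymptotic state.

## The exact oracle

For tiny populations the dynamics is a finite Markov chain: agents of the
same group with the same repertoire are exchangeable, so a state is a
pair of multisets over the 7 possible repertoires, and
`build_transition_matrix()` accumulates the exact probability of every
(pair draw, role assignment, $\varepsilon$ gate, utterance, $\delta$
draw, $\gamma$ draw) outcome. Row sums are required to be 1 within
1e-12. Finite-horizon absorption probabilities are computed by repeated
matrix--vector products (robust for near-absorbing chains, and the
natural match to a simulation horizon); the infinite-horizon limit is
solved from the linear absorption system restricted to states that can
reach all-E. The test suite uses the oracle to validate the compiled
engine at one-step resolution (empirical one-step laws against the matrix
row) and at run resolution (absorption frequencies over thousands of
replicates within three standard errors), under both rule variants.

```{r oracle-example}
p <- model_params(gamma = 0.8, delta = 0.1, epsilon = 0.06,
                  max_interactions_per_agent = 10)
chain <- build_transition_matrix(1, 1, 1, p)
absorption_probability(chain, horizon = 20)
```

## Phase diagram and transition stripe

`estimate_dominance()` turns replicate runs at one $(x, y)$ point into a
creole-dominance probability; `transition_curve()` locates $y^*(x)$ by
bisection on that probability crossing 0.5 (a replicate-based boundary
estimator is much more stable than single-run outcomes); and
`build_stripe()` assembles the three curves at $\varepsilon$ = 0.05,
0.06, 0.07. The same base seed is reused across the three $\varepsilon$
values (common random numbers), sharpening the between-curve comparison.
Integerization of a point uses round-half-up on the Black total, then on
the Mulatto count, keeping at least one European whenever $y < 1$. Where
the dominance probability never crosses 0.5 -- e.g. $x = 1$, where there
are no Bozals, hence no A, hence no possible creole -- the curve is
reported as undefined (`NA`) rather than extrapolated.

Problem sizes: the package's tested default is a desk scale of
$N = 2000$ with 8--16 replicates per probability evaluation and a
bisection tolerance of 0.015--0.03 in $y$, which resolves the stripe
cleanly; the reference scale of $N = 10000$ on a fine $x$ grid is a
matter of configuration (`n_total`, `xs`, `n_replicates`) and is what the
dominance checks at single points use.

## Census classification and synthetic fixtures

`read_census_csv()` loads tables of Free Whites, Free Colored and Slaves
(schema above, aliases supported); `to_point()` projects them into the
plane -- a pure ratio, so scale-invariant; `classify()` compares each
point with the stripe, with linear interpolation between tabulated $x$
values, nearest-endpoint beyond them (with a warning), and the boundary
curves counted as uncertain. County- or parish-level rows go through the
identical operation; there is no special casing.

The package bundles **no historical census numbers**: the published
tables are third-party supplementary data, and users supply their own
transcription. What ships instead is `synthesize_census()`, a generator
of labelled synthetic records placed at least a chosen margin above or
below a given stripe, with totals drawn log-uniformly between $10^2$ and
$10^6$ and integerized so the round-trip projection stays on the intended
side. The fixtures emulate the *geometry* of the historical clustering --
creole territories at high Black fraction, non-creole ones at low -- but
none of its historical texture: no correlation between size and position,
no shared colonial history between neighbouring records, and no
borderline cases unless the margin is set near zero. A passing round-trip
test therefore validates the classifier's geometry, not the historical
claim itself.

```{r fixtures-example, eval = FALSE}
p <- model_params(gamma = 0.8, delta = 0.1, epsilon = 0.06)
stripe <- build_stripe(p, xs = c(0.02, 0.05, 0.12, 0.25),
                       n_total = 1000, n_replicates = 8,
                       y_tolerance = 0.03, seed = 600)
fix <- synthesize_census(8, 8, margin = 0.05, stripe = stripe, seed = 601)
head(classify_census(fix, stripe))
```

## Numerical choices

* Repertoires are bitmasks; language fractions are maintained
  incrementally in the compiled loop, which can leave $\sim 10^{-15}$
  drift around 0 and 1; summaries are clamped to $[0,1]$.
* Replicate $r$ of any replicate set uses seed `seed + r`; every seeded
  path restores the caller's RNG state.
* The engine uses R's own RNG stream, so `set.seed()` governs compiled
  runs exactly as interpreted ones.
* Bisection stops on interval width, not on a probability tolerance; with
  small replicate counts the 0.5-crossing itself is the noisy object, so
  tolerances below ~0.01 in $y$ buy nothing at desk scale.

## Known limitations

* No population turnover (births, deaths, continued slave imports), no
  creole-speaking Europeans, and no spatial structure within a territory
  beyond what the user encodes as separate rows.
* The substrate is a single coarse-grained A; the regime where many
  Bozals share one African language (which could let A itself win) is
  outside this parameterization -- `delta` sweeps are only a crude proxy.
* Census categories (Whites / Free Colored / Slaves) do not literally
  coincide with the linguistic populations they proxy; the mapping is the
  user's responsibility.
* The transition stripe is estimated from finite replicates of a finite
  system; near the curve the true dominance probability changes over a
  width comparable to the bisection tolerance, and classifications there
  are reported as uncertain by design.
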