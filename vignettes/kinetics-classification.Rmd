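---
title: "Classifying reaction kinetics from rate-law structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying reaction kinetics from rate-law structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinclass)
```

## The problem and the scheme

Repositories of SBML models encode reaction rates as algebraic kinetic
laws.  Surveying which *kinds* of laws modellers use — and recommending a
law for a new reaction — requires grouping similar reactions, and the
annotation channels designed for this (SBO terms, MIRIAM references) are
missing or inconsistent in much of the curated literature.  `kinclass`
therefore classifies every reaction from two annotation-free signals only:

1. the algebraic structure of its kinetic law (plus which of the law's
   species are reactants), yielding one of ten mutually exclusive
   **kinetics types** (K types), and
2. its distinct-reactant and distinct-product counts, each binned as
   0, 1, 2 or >2, yielding one of sixteen **reaction types** (R types).

Parameter *values* and units play no role: the scheme is purely structural,
so a Michaelis–Menten law is recognised whether its constants are fitted,
guessed, or dimensionally odd.

## From SBML file to expression tree

`read_sbml()` accepts levels 1–3: level 1 infix `formula` strings and
level 2/3 MathML content markup both parse into the same internal form —
plain R language objects over the operators `+ - * / ^`.  Three
normalisations happen on input:

* `pow(x, y)` and MathML `<power>` become `^`; parentheses and unary `+`
  disappear; purely numeric subtrees are folded (`2*3*A` → `6*A`).  A
  subtree containing any symbol is never folded, so `1 + -1*M` keeps its
  additive structure.
* SBML function definitions are inlined by `expand_functions()` before any
  analysis: each call site is replaced by the definition body with formal
  arguments substituted by the actual argument subtrees, recursively.
  Cycles and arity mismatches are reported as errors; in a corpus run they
  degrade that one reaction to `NA` with a logged diagnostic instead of
  aborting.
* Identifier roles are resolved from the model: species, parameter,
  compartment, function name, with a reaction's local parameters shadowing
  global identifiers inside its own law.  Variable compartment sizes count
  as compartments (never species); boundary-condition and constant species
  still count as species, since the scheme distinguishes identity, not
  dynamics.

Reactant/product/modifier lists are *sets*: a species listed twice or with
stoichiometry 2 contributes one element, because only distinct participants
define the reaction type.  The reversibility flag is read but deliberately
ignored — the categories do not distinguish reversible from irreversible
forms.  Rate rules, assignment rules and events are outside the scheme and
are flagged in the log when present.

## The eight properties and the decision table

Each law is reduced to eight properties:

* **a** — number of distinct species anywhere in the law.
* **b** — the law is a *single product of terms*: brought to a single
  fraction, its denominator is species-free and every species-containing
  factor of the numerator is a bare species or a species raised to a
  positive literal exponent.  Species-free additive factors are harmless:
  `(k1 + k2)*A` is still a single product.
* **c** — the law is the *difference of two products*: after distributing
  products over sums exactly two terms remain, of opposite sign, each
  individually a single product.  Common prefactors (a compartment
  multiplying the difference) distribute into both terms.
* **d** — correspondence with the reaction: under **b**, the law's species
  set equals the reactant set; under **c**, the positive term's species
  equal the reactants *and* the negative term's species equal the
  products.  Swapping the two terms of a difference therefore demotes a
  bi-directional mass-action law to the moderated class — orientation is
  meaningful, and sign normalisation (a `-1` coefficient counts as a
  negative sign) happens first.
* **e**/**f** — the two Michaelis–Menten shapes.  In rational form the
  numerator must be a single product whose species factors are exactly one
  reactant `S` (for **e**) or a reactant `S` times one other species `E`
  (for **f**), all with exponent 1; the denominator must be a sum of two
  *or more* terms whose only species is `S`, appearing with exponent 1 in
  at least one term, and `E` must be absent from it.  Accepting more than
  two denominator terms (`V*S/(K1 + K2 + S)`) is an interpretation choice:
  such laws are Michaelis–Menten up to a reparameterised constant.
* **g** — the Hill shape: one species `S` in the numerator raised to an
  exponent `p` (a symbol, or a literal other than 1), denominator a
  two-term sum of `S^p` and a species-free term, with `p` *syntactically
  identical* in both places after constant folding.  No attempt is made to
  prove algebraic equality of distinct exponent expressions — syntactic
  identity is decidable and deterministic.  A literal exponent of 1 never
  matches Hill: it is the Michaelis–Menten shape.
* **h** — fraction format: the single-fraction denominator contains at
  least one species.

The decision table is evaluated in a fixed order, first match wins:
`ZERO` (a = 0); `UNDR` (b ∧ d); `UNMO` (b ∧ ¬d); `BIDR` (c ∧ d);
`BIMO` (c ∧ ¬d); `MM` (a = 1 ∧ e ∧ h); `MMCAT` (a = 2 ∧ f ∧ h);
`HILL` (a = 1 ∧ g ∧ h); `FR` (a > 0 ∧ h ∧ ¬e ∧ ¬f ∧ ¬g); else `NA`.

Two conventions make the categories provably exclusive:

* **b** and **c** are defined false whenever **h** is true.  Without this
  gate `Cell*MI*V1*pow(K1 + MI, -1)` would literally be "a single product
  of terms" and the mass-action and Michaelis–Menten columns would
  overlap.  With the gate, the order of columns is immaterial (the test
  suite enumerates all 512 property states and checks totality).
* **d** uses set *equality* rather than one-sided containment.  The
  category prose can be read either direction ("all species are
  reactants" vs "contains all the reactants"); equality satisfies both.

Two more interpretation choices are worth naming.  A law matching the
Michaelis–Menten numerator but carrying a stray extra species in the
denominator (or vice versa) falls to `FR` whenever **h** holds — the
fraction family is the declared catch-all below `NA`.  And a species power
with a *symbolic* exponent is not accepted as a mass-action factor
(positivity of a symbol is undecidable), so `k*pow(S, n)` classifies `NA`.

### Unanalyzable laws

`piecewise`, `delay`, the `time` csymbol, boolean atoms and any other
function application surviving expansion make a law unanalyzable: all the
structural properties **b**–**h** return their negative values.  The
species census **a** still counts species wherever they occur, so an
unanalyzable law with species falls through to `NA`, while one with no
species at all is `ZERO` — consistent with the zeroth-order definition,
which reads only the census.

## Rational form and numeric guarantees

`rational_form()` combines every division and explicitly negative exponent
into one numerator/denominator pair: `pow(K1 + MI, -1)` is a division in
disguise, `(a/b)/(c/d)` becomes `a*d` over `b*c`.  Symbolic exponents are
never assumed negative; they reach the denominator only when their base is
itself a fraction or the exponent is an explicit negation.  Beyond this,
the package deliberately does **no** computer-algebra simplification — no
cancellation, no factorisation — because the categories are defined on the
law as written.  (`V*S/(K*S)` is a fraction with a species denominator,
`FR`, even though a CAS would cancel it to `V/K`.)

Every transformation must preserve numeric value.  The test suite checks
each template of a 55-shape library at 20 random positive assignments
(drawn from (0.1, 3), relative tolerance 1e-9) and additionally confirms
the rational-form identity, the denominator-species placement and the
species census against an independent computer-algebra oracle (sympy via
the system python).  Canonicalisation is idempotent, and structural queries
are invariant under renaming of non-species symbols.

## Corpus statistics

Distributions are reported on three axes (10 K types, 16 R types, 160 K×R
cells, zero categories included) in two flavours:

* **pooled** — reactions in the category divided by all classified
  reactions, every model weighted by its size;
* **per-model mean** — the average over models of within-model fractions,
  with a standard error computed as the sample standard deviation across
  models (denominator M−1) divided by √M.  The convention is stated
  because "standard error among models" does not by itself fix the
  denominator.  With a single model the SE is reported as 0 and flagged.

Reactions with *no* kinetic law are excluded from all distributions and
counted separately in the run manifest; `NA` classifications (a law exists
but matches nothing) are included, so `NA` fractions are fractions of all
classified reactions.  Models with zero classified reactions are dropped
from per-model averaging (a 0/0 fraction is undefined) with a logged
count.  Pooled fractions are invariant to model boundaries; per-model
means are not — both facts are asserted in tests.  `k_by_r_table()` gives
the conditional K distribution inside each R cell plus that cell's share,
and `compare_corpora()` reports side-by-side fractions, absolute
differences and each corpus's top category.

## The synthetic-corpus generator

`generate_corpus()` exists for two purposes: validating the classifier
end-to-end (every emitted reaction carries its ground-truth K and R label)
and letting users build random reaction networks with a chosen kinetics
profile.  Each K type is emitted from its canonical shape family with
fresh identifiers — mass-action products over the reactant set, moderated
products using modifier species, oriented two-term differences,
`V*S/(K + S)` and `kcat*E*S/(K + S)` fractions, Hill laws with symbolic or
literal (2–4) exponents, two `FR` shapes (an extra denominator species; a
`(1 - M)` numerator over a shifted denominator), and two `NA` shapes (a
nested non-matching fraction/power structure, and a piecewise law).
Four obfuscations, applied per reaction with configurable probabilities,
change the representation but may not change the class: wrapping the law
in an SBML function definition, multiplying by the model compartment,
rewriting `/` as `pow(x, -1)`, and shuffling factor order (difference
terms keep their orientation, since orientation is class-relevant).

Default conditions: 10 models of 5–10 reactions; a kinetics mix with
uni-directional mass action dominant (40%), the remaining mass spread over
the other classes and 4% `NA` — a profile shaped like published
repository surveys, where UNDR tops the distribution and a few percent of
laws resist classification; a reaction-type mix concentrated on the six
common cells (one/two reactants to zero/one/two products).  Kinetics
types are drawn first; the reaction type is then drawn from the configured
R distribution restricted to the bins feasible for that kinetics type
(a mass-action or Michaelis–Menten law needs a reactant; a bi-directional
law needs both sides), renormalised.  Explicitly requested infeasible
pairs error rather than being silently remapped, so distribution targeting
stays honest; when the configured R mass lies entirely on feasible bins,
both marginals hit their targets within binomial sampling error.  A single
integer seed determines the output bytes completely, and the caller's
random stream is restored afterwards.

What the generator does *not* emulate: real stoichiometry or mass
conservation, thermodynamic consistency, shared species across reactions,
annotation metadata, or the long tail of hand-written law idioms in real
repositories.  A perfect round-trip score therefore demonstrates that the
classifier is faithful on every shape family it defines — not that real
corpora contain only those shapes; on real data the `NA` class absorbs the
remainder.

## Validation problem sizes

The shipped validation runs use sizes chosen to exercise every code path
while staying comfortably interactive: the ten worked-example models for
exactness; exhaustive enumeration of all 512 property states for decision
totality; a 50-model seeded corpus for normalization identities (sums to 1
within 1e-12; K×R marginals reproduce the K axis); a 200-model corpus
(~1,500 reactions) with every obfuscation enabled for 100% label recovery
and 3-binomial-SE frequency targeting; and the 55-template library (53 analyzable) for
algebraic fidelity.  `scripts/acceptance.R` recomputes all of these from
scratch for any seed.

## Known limitations

* Equality of Hill exponents is syntactic; `S^(2*n)/(K^(n+n) + S^(2*n))`
  is not recognised as Hill (it falls to `FR`).
* No cancellation means deliberately redundant laws (`V*S/(K*S)`) stay in
  the fraction class; this matches the scheme's as-written philosophy but
  may surprise users expecting CAS behaviour.
* Laws using `exp`, `log`, piecewise or delays are never classified even
  when a human would recognise an underlying family.
* The per-model standard error treats models as exchangeable units; no
  hypothesis testing between corpora is offered — comparisons are
  descriptive.
* Species appearing in both reactant and product lists are members of both
  sets; SBML documents are trusted to declare species lists correctly.
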