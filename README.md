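# kinclass — annotation-independent classification of reaction kinetics in SBML models

Mechanistic models in systems biology pair a reaction network with kinetic
laws — the algebraic rate expressions that determine the dynamics.  Model
repositories hold thousands of such models, but their annotations (SBO,
MIRIAM) are too sparse and inconsistent to answer a basic question: *what
kinds of rate laws do modellers actually use for reactions like mine?*

`kinclass` answers it without annotations.  Every reaction in a collection
of SBML models (levels 1–3) is classified along two dimensions, purely from
the structure of its rate expression and its stoichiometry:

- **Kinetics type (K type)** — one of ten mutually exclusive categories:

  | K type | meaning | example law |
  |--------|---------|-------------|
  | `ZERO`  | zeroth order: no species in the law | `Cell*k1aa` |
  | `UNDR`  | uni-directional mass action: single product of terms, species = reactants | `Cell*CP*k9` |
  | `UNMO`  | uni-term with a moderator: single product, some species not a reactant | `k_tl*X` |
  | `BIDR`  | bi-directional mass action: difference of two products matching reactants/products | `Comp1*(kf_0*B - kr_0*BL)` |
  | `BIMO`  | bi-terms with a moderator: a two-term difference that is not BIDR | `c1*g*s173*(s172 - s135)` |
  | `MM`    | Michaelis–Menten without explicit enzyme | `Cell*MI*V1*pow(K1 + MI, -1)` |
  | `MMCAT` | Michaelis–Menten with explicit enzyme | `uVol*k3*MKKK_P*MKK/(KK3 + MKK)` |
  | `HILL`  | Hill equation `S^p/(K^p + S^p)` up to species-free factors | `n1*pow(cXn, a)/(pow(g1, a) + pow(cXn, a))` |
  | `FR`    | any other fraction with a species in the denominator | `Cell*(1 - M)*V1/(K1 - M + 1)` |
  | `NA`    | not classified | nested fractional/power structures, piecewise laws, … |

- **Reaction type (R type)** — the pair (number of distinct reactants,
  number of distinct products), each binned as 0, 1, 2 or >2: sixteen cells
  such as `R=2,P=1`.

The decision is driven by eight structural properties of the law (species
census **a**; single-product **b**; two-term difference **c**; correspondence
of terms/species with reactants and products **d**; the Michaelis–Menten
shapes **e**/**f**; the Hill shape **g**; species-in-denominator **h**)
evaluated on a canonical expression tree after inlining SBML function
definitions and combining the law into a single fraction.  Corpus statistics
are reported two ways: pooled over all reactions, and as per-model means with
standard errors across models.  A seeded generator emits labelled synthetic
SBML corpora for validation and for random reaction-network studies.

## Worked example

Ten one-reaction models, one per kinetics type (rate laws from curated
repository entries), ship with the package:

```r
library(kinclass)
dir <- file.path(tempdir(), "examples")
write_kinetics_examples(dir)
prof <- classify_corpus(dir)
prof$results[, c("model_id", "reaction", "kinetic_law", "k_type", "r_type")]
```

```
   model_id      reaction                           kinetic_law            k_type  r_type
1   ex_bidr       B -> BL        Comp1 * (kf_0 * B - kr_0 * BL)              BIDR R=1,P=1
2   ex_bimo  s172 -> s135         c1 * g * s173 * (s172 - s135)              BIMO R=1,P=1
3     ex_fr          -> M  Cell * (1 + -1 * M) * V1 * (K1 + ...)              FR R=0,P=1
4   ex_hill        -> cLm  Compartment * (n1 * cXn^a/(g1^a + cXn^a))       HILL R=0,P=1
5     ex_mm       MI -> M          Cell * MI * V1 * (K1 + MI)^-1              MM R=1,P=1
6  ex_mmcat  MKK -> MKK_P  uVol * k3 * MKKK_P * MKK/(KK3 + MKK)           MMCAT R=1,P=1
7     ex_na       -> timm  WholeCell * ((1 - (1 - prct)^npt) * ...)          NA R=0,P=1
8   ex_undr      CP -> C2                        Cell * CP * k9              UNDR R=1,P=1
9   ex_unmo         -> PX                              k_tl * X              UNMO R=0,P=1
10  ex_zero EmptySet -> Y                           Cell * k1aa              ZERO R=1,P=1
```

Each row shows a reaction, its rate law as read from the SBML file, and the
recovered types — e.g. `Cell * CP * k9` is a single product whose only
species `CP` is exactly the reactant set, hence uni-directional mass action
(`UNDR`) for a one-reactant/one-product reaction.

```r
print(prof)
#> Kinetics classification profile
#>   models:    10
#>   reactions: 10 classified, 0 without a kinetic law
#>   top K types: ZERO, UNDR, UNMO
#>   unclassified (NA): 10.00%
distribution(prof, "K")      # pooled and per-model-mean fractions with SEs
plot(prof)                   # grouped bar chart, SE whiskers
```

Here each type occurs once, so every fraction is 0.1 and the "top" types are
ties broken in canonical order.  On a real corpus, `distribution(prof, "K")`,
`distribution(prof, "R")`, `k_by_r_table(prof)` (conditional K distributions
per R type) and `compare_corpora()` reproduce the standard repository-survey
statistics; `corpus_config()`/`generate_corpus()` create labelled synthetic
corpora.

A command-line front end is included:

```sh
Rscript inst/cli/kinclass.R classify --input models/ --output report/ --plots
Rscript inst/cli/kinclass.R generate --config config.json --out corpus/
Rscript inst/cli/kinclass.R compare a.json b.json
```

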