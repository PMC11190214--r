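---
title: "Multimodal Shapley explanations for text-tabular mortality models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal Shapley explanations for text-tabular mortality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Veterinary electronic health records mix two modalities: structured
tabular fields (age, breed, sex, insurance status, counts of 21 high-level
disease-indicator categories) and a free-text clinical narrative written
by the practitioner. Classifiers over such records — here, models that
predict whether an animal is near the end of its life — can combine the
modalities in several ways, and the question this package addresses is
*which inputs, words or tabular values, drive the prediction*, in a way
that lets a word in the narrative be compared directly against a tabular
feature on one scale.

Classic Shapley-value attribution treats each input as a *player* in a
cooperative game: the value of a coalition of players is the model output
when exactly those players are "present", and a player's attribution is
its average marginal contribution over all orderings. The complication in
the multimodal setting is what "absent" means, because it differs by
modality:

* **Text players** (one per word-piece) are masked *in place* by a
  reserved `[MASK]` token. Tokenization boundaries are fixed once per
  instance and never recomputed, so player identity is stable across
  coalitions.
* **Tabular players** (one per feature) are simulated as absent by
  drawing values from a *background dataset* and averaging the model
  output over those draws — an empirical integration over the marginal
  distribution of the missing features.

`mmshap` implements this joint game for any predictor built from the
package's components, solves it exactly by coalition enumeration when the
player count is small, and otherwise with an unbiased permutation-sampling
estimator.

## The coalition game and its estimators

For an instance with players $1,\dots,n$ and a model $f$ returning a
probability pair $(p_\text{alive}, p_\text{dead})$, the coalition value
$v(S)$ is the mean of $f$ over the background-completed, mask-completed
inputs for coalition $S$. The Shapley value of player $i$ for label $l$ is

$$\phi_i^l = \sum_{S \subseteq N \setminus \{i\}}
  \frac{|S|!\,(n-|S|-1)!}{n!}\left[v_l(S \cup \{i\}) - v_l(S)\right].$$

Design choices that matter:

* **Fixed background rows.** The `n_background_samples` rows (default 50)
  are drawn once per explanation, seeded, and reused for every coalition.
  This removes background-sampling noise from coalition *contrasts*; the
  exact engine is then deterministic, and the axioms (efficiency,
  symmetry, dummy, linearity) hold to floating tolerance with respect to
  the background-completed model.
* **Exact limit.** Full enumeration costs $2^n$ coalition evaluations
  (each itself a background average); the default limit is 12 players.
  `explain_ensemble(estimator = "auto")` enumerates below the limit and
  samples above it.
* **Permutation estimator.** For each sampled permutation the players are
  inserted one at a time and marginal contributions recorded, once in
  forward and once in reversed order; the two traversals are averaged
  into one (antithetic) sample per permutation, and per-player standard
  errors come from the spread of those samples. Because every traversal
  telescopes from $v(\varnothing)$ to $v(N)$, the efficiency identity
  $\text{base} + \sum_i \phi_i = f(x)$ holds *exactly* for sampled
  explanations too, not just in expectation.
* **Coalition bookkeeping.** Coalitions are deduplicated and evaluated in
  one batched call. Up to 46 players they are keyed by integer bitmasks
  held in doubles; beyond that a double can no longer hold the mask
  exactly, so membership-string keys are used instead. The switch is
  internal and changes nothing observable.
* **Probability-pair labels.** For a two-label model whose outputs sum
  to one, the two labels' attributions are exact negatives of each other;
  this antisymmetry is a useful free invariant and is tested.

## The five combination architectures

The explanation engine works for five ways of combining a text model with
a tabular model, all exposed as predictors with a uniform
`predict_proba()` surface:

1. **All-Text** — the whole record is serialised as
   `"Name: value | Name: value | ... | Clinical narrative: ..."` and read
   by the text model. Field labels and separators are *scaffolding*:
   ever-present tokens that belong to no player. Tabular values rendered
   into the template remain tabular-typed players; masking one replaces
   its whole rendered span with the background row's rendered value.
2. **Weighted ensembles** — $w\,p_\text{text} + (1-w)\,p_\text{tab}$ on
   the probability scale, with the reference grid $w \in \{0.25, 0.50,
   0.75\}$. The weighted sum is taken on probabilities rather than
   logits because that is the plain reading of a "weighted sum" of
   predictions; this is an assumption and is confined to one function
   (`predict_weighted()`).
3. **Stack ensemble** — a gradient-boosting meta-model over the tabular
   feature vector plus the two base models' positive-class probabilities
   (meta input dimensionality $|\text{tabular}| + 2$), fitted on a
   held-out validation split only. The gradient-boosting backend is
   xgboost, for both the tabular base model and the meta-model.

Because the weighted ensemble is a convex combination of two games that
each depend only on their own modality's players, Shapley linearity makes
the joint explanation equal $w$ times the text-only explanation (padded
with zeros on tabular players) plus $1-w$ times the tabular-only
explanation. The package treats this as a *test*, not an assumption: the
joint game is always explained directly.

**High-cardinality routing.** Categorical tabular features with more than
30 unique values (breed, region in realistic cohorts) are routed to the
text side and rendered through the same template, conjoined with the
narrative. Routing is restricted to categorical features: the rule exists
to avoid enormous one-hot or meaningless ordinal encodings, a problem
continuous features do not have — a numeric age would otherwise always be
routed in any realistically sized cohort. Routed features are removed
from the tabular model's inputs to avoid double counting.

## From player values to feature importance

Word-piece attributions are aggregated to one non-negative score per
feature: sum the player values within the feature separately per label,
take absolute values, add the two labels:

$$\phi_f = \Bigl|\sum_{t \in f} v_{t,\text{alive}}\Bigr| +
           \Bigl|\sum_{t \in f} v_{t,\text{dead}}\Bigr|.$$

Summing *before* the absolute value lets opposite-signed pieces of one
feature cancel, which is the intended semantics (a feature whose words
argue both ways is genuinely less decisive). For probability-pair models
the two terms are equal, so $\phi_f$ is twice the absolute alive-label
sum. Dataset-level comparisons use mean $|\phi_f|$ per feature as a
proportion of the sum over features, so each model's profile sums to one.

**Rank stability.** Two explanation sets over the same instances are
compared by Kendall's $\tau$ per instance — concordant minus discordant
feature pairs over all pairs — then summarised by the mean and SD of the
per-instance values; a pooled "total" over several comparisons
concatenates the raw per-instance values rather than averaging means.
Ties count as neither concordant nor discordant while staying in the
denominator (the tau-a convention, which is what the plain pairwise
formula says). This diverges from the tau-b used by
`stats::cor(method = "kendall")` only when ties occur, and with
continuous importance scores ties have measure zero; the two agree
exactly on tie-free data, which is tested.

**Distributional comparison.** The per-instance difference
$\phi_\text{narrative} - \phi_\text{age}$ across architecture groups is
tested with a Kruskal–Wallis H test; the share of rank variance explained
by the grouping is reported as epsilon-squared,
$E^2 = H \,/\, \frac{n^2-1}{n+1}$. The effect-size formula is a
documented assumption (the H statistic alone does not fix one). When
every difference is identical the tie-corrected H is a 0/0 form;
the package reports $H = 0$ in that degenerate case, which is its
analytical value.

**Phrases.** For ranked phrase lists, continuation word-pieces
(`"##..."`) always merge into their word; adjacent words of one feature
merge into a phrase when their values share a sign and the magnitude
ratio $\min(|a|,|b|)/\max(|a|,|b|)$ exceeds `grouping_threshold`
(default 0.4). The threshold semantics are a design choice: they are
deterministic, merge aggressively enough to produce multi-word phrases,
and never merge across a sign change. Repeated strings are averaged;
tabular players render as `"feature = value"`; the sign convention is
alive-positive (configurable).

## Cohort construction

The mortality-labelling pipeline reproduces a case-control construction
around a *declaration of death* found in the narrative:

* **Regex flagging** uses a case-insensitive substring alternation
  (`euth|dead|died|pts|put to sleep|pento|doa|crem|burial|bury|qol|quality|ashes|scatter|casket`)
  with no word boundaries — `"pento"` fires inside `"pentobarbital"`.
  Boundary matching is available behind a flag. `matched_terms` reports
  every alternative that fired, in pattern order, and is tested against
  an independent per-alternative scan.
* **Teacher-student propagation** scales a small manually-validated seed
  set to the full corpus: a student classifier (ridge-penalised logistic
  regression over word-piece counts; penalty keeps perfectly separable
  seed vocabularies stable) is trained on the seed set only and applied
  to everything else. A single student generation is implemented; the
  trainer is pluggable.
* **Case assembly**: the case example for a flagged animal is the
  consultation *immediately preceding* the declaration, labelled dead.
  Animals whose declaration is their only consultation are discarded
  (`single_narrative`). Examples missing a required field (age, breed,
  sex, species or region by default) are discarded (`incomplete`).
* **Controls** are drawn uniformly without replacement, seeded, from
  animals whose *latest* consultation carries no death flag, at
  `balance_ratio` controls per case (default 1). The control example is
  the animal's latest consultation, mirroring the case construction's
  recency; this choice is configurable because nothing in the problem
  fixes it.
* **Dual membership**: with eligibility defined as above, an animal
  flagged mid-history whose record continues (a typical false positive:
  a discussion of *future* euthanasia) qualifies as both case and
  control; such animals are removed from both sides and counted. Every
  exclusion rule logs its count.
* **ICD history**: each surviving example's 21 indicator counts are
  replaced by cumulative sums over the animal's history up to and
  including the example consultation, so the tabular side summarises
  prior clinical history.
* **Splitting** is stratified by label and grouped by animal (no animal
  straddles splits): per label stratum, `floor(test_fraction * n)`
  animals to test, `floor(validation_fraction * n)` to validation
  (default 0.20 / 0.10 — the 80:20 convention with a tenth of the data
  reserved for stack meta-fitting), remainder to train, in seeded
  shuffled order.

## The synthetic cohort generator

Real consultation datasets of this kind are not publicly distributable,
so every stage is exercised against a seeded generator
(`generate_cohort()`) whose ground truth is known by construction:

* death is generated from a single logistic model —
  $P(\text{death}) = \mathrm{logit}^{-1}(\mathrm{logit}(b) +
  \beta_\text{age}(a - \bar a) + \sum_k \beta_k\,[\text{keyword}_k])$ —
  so planted-signal recovery has an unambiguous truth;
* terminal age is drawn from a young/old mixture so both young-alive and
  old-dead regimes exist;
* dying animals always have at least one prior consultation and a
  terminal narrative built from mortality phrases that match the
  extraction regex by construction; benign narratives never match it;
* planted signal keywords are written into the narrative the pipeline
  will extract (the pre-terminal one for dying animals, the latest one
  otherwise);
* narratives are templated clinical-note-like strings with shorthand
  (`"abdo palp nad"`, `"bar"`, `"ce unremarkable"`) so word-piece
  grouping and shorthand survive the pipeline;
* ICD indicator counts are small per-consultation increments that the
  cohort builder accumulates.

Defaults: 500 animals, mean 3 consultations, baseline death rate 0.15 at
average age, 0.25 log-odds per year of age, one planted keyword
(`collapse`, +2.5 log-odds) at rate 0.3. These are the package's standard
test conditions: the death rate is in the range where a balanced
case-control set of a few hundred examples emerges from 2000 animals, and
the keyword and age effects are strong enough that a correctly working
pipeline must find them.

What the generator does **not** emulate: real clinical language (spelling
noise, negation, context), correlations between tabular covariates,
calendar time (consultations are ordered by index; the 28-day
death-window criterion is satisfied by construction rather than checked
against dates), and practice-level recruitment structure. Passing tests
therefore demonstrate that the machinery is correct on data with the
assumed statistical shape, not that any particular clinical finding
transfers to real records.

## Problem sizes used by the test-suite and acceptance script

Chosen to give stable checks at interactive runtimes: estimator-vs-exact
agreement on 20 instances of at most 10 players at 2000 permutations;
efficiency over 100 explanations; linearity on the $w$ grid under exact
enumeration; planted-signal recovery over 10 independent pipeline runs of
2000 animals each, explaining 8 test instances per run with 40
permutations and 6 background rows; the text-share trend over 15
fixed-model instances per $w$; and 1000 instances for the null behaviour
of rank comparisons.

## Known limitations

* The permutation estimator reports per-player standard errors but no
  joint confidence region; comparisons across many players should use
  the per-player errors loosely.
* Background integration assumes feature independence (marginal, not
  conditional, imputation) — inherited from the underlying attribution
  framework.
* The All-Text game re-renders tabular spans per background row, so its
  cost scales with `n_background_samples` times coalition count; keep
  instances small under exact enumeration.
* The word-piece tokenizer is a deliberately small fixture (greedy
  longest-match over a shipped vocabulary). It exists so that multi-piece
  words and phrase grouping are genuinely exercised, not to reproduce any
  production tokenizer; an adapter for external tokenizers only needs to
  produce stable token lists.
* `fit_text_model()` is a bag-of-word-pieces logistic model: a stand-in
  with the right interface and a closed form, not a language model.
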