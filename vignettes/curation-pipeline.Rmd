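---
title: "Role-based curation of series metadata: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Role-based curation of series metadata: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geocurate)
```

## The problem

Public gene-expression repositories hold hundreds of thousands of series
whose experimental design lives in free text: which samples are controls,
which carry a perturbation, what the perturbation is. Turning that text
into structured control-versus-perturbation annotations at scale is the
bottleneck for downstream reanalysis such as signature-based drug
repurposing. geocurate implements a curation pipeline in which a set of
cooperating annotator roles (an original annotator, a result checker, a
prompt optimizer, the promoted optimal annotator, and a quality
controller) produce and police those annotations. The language-model
backend is abstracted behind a completion contract; a deterministic
rule-based mock ships with the package so every stage runs offline and
every test has known ground truth.

## The quality-control model

An annotation names a control group (`ctrl_ids`), a perturbation group
(`pert_ids`), a perturbation type (drug, disease or gene), a perturbation
name and a cell type. The rule engine accepts it only when three criteria
hold simultaneously:

1. **Characteristic alignment.** For every normalized characteristic key
   other than the designated perturbation key, the set of values in the
   control group equals the set in the perturbation group. Sex and age
   keys are expressly ignored — an age gap between arms is not grounds
   for rejection. Values are compared as sets rather than multisets
   because replicate counts legitimately differ between arms.
2. **Grouping uniformity.** Samples of the same type must be consolidated:
   no sample left out of the annotation may share the full non-ignored
   characteristic profile of an assigned sample, and neither group may mix
   two distinct values of the perturbation key (e.g. two doses in one
   group when an unmixed grouping exists).
3. **Correct perturbation assignment.** The type must be a valid category,
   the name non-empty and present (case-insensitive substring, optionally
   through a user-supplied synonym table) in the perturbation-group sample
   texts, and the direction right: the control group must not carry the
   perturbation as its value of the perturbation key.

The verdict is `Success` exactly when all three hold. Because real
metadata never declares which key encodes the perturbation, the engine
infers it: first a key whose values contain the annotated name; failing
that, the unique key whose control and perturbation value sets are
disjoint; failing both, criterion 1 runs over all non-ignored keys and
criterion 3 falls back to text search alone. Whether alignment should be
compared group-wise or per sample pair is genuinely open; we chose
group-wise set equality and state it as this package's convention.

Name matching is deliberately exact-substring with an opt-in synonym
table rather than fuzzy: inconsistent perturbation naming is a documented
error cause that fuzzy matching would silently hide.

## Consistency machinery and metrics

A production run annotates every series (round 1) and applies two
quality-control channels: the deterministic rule engine and an LLM-backed
channel answering in the same JSON verdict schema. When the channels
disagree the series is re-annotated once (round 2) and rule
quality-control of the round-2 annotation supplies a third verdict; the
majority decides. Three metrics summarise a run: QCC, the fraction of
annotation pairs on which the two channels agree (final status only, not
per-criterion flags); APR, the fraction of annotations passing; and DPR,
the fraction of datasets with at least one passing annotation. Undefined
metrics (empty inputs) raise errors rather than returning zero, because
silent zeros corrupt reports. Manual three-level grades
(Excellent/Moderate/Error) cross-tabulate against automatic verdicts
with the convention that Excellent and Moderate agree with Success and
Error agrees with Fail — a Fail on a manually Error-graded annotation is
the controller correctly catching a bad grouping.

With the mock backend the LLM channel reproduces the rule verdict and
flips its status with a configured Bernoulli probability drawn from the
backend's private stream, so the consistency machinery can be exercised
at any target QCC level and the expected QCC is exactly one minus the
disagreement rate.

## The prompt-optimization loop

Training iterates annotate → check-against-gold → optimize. Annotations
are paired to gold records by maximal Jaccard similarity of their
combined sample sets (ties broken by name equality, then gold order); a
control/perturbation swap is one conceptual `grouping` discrepancy, not
two id-set discrepancies, since direction is tested separately by
criterion 3. The optimizer bumps the template version and appends an
instruction addressing the majority discrepancy field; under the mock
annotator the version gates dose-aware splitting, so the planted
dose-blindness deficiency (version 0 merges all perturbed arms into one
group) is corrected after a single optimization. The loop is bounded:
default target discrepancy rate 0 and at most 5 optimizations, because an
unbounded "repeat until converged" is not acceptable engineering. With no
budget (`max_iters = 0`) the history reports non-convergence and returns
the starting template untouched.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` defines the test conditions: series of 2–4 samples
per arm (uniform over the range), one perturbation key named after the
perturbation type, constant background keys (tissue, cell line, strain),
randomized ignored keys (sex; age fixed at "8 weeks" unless perturbed),
and templated title/summary/design prose mentioning the perturbation
name. Error classes are injected at user-set rates with one label per
gold annotation, and every label corresponds to an actual edit:

* `confounder` — the perturbation arm sits in a different tissue
  (criterion 1 must fail);
* `swap` — the emitted gold annotation exchanges the two groups
  (criterion 3 direction must fail);
* `name_inconsistency` — the annotated name is corrupted to a token
  absent from the sample texts (criterion 3 must fail);
* `multiple_disturbances` — a second treatment key varies between the
  arms (criterion 1 must fail);
* `age_difference` — the arms differ only in age; this class is benign
  by construction and encodes the ignore rule as a test: quality control
  must still pass it.

Because injection is exclusive and labelled, the rule-QC failure set on a
generated corpus must equal the union of the non-benign injected sets
exactly — a property the test suite asserts at 300 series.

The generator's text realism is minimal (templated sentences) because the
mock annotator reads structured characteristics, not prose. Consequently,
green tests here demonstrate the correctness of the rules, metrics and
workflow plumbing, not the linguistic robustness of any live
language-model backend against real submitter prose; runs against a live
endpoint remain necessary to evaluate that. Accession grammar is also not
mimicked — identifiers are arbitrary unique tokens.

## The signature stage

Quality-passed annotations feed a standardized differential-expression
procedure applied identically to both platforms: counts are library-size
normalized to counts-per-million and transformed `log2(x + 1)`;
log-intensity values pass through; the per-gene statistic is the Welch
t-statistic of perturbation versus control. Genes with zero variance in
both groups carry no contrast and are dropped; groups need at least two
samples each.

Connectivity between two signatures is the Spearman correlation over the
union of each signature's `n_top = 250` strongest-|statistic| genes
(restricted to shared genes; at least 10 required). Rank correlation is
used instead of Pearson because the library spans platforms with
incomparable scales — and it makes every result invariant to positive
rescaling of a signature. The p-value is a label-permutation test: the
target's gene labels are permuted and the full statistic, including the
top-gene selection, is recomputed per draw. Recomputing the selection is
essential — keeping the observed union fixed while permuting would break
exchangeability (selected genes are extreme in one signature by
construction) and produce non-uniform null p-values. The +1-corrected
two-sided p is exact under label exchangeability; the default 10,000
draws and a mandatory seed make results reproducible. Library screens
apply Benjamini–Hochberg across members and sort by correlation, with
positive correlation labelled `similar` and non-positive `opposing` (the
repurposing direction).

## Numerical and engineering choices

* Characteristic keys are normalized by case-folding, trimming and
  collapsing internal whitespace — one deterministic rule so verdicts are
  reproducible; normalization is idempotent and collisions are
  disambiguated with numeric suffixes.
* Missing keys contribute an explicit absent sentinel to value sets, so
  a key present in one arm only counts as a difference.
* All annotator roles must answer in a fixed JSON schema; one re-prompt
  is allowed on parse failure, after which the annotation is recorded as
  a Fail with reason "unparseable". The parser is total — arbitrary text
  yields a structured failure, never an exception mid-corpus.
* The mock backend's randomness lives in a private stream seeded at
  construction, so it never perturbs (and is never perturbed by) the
  caller's RNG, and a run report serializes without timestamps: two runs
  with the same corpus, template and backend seed are byte-identical.
* Verdict consensus with two agreeing verdicts needs no third round; two
  disagreeing verdicts raise until a third is supplied.

Test problem sizes (500 random series for the brute-force comparison,
200–300-series corpora for injection and ignore-class sweeps, 2,000
draws for QCC calibration, 500 replicates for permutation-null
uniformity, 300 for planted-sign recovery) were chosen so the full suite
exercises every property at statistically meaningful scale while
remaining a routine desktop run.

## Known limitations

* The rule engine's perturbation-key inference can stay undetermined on
  pathological metadata (no name match, several separating keys); it then
  degrades conservatively as described above.
* No ontology-backed drug-name resolution: synonyms must be supplied
  explicitly.
* The live-backend transport is an injected function; the package ships
  no network client, token accounting or batch scheduling.
* Probe-to-gene mapping and batch correction are out of scope for the
  signature stage; inputs are assumed gene-level.
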