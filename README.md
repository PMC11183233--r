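# geocurate

Role-based annotation and quality control of gene-expression series
metadata, with a downstream signature-connectivity stage for
drug-repurposing queries.

## The problem

Series in GEO-style repositories describe their experimental design in
free text. Reanalysis at scale — differential expression, signature
matching, repurposing screens — needs that design as structured data:
which samples are controls (`ctrl_ids`), which carry the perturbation
(`pert_ids`), and what the perturbation is (`pert_type` ∈ {drug,
disease, gene}, `pert_name`, `cell_type`). geocurate implements a
multi-role curation pipeline for this task: an *original annotator*
proposes designs, a *result checker* compares them against a gold
standard, a *prompt optimizer* revises the annotator's instructions in a
bounded negative-feedback loop until the promoted *optimal annotator*
matches gold, and a *quality controller* polices every production
annotation.

The quality controller is a deterministic rule engine over three
criteria, with sex and age expressly ignored throughout:

1. **alignment** — every non-ignored characteristic key except the
   perturbation key shows the same value set in both groups;
2. **uniformity** — same-profile samples are consolidated into a single
   group, and no group mixes two values of the perturbation key;
3. **perturbation** — the type is valid and the name is real, present in
   the perturbation-group texts and absent from the control group's
   perturbation-key values (direction).

A run is summarised by **QCC** (agreement between two QC channels),
**APR** (fraction of annotations passing) and **DPR** (fraction of
datasets with ≥ 1 passing annotation). Channel disagreements trigger one
re-annotation round and a majority consensus.

Downstream, quality-passed annotations yield per-gene Welch-*t*
signatures (counts are CPM-normalized and `log2(x+1)`-transformed), and
connectivity between signatures is the Spearman correlation over the
union of each signature's top-250 |statistic| genes, with an exact
label-permutation p-value and Benjamini–Hochberg q-values across a
library. Positive correlation = similar pattern; negative = opposing
(the repurposing direction).

Everything runs offline: the language-model backend is a contract, and
the shipped mock backend is a deterministic rule-based annotator whose
only wrong answers come from a labelled error-injection knob, so ground
truth is always known. The synthetic-corpus generator plants the
documented error classes (confounders, group swaps, inconsistent
perturbation names, multiple disturbances, benign age differences) at
chosen rates with per-annotation bookkeeping.

## Worked example

```r
library(geocurate)

spec <- corpus_spec(50,
                    error_rates = c(confounder = 0.1, swap = 0.05,
                                    age_difference = 0.1),
                    seed = 7)
corpus <- generate_corpus(spec)
report <- run_waterfall(corpus,
                        prompt_template("optimal_annotator", version = 1L),
                        mock_backend(seed = 7, disagreement_rate = 0.1))
report
#> <run report> 50 annotations over 50 datasets
#>   QCC 0.8800 | APR 0.9600 | DPR 0.9600 (50 annotations, 50 datasets)
#>   round 1: n=50 APR=0.9600
#>   round 2: n=6 APR=1.0000
#>   error causes: confounder=2
```

Read: the mock LLM channel disagreed with the rule channel on 6 of 50
annotations (QCC 0.88, matching the configured 10% disagreement rate up
to binomial noise); those 6 series were re-annotated in round 2 and
settled by majority consensus. The two final failures (APR 0.96) are the
two confounder bundles this seed drew — their metadata genuinely
violates characteristic alignment, so the honest mock annotation fails
rule QC. Swap injections live in the *gold* annotations, which a
production run does not consume, so they surface in gold-checking
workflows (or when the backend's error knob replays them), not here.
Individual verdicts explain themselves:

```r
run_rule_qc(corpus[[8]]$gold[[1]], corpus[[8]]$series)   # a confounder bundle
#> <verdict SYN0008/rule Fail round 1> alignment=FALSE uniformity=TRUE
#>   perturbation=TRUE [characteristic 'tissue' differs between groups]

run_rule_qc(corpus[[1]]$gold[[1]], corpus[[1]]$series)   # a swapped bundle
#> <verdict SYN0001/rule Fail round 1> alignment=TRUE uniformity=TRUE
#>   perturbation=FALSE [pert_name 'gammaron' not found in
#>   perturbation-group sample texts; direction: control group carries
#>   'gammaron' as its 'treatment' value]
```

A command-line wrapper over the same functions lives at
`inst/cli/geocurate.R` (`simulate`, `train`, `run`, `qc`, `metrics`,
`signature`, `connect`).

## Package layout

- `R/metadata_model.R`, `R/soft_io.R`, `R/annotations_io.R` — records,
  SOFT-dialect reader/writer, annotation TSV I/O
- `R/llm_backend.R`, `R/mock_annotator.R` — completion contract,
  exchange log, structured-response parsing, deterministic mock
- `R/quality_controller.R` — the three-criterion rule engine, LLM-channel
  QC, consensus
- `R/roles_workflow.R` — gold checking, prompt optimization, training
  loop, production waterfall
- `R/evaluation_metrics.R` — QCC/APR/DPR, manual-vs-automatic crosstab,
  error-cause report
- `R/signature_pipeline.R` — signatures, connectivity, repurposing
  ranking
- `R/synthetic_data.R` — corpus and expression generators with labelled
  injection

The methods vignette (`vignettes/curation-pipeline.Rmd`) documents the
model, the rule definitions, the generator's scope and the numerical
design choices.
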