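# speechdisorg

Speech graph connectedness analysis of formal thought disorder.

Disorganized speech is a core feature of psychosis, classically rated by
clinical impression. This package implements a structural, fully
quantitative alternative aimed at computational-psychiatry researchers:
a short verbal report is represented as a directed word-trajectory
multigraph (each distinct word a node, each consecutive word pair one
directed edge), and thought disorder is measured from the graph's
connectedness and from its distance to randomly reordered speech.

The quantities at the core:

- **E** — number of edges (= token count − 1), a direct verbosity measure;
- **LCC** — nodes in the largest connected component, ignoring edge
  direction;
- **LSC** — nodes in the largest *strongly* connected component (mutual
  directed reachability), the signature of recurrent loop structure in
  organized discourse;
- **LCCz, LSCz** — z-scores of LCC/LSC against 1000 surrogate graphs built
  by shuffling the word sequence (same words, same number of edges, no
  temporal structure). A report with |LSCz| ≤ 2 is **random-like**:
  indistinguishable from chance rearrangements of its own words;
- **Disorganization Index** — an affine combination of connectedness
  attributes, `intercept + Σ coef·attribute`, either one of four fixed
  published equations (`reference_index_models()`) or re-derived on a
  cohort by collinearity-pruned multiple regression against negative
  symptom scores (`fit_disorg_index()`, Belsley condition-index rule,
  threshold 10, OLS on the survivors).

Around that core: a non-parametric statistics battery (Kruskal–Wallis,
Wilcoxon rank-sum, 2×2 chi-square, Spearman and partial Spearman,
Bonferroni thresholds, KS/Levene checks), cross-validated Gaussian Naive
Bayes classification of diagnosis and of negative-symptom severity with
the full metric panel (sensitivity, specificity, precision, recall,
F-measure, AUC, accuracy), a synthetic transcript/cohort generator with a
single interpretable recurrence parameter, and a one-call pipeline
(`run_pipeline()`) plus a thin CLI (`inst/cli/speechdisorg.R`).

## Worked example

```r
library(speechdisorg)

# one report: tokens -> graph -> attributes
att <- connectedness(tokenize("the dog chased the cat and the cat chased the dog"))
att
#> <connectedness> E=10 LCC=5 LSC=5 word_rate=11 (E/w=0.909 LCC/w=0.455 LSC/w=0.455)

# distance from the report's own shuffle null
d <- make_surrogates(tokenize("the dog chased the cat and the cat chased the dog"),
                     n = 1000, seed = 1)
z_scores(att, d)
#> <randomness_scores> LCCz=0.000 LSCz=0.562 random_like=TRUE

# a synthetic cohort through the full pipeline
co <- generate_cohort(generator_config(seed = 42))
dir <- tempfile(); export_cohort(co, dir)
res <- run_pipeline(file.path(dir, "transcripts.tsv"),
                    file.path(dir, "metadata.tsv"),
                    file.path(dir, "out"), n_surrogates = 1000, seed = 7)
res$stats$random_like$proportions
#>       bipolar_like       control_like schizophrenia_like
#>         0.10000000         0.04761905         0.72727273
res$index_model
#> Disorganization Index (fitted)
#>   score = 29.4863 + LSC_negative x (0.0827) + LSCz_negative x (1.3642)
#>   R^2 = 0.727, p = 8.562e-06, observed power = 1.0000, n = 21
res$classification$diagnosis
#> <classification_report>
#>   sensitivity 0.82  specificity 0.74  precision 0.53  recall 0.82
#>   F-measure 0.64  AUC 0.82  accuracy 76.19%
#>   (pooled single-ROC AUC 0.86)
```

Reading the output: the sentence's returns to "the"/"cat"/"dog" put all
five words in one strong component (LSC = 5), but an 11-token report is
far too short for that to clear its shuffle null (LSCz ≈ 0.56,
random-like). In the synthetic cohort, random-like prevalence is ordered
schizophrenia-like (73%) > bipolar-like (10%) > control-like (4.8%) —
this particular bipolar-like draw (n = 10) lands below its ~30% expected
rate. The index re-fitted on the 21 patients recovers the dominant
generating coefficient (+1.36 on LSCz against a true +1.0) while the
small LSC effect (true −0.25) is lost in noise at this n, and the index
alone classifies the schizophrenia-like group against everyone else with
AUC ≈ 0.82.

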