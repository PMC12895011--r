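# attnmil

Attention-based multiple instance learning (ABMIL) for predicting
breast-cancer recurrence risk from whole-slide images, with a full
benchmarking and interpretability stack.

## The problem

Transcriptomic assays such as the PAM50-based ROR-P score stratify
non-metastatic, ER-positive, HER2-negative breast cancer into low, medium
and high recurrence risk at fixed cutpoints (low `< 11.76471`, medium
`[11.76471, 52.94118)`, high `>= 52.94118`), but they are expensive and not
universally available. H&E-stained slides exist for every patient. This
package provides the modelling machinery for inferring the risk score from
slide patch embeddings, for benchmarking competing patch encoders under a
rigorous cross-validation and survival-evaluation protocol, and for asking
— by direct perturbation of the input — *which tissue regions* a trained
model actually relies on.

It is aimed at computational-pathology researchers who already have
per-patch embeddings (from any pretrained encoder) and want a transparent,
fully testable reference implementation of the ABMIL + evaluation +
perturbation pipeline. Because slide cohorts with matched transcriptomics
are access-controlled, the package includes a synthetic-cohort generator
that reproduces the statistical structure of such a study (planted
tumor signal, three-way risk grouping at the assay cutpoints, exponential
recurrence with 10-year censoring) so that every stage is exercisable and
testable without any external data.

## The model

A slide is a *bag* of patch embeddings `x_1, ..., x_N` (patches of constant
physical size, 128 x 128 um^2 by default). The gated ABMIL head computes

    h_i   = Dropout(ReLU(W1 x_i))                        # patch embedder, L = 512
    a_i   = w' (tanh(V h_i) * sigmoid(U h_i))            # gated attention, D = 384
    alpha = softmax(a)                                   # attention weights
    z     = sum_i alpha_i h_i                            # slide representation
    out   = W2 z                                         # 2 logits or 1 score

trained with AdamW and early stopping on a validation fold. Evaluation
uses ROC AUC (DeLong comparisons), Pearson r (Meng's z), Harrell's
C-index (paired jackknife comparison of correlated C-indices), univariable
Cox and log-rank tests, Youden-J threshold selection on pooled validation
predictions, and Benjamini-Hochberg correction within comparison families.
The perturbation suite tests region *necessity* (remove the masked patches)
and *sufficiency* (keep only the masked patches) with paired t-tests and
Cohen's d, and greedily searches for minimal patch sets that flip a
low-risk slide to a high-risk prediction.

## Worked example

```r
library(attnmil)

# a synthetic cohort: 200 participants, 32-dim embeddings, planted tumor
# signal, recurrence outcomes with 10-year censoring
co <- simulate_cohort(n_participants = 200, d = 32, signal_strength = 0.2,
                      seed = 11)

# 10-fold participant-stratified cross-validation of the classification head
cfg <- abmil_config(embed_dim = 64, attention_dim = 48, lr = 1e-3,
                    max_epochs = 20, patience = 4)
cv <- crossval_abmil(co, "classification", k = 10, config = cfg, seed = 5)
roc_auc(cv$predictions$prob_high, cv$predictions$label)
#> [1] 0.9762203

# regression head: correlation of out-of-fold predictions with the true score
cvr <- crossval_abmil(co, "regression", k = 10, config = cfg, seed = 6)
pearson_r(cvr$predictions$score, cvr$predictions$label)
#> [1] 0.9801114

# is the planted "tumor" region necessary for high-risk predictions?
fit <- abmil(co$bags, binarize_rorp_group(co$clinical$rorp_group),
             "classification", config = cfg, seed = 2)
necessity_test(fit, co$bags, co$masks)
#> necessity (region removal) perturbation test on 39 slides
#>   mean delta = -0.8841, t = -49.7, p = 3.6e-36, Cohen's d = -7.95
```

The out-of-fold AUC (0.976) and Pearson r (0.980) say the pipeline
recovers a strongly planted signal almost perfectly. The necessity test
restricts to the 39 slides the model called high-risk and removes each
one's planted signal patches: the mean probability drop of -0.88 (Cohen's
d = -7.95) says the model's high-risk calls collapse without the "tumor"
region — it relies on the planted tissue, not on background noise.

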