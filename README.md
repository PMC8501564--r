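# ordppi

Sequence-based protein–protein interaction (PPI) prediction by ordinal
regression on interaction confidence scores.

Interaction resources such as STRING attach a confidence score in (0, 1) to
each protein pair; the higher the score, the more likely the interaction.
`ordppi` predicts that score from the two primary sequences alone and calls
an interaction when the predicted score exceeds a threshold θ. It is aimed
at computational biologists who have scored pair tables and FASTA sequences
and want a self-contained, reproducible model plus the evaluation protocol
around it.

## Model

Two parts, trained end to end:

1. **Siamese RCNN encoder.** Each sequence is embedded per residue
   (one-hot, a 7-class physicochemical indicator, or pre-trained skip-gram
   vectors), right-padded to a fixed length, and passed through stacked
   RCNN units: affine convolution *h*<sub>t</sub> = *M v*<sub>t:t+d−1</sub> + *b*,
   n-max pooling over disjoint blocks, and a bidirectional GRU whose output
   is merged with the layer input by concatenation
   [→h<sub>t</sub>, ←h<sub>t</sub>, v<sub>t</sub>] (or a residual sum). A
   final convolution and global average pooling yield E(S) ∈ ℝ^d′. The two
   arms share one parameter bundle, and a pair is fused symmetrically by
   element-wise multiplication x̄ = E(S₁) ⊙ E(S₂).
2. **Ordinal head.** The score range is split into K equal sub-intervals;
   the pair's sub-interval index is an ordered label k ∈ {1..K}. K−1 binary
   MLP sub-classifiers answer "is y > k?"; the predicted rank is
   r̄ = 1 + Σ<sub>k</sub> [f<sub>k</sub>(x̄) > 0], decoded to a score as the
   middle value of the r̄-th sub-interval, and thresholded (score > θ) into
   the PPI call. A scalar-regression head with the same encoder is included
   as the ablation baseline.

Training uses AMSGrad (lr 0.001, β₁ 0.9, β₂ 0.999, batch 768 at full
scale) on the summed cross-entropy of all K−1 relabelled sub-problems.
Evaluation covers accuracy, precision, sensitivity, specificity and F1 per
sub-classifier or per θ, plus MAE/MSE of the predicted scores and the
θ = 0.1…0.9 sweep.

## Worked example

Everything below is synthetic and self-contained: the generator plants a
monotone relationship between a pair-composition statistic and the score,
so the pipeline is testable without any database download.

```r
library(ordppi)

cfg      <- synthetic_config(seed = 1)             # 300 seqs, 3000 pairs, K = 5
records  <- gen_sequences(cfg)
pairs    <- label_pairs(gen_scored_pairs(records, cfg),
                        interval_partition(0, 1, K = 5))
pairs    <- balance_subsample(pairs, cap = 600, seed = 1)
split    <- split_train_test(pairs, train_fraction = 0.9, seed = 1)

model <- ordinal_model(interval_partition(0, 1, 5),
                       rcnn_config(num_units = 2, hidden = 16),
                       eh_table(), max_len = 120, head_hidden = 16, seed = 1)
fit   <- train_ordinal(model, split$train, records,
                       training_config(learning_rate = 0.003,
                                       batch_size = 128, epochs = 600,
                                       seed = 1, validation_fraction = 0.1,
                                       patience = 60))
preds <- predict_pairs(fit$model, split$test, records, theta = 0.5)
head(preds, 3)
score_errors(preds$score, split$test$score)
```

```
       id1      id2 rank score  call
1 seq00269 seq00245    1   0.1 FALSE
2 seq00078 seq00072    2   0.3 FALSE
3 seq00180 seq00096    2   0.3 FALSE
trained for 112 epochs; test MAE 0.108, MSE 0.0192 on 234 held-out pairs
```

The `rank` column is the predicted sub-interval (1–5), `score` its middle
value, `call` the thresholded PPI decision. An identically trained model
with shuffled training labels scores test MAE 0.202 (the class prior), so
the 0.108 above reflects genuine recovery of the planted composition
signal — roughly halving the prior-level error, though short of the
≈ 0.06 censored noise floor; the methods vignette quantifies why the
margin is limited at this data scale.

The same workflow is scriptable:

```sh
ordppi simulate       --out-dir fixture --seed 1
ordppi pretrain-embed --fasta fixture/sequences.fasta --out emb.txt --method skipgram
ordppi train          --fasta fixture/sequences.fasta --pairs fixture/pairs.tsv \
                      --out-prefix model --embedding eh --K 5 --max-len 120 \
                      --units 2 --hidden 16 --epochs 60 --batch-size 128 --lr 0.003
ordppi predict        --checkpoint model.ckpt.rds --fasta fixture/sequences.fasta \
                      --pairs fixture/pairs.tsv --out preds.tsv --theta 0.5
ordppi evaluate       --predictions preds.tsv --truth fixture/pairs.tsv \
                      --out-prefix eval --K 5 --subclassifiers 2,3 --sweep
```

(`ordppi` is the installed `exec/ordppi` script; `Rscript -e
'ordppi::ordppi_main(...)'` is equivalent.)

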