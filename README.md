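# ecglink

Arrhythmia classification of variable-length 12-lead ECG records with a
CNN-transformer model and a must-link/cannot-link embedding regularizer.

Clinicians label 12-lead electrocardiograms — twelve voltage channels
sampled at 500 Hz for 6 to 60 seconds — with rhythm diagnoses such as
atrial fibrillation (AF), first-degree atrioventricular block (I-AVB),
bundle branch blocks (LBBB/RBBB), premature contractions (PAC/PVC) and
ST-segment deviations (STD/STE). Automating this is hard because records
differ in length, the class-defining features are subtle intervals and
sub-millivolt offsets, and recordings carry baseline wander, muscle noise
and electrode artifacts. `ecglink` is for researchers who want a fully
inspectable, dependency-light R implementation of an end-to-end pipeline
for this problem, testable without any clinical data.

## The method

1. **Signal conditioning.** Per channel: clip outliers to a threshold set
   from the whole signal (default `median(|x|) + 8·MAD`), then a 6-level
   bior2.6 discrete wavelet decomposition in which the two finest detail
   bands (high-frequency noise) and the coarsest approximation (baseline
   drift, < 3.9 Hz) are zeroed before reconstruction.
2. **Segmentation.** Fixed windows of 3000 samples every 1500 samples; a
   record of `T` samples yields `floor((T − 3000)/1500) + 1` windows.
3. **Model.** Each window maps through seven conv–batchnorm–ReLU–maxpool
   blocks to a 150-dim feature; features are projected to `d_model = 256`,
   sinusoidal positional encoding is added, and an 8-layer transformer
   encoder (8 heads, `softmax(QKᵀ/√d_k)V` attention, 256→1024→256
   feed-forward) runs over the window sequence. Mean pooling gives one
   256-dim embedding `X_embed` per record; a linear–ReLU–linear–softmax
   head gives class probabilities.
4. **Link-constrained loss.** With `e_pq = +1` for same-class pairs and
   `−1` otherwise, training minimizes

   `CE + λ · Σ_{p≠q} ½‖β_p − e_pq β_q‖²`,

   which drives same-class embeddings together and different-class
   embeddings toward antipodes — equivalently, pushes intra-class Pearson
   correlation to +1 and inter-class correlation to −1.
5. **Evaluation.** Confusion matrix, per-class F1 = 2TP/(2TP+FP+FN), macro
   F1, per-class embedding centers (centroids) and their Pearson
   similarity matrix.

Every forward and backward pass (convolution, batch/layer norm, attention,
Adam) is explicit matrix code in `R/`; analytic gradients are verified
against finite differences in the test suite. A seeded generator produces
class-conditional synthetic 12-lead records (Gaussian-bump P-QRS-T beats
whose parameters carry each class's defining feature) plus the three noise
processes the conditioning stage removes.

## Worked example

```r
library(ecglink)

spec <- synthetic_spec(n_records = 30, n_classes = 3,
                       duration_range = c(6, 10), seed = 42)
ds <- generate_dataset(spec)
ds
#> <ecg_dataset: 30 records; labels: normal=10 AF=10 I-AVB=10>
ds[[1]]
#> <ecg_record syn0001: 12 x 3939 @ 500 Hz (7.9 s), label = 0 (normal)>

cond <- preprocess_record(ds[[1]])     # clip outliers + wavelet denoise
st <- segment_record(cond)             # 7.9 s -> 1 full 6-s window
dim(st$segments)
#> [1]    1   12 3000
```

The package's reduced-scale experiment (300 synthetic records over
normal/AF/I-AVB, a 2-conv-block / 2-encoder-layer / `d_model` 32 model,
20 epochs, a few minutes on one CPU core):

```r
res <- run_reduced_experiment(seed = 1, lambda = 0.1)
res$evaluation$diagnostics$macro_f1
#> [1] 0.9333333
res$gap          # mean intra-class minus inter-class embedding correlation
#> [1] 1.270455

res0 <- run_reduced_experiment(seed = 1, lambda = 0)   # same budget, no link term
res0$evaluation$diagnostics$macro_f1
#> [1] 0.8997494
res0$gap
#> [1] 0.7582125
```

The held-out macro F1 of 0.93 says the reduced model learns the synthetic
task; the correlation gap of 1.27 with the link penalty versus 0.76
without it shows the regularizer doing exactly what it is designed to do —
same-class embeddings become more similar, different-class embeddings less
so, under an otherwise identical training run.

## Command line

A thin CLI over the same functions ships at `inst/cli/ecglink.R`
(subcommands `simulate`, `preprocess`, `train`, `evaluate`, `describe`,
`run`), e.g.:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ecglink.R",package="ecglink"))')" \
  simulate --n-records 50 --classes 3 --seed 7 --out data/
```

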