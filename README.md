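# ftirnet

Chemometric classification of ATR-FT-IR spectra by geographic origin.

Medicinal plants such as gentian root vary in chemical composition
with the region they grew in, and mid-infrared absorbance spectra
carry those compositional signatures. `ftirnet` implements the full
benchmark pipeline for recovering origin from a spectrum:

* **Pre-processing** — the six standard chemometric operators
  (per-spectrum min-max normalisation *Norm*, Savitzky–Golay
  smoothing *SG*, per-wavenumber mean centring *MC*, wavelet denoising
  *WT*, multiplicative scatter correction *MSC*, standard normal
  variate *SNV*) and the enumeration of their 21 one- and two-step
  chains, fitted leakage-safely on the training partition.
* **Features** — PCA (default 20 components, sign-fixed, fitted on
  train) feeding three classical learners: decision tree, Gaussian
  naive Bayes, RBF SVM (one-vs-one).
* **Networks** — a back-propagation MLP and the two-branch
  **Double-Net**: two feed-forward branches of identical topology
  over the same full-resolution spectrum, merged by elementwise
  summation of their output activations before a softmax head,

      p(y | x) = softmax( W [f₁(x) + f₂(x)] + b ),

  trained by mini-batch Adam on the multiclass cross-entropy,
  seed-deterministic end to end.
* **Benchmark harness** — one stratified 80/20 split shared across
  all 22 configurations (NO_OP + 21 chains), per-cell accuracy and
  macro-F1 from one-vs-rest confusion counts
  (precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R)), and
  a rendered table with Max/Min/Avg summary rows.
* **Synthetic generator** — Gaussian band mixtures with
  class-dependent band-amplitude shifts, per-sample perturbations,
  polynomial baseline drift, `gain·x + offset` scatter and white
  noise, averaged over analytical replicates. The default
  configuration (222 samples, 7 origin classes, 7468-point grid,
  4000–400 cm⁻¹) is the packaged benchmark; every downstream stage is
  testable without instrument data.

See the methods vignette (`vignettes/ftirnet-methods.Rmd`) for the
model, its assumptions, and all numerical conventions.

## Worked example

```r
library(ftirnet)

ds <- generate_dataset(synthetic_config(seed = 1))
ds
#> <spectra_dataset> 222 spectra x 7468 points, 7 classes; grid 4000 -> 400 cm^-1
#>
#> class1 class2 class3 class4 class5 class6 class7
#>     38     36     34     32     30     28     24

class_separation(ds)
#> [1] 1.313596

rep <- run_benchmark(
  ds,
  configs = list(preproc_config(),                 # NO_OP
                 preproc_config("SNV"),
                 preproc_config(c("WT", "SNV"))),
  models = c("naive_bayes", "svm", "double_net"),
  split_seed = 1)
report_table(rep)
#>     config naive_bayes_acc naive_bayes_f1   svm_acc    svm_f1 double_net_acc double_net_f1
#> 1    NO_OP       0.9545455      0.9581668 0.9772727 0.9794872      0.8409091     0.8384615
#> 2      SNV       0.9090909      0.9046600 0.9772727 0.9794872      0.7272727     0.6975007
#> 3 WT + SNV       0.9318182      0.9301948 0.9772727 0.9774892      1.0000000     1.0000000
#> 4      Max       0.9545455      0.9581668 0.9772727 0.9794872      1.0000000     1.0000000
#> 5      Min       0.9090909      0.9046600 0.9772727 0.9774892      0.7272727     0.6975007
#> 6      Avg       0.9318182      0.9310072 0.9772727 0.9788212      0.8560606     0.8453208
```

Reading the numbers: each row is one pre-processing chain, each cell a
held-out score on the shared 44-spectrum stratified test set. The
classical learners see 20 train-fitted PCA scores, which already
absorb most of the baseline/scatter variation, so naive Bayes and the
SVM do well even on raw spectra. The networks consume the raw
7468-point spectra directly and are more sensitive to both the
pre-processing chain and the mini-batch seed (each cell trains with
its own logged seed): on this split the Double-Net goes from 84 % on
NO_OP to a perfect test set — accuracy 1.0, macro-F1 1.0 — once
wavelet denoising and SNV strip the noise and the `gain·x + offset`
scatter family. The full 22-row sweep is `run_benchmark(ds)` (~5
minutes for `models = "double_net"` on one CPU core), and
`render_report(rep, "report")` writes the CSV/text/JSON report
triplet.

A command-line wrapper covers the same workflow
(`generate`, `preprocess`, `benchmark`, `report`):

```sh
Rscript inst/cli/ftirnet.R benchmark --synthetic --seed 1 --configs all21 --out runs/
```

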