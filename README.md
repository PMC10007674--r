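# ChoquetFusion

Decision-level fusion of multi-view classifier outputs with the discrete
Choquet integral, for consensus classification from a camera array.

## The problem

When several cameras observe the same plant, each view's classifier yields a
softmax probability vector over the same C disease classes — a C×K score
matrix per capture (the motivating instance is 38 classes × 4 cameras). A
single view can be ruined by occlusion or background clutter; a consensus
over views should not be. ChoquetFusion is for researchers and engineers who
have such per-view probability outputs (from any classifier) and want a
principled, reproducible fusion rule plus the evaluation and simulation
machinery to quantify its robustness.

## The method

For each class c, the K view scores are sorted increasingly and aggregated
by the discrete Choquet integral with respect to a fuzzy measure m:

    C_m(x) = Σ_{i=1..n} (x_(i) − x_(i−1)) · m(A_(i)),     x_(0) = 0,

where A_(i) holds the indices of the n−i+1 largest components. The measure
is the symmetric power measure m_q(X) = (|X|/n)^q with q > 0, so m(A_(i))
depends only on cardinality. The consensus class is the maximum fused
response, with deterministic lowest-index tie-breaking. q = 1 gives the
arithmetic mean; q → 0⁺ tends to max, q → ∞ to min. Decisions are scored
with one-vs-rest precision, recall and F_β = (1+β²)·P·R/(β²·P+R) for
β ∈ {0.5, 1}, macro-averaged over classes.

A Dirichlet-based simulator generates per-view softmax outputs in a clean
regime (strong signal, rare corrupted views) and a degraded regime (weaker
signal, 35% of views carrying no information), so the single-camera vs
camera-array comparison can be run entirely in probability space — no
images or trained networks required.

## Worked example

```r
library(ChoquetFusion)

m <- powerMeasure(q = 1, n = 4)
m
#> CardinalityMeasure 'power(q=1)' on n = 4 elements
#>   m(|X|=k), k = 0..n: 0.00 0.25 0.50 0.75 1.00

choquet(c(0.10, 0.50, 0.70, 0.90), m)
#> [1] 0.55        # q = 1 makes the integral the arithmetic mean

cfg <- simulationConfig("degraded", nCaptures = 2000, seed = 2023)
rep <- runExperiment(cfg, qValues = 1, modes = c("choquet", "single_view"))
rep[, c("mode", "q", "Prec", "Rec", "F0.5", "F1", "accuracy")]
#>              mode  q  Prec   Rec  F0.5    F1 accuracy
#> 1         choquet  1 0.945 0.946 0.945 0.945    0.946
#> 2   single_view:1 NA 0.633 0.634 0.632 0.632    0.636
#> 3   single_view:2 NA 0.624 0.625 0.623 0.622    0.625
#> 4   single_view:3 NA 0.617 0.618 0.616 0.615    0.618
#> 5   single_view:4 NA 0.637 0.637 0.635 0.635    0.636
#> 6 single_view:avg NA 0.628 0.629 0.627 0.626    0.629
```

With 35% of views corrupted, any single camera reaches macro-F1 ≈ 0.63
while the four-camera Choquet consensus reaches ≈ 0.95: fusing the array
averages out the uninformative views. In the clean regime the same
comparison gives a much smaller gain — robustness is where the array pays.

## Command line

A thin Rscript front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/choquetfuse.R", package="ChoquetFusion"))')
Rscript "$CLI" simulate --regime degraded --n 2000 --seed 1 --out-dir out/
Rscript "$CLI" fuse     --scores out/scores.csv --q 1 --out-dir out/
Rscript "$CLI" evaluate --predictions out/predictions.csv \
                        --truth out/labels.csv --out-dir out/
```

Score matrices travel as CSV (`capture_id,class,view1,...`), predictions
and reports as CSV/JSON with the run configuration echoed as provenance.
Options may also come from a YAML/JSON `--config` file; explicit flags win.

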