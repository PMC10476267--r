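# bridgeTMT

Normalization and inference for longitudinal tandem-mass-tag (TMT)
proteomics experiments that are split across several multiplexes joined by
an identical **bridge channel**.

The motivating design is an in vitro myogenesis time course: C2C12 cells
sampled as myoblasts (M, day 0), early myotubes (EM, day 5) and late
myotubes (LM, day 9), each stage labeled as one TMT 10-plex with nine
sample channels ({untreated, vehicle, tamoxifen} × 3 replicates) and a
tenth channel carrying a pooled bridge sample common to all three
multiplexes. The same machinery applies to any multi-batch isobaric design
with a reference channel.

## What it computes

**Two-layer normalization.** Channels are first scaled so every channel
total equals the grand mean of all channel totals (sample-loading
normalization). Then, per protein *p* and non-reference multiplex *m*, the
bridge offset

    Δ(p, m) = log2 bridge(p, ref) − log2 bridge(p, m)

is added to every log2 channel value of *p* in *m*. Because the bridge is
the same physical sample in every multiplex, Δ estimates the multiplex
batch effect per protein, and after correction each protein's bridge value
is identical across multiplexes.

**Longitudinal regulation (MR) calls.** For each condition, per-protein
stage ratios log2FC(EM/M) and log2FC(LM/M) are tested with two-sample
pooled-variance (Student) t tests on log2 abundances and adjusted with
Benjamini–Hochberg per comparison family. A protein is *myogenically
regulated* iff both adjusted p-values are ≤ 0.05 **and** |log2FC| ≥ 1 at
either stage.

**Trajectory clustering.** MR proteins are represented by the standardized
triple (log2 mean M abundance, log2FC EM/M, log2FC LM/M) — each column
median-centred and scaled to SD 1 — and clustered with k-means (k = 5,
k-means++ seeding, best of 50 restarts). Clusters from two conditions are
matched by the minimum-cost assignment of centroids, with per-pair protein
overlaps.

**Stagewise differential expression.** Within each multiplex, vehicle and
tamoxifen channels are corrected to the per-protein mean untreated log2
value (removing vehicle/treatment interactions tied to the baseline), then
TMX vs vehicle is tested per protein; DE requires |log2FC| ≥ 1 and
BH-adjusted p < 0.05.

**Set logic.** Three-way Venn partition of the MR sets, exclusion of
proteins regulated only in the presence of vehicle, DE ∩ MR splits, and
the "highly regulated" call (DE at ≥ 2 stages).

**Synthetic data.** `sim_config()` / `simulate_multiplexes()` generate the
full three-multiplex design from five planted trajectory archetypes with
per-multiplex batch factors, per-channel loading factors, vehicle-only and
treatment-specific effects, and log-normal measurement noise — with a
ground-truth ledger for recovery benchmarking.

## Worked example

```r
library(bridgeTMT)

cfg   <- sim_config(n_proteins = 2000, seed = 3)   # ~10% regulated proteome
truth <- generate_ground_truth(cfg)
sim   <- simulate_multiplexes(truth, cfg)

bridged <- normalize_experiment(sim$matrices, sim$design, reference = "M")
bridged
#> bridged_abundance: 2000 proteins x 27 sample channels (reference
#> multiplex 'M'; 0 proteins dropped for missing bridge)

max(apply(bridged$bridge_log2, 1, function(v) diff(range(v))))
#> [1] 0        # bridges exactly aligned across multiplexes

mr <- call_mr(bridged, "untreated")
sum(mr$is_mr)
#> [1] 58       # proteins passing both-stage significance + fold change

de <- stage_de(bridged, "M")
sum(de$is_de)
#> [1] 0        # no treatment effects planted, none called

traj <- build_trajectories(bridged,
                           truth$protein_id[truth$archetype != "flat"])
km <- kmeans_cluster(traj, k = 5, seed = 17, n_restarts = 20)
km
#> cluster_model: k = 5, n = 214, sizes = [32, 33, 70, 31, 48],
#> inertia = 158.015
```

The bridge spread of 0 shows the per-protein correction removed all
between-multiplex offsets; the MR count is the planted strongly-regulated
subset recovered at the default thresholds; the cluster sizes partition
the regulated proteins among the five trajectory shapes.

A full run from one YAML config (simulation or TSV inputs, thresholds,
clustering settings) writes every stage's TSV plus a JSON manifest:

```r
run_pipeline("run.yaml", "results/")
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --config run.yaml
--out results/`.

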