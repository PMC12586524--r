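# fedgat

Federated multi-label graph classification with client-specific label
semantics, structure-sensitive spectral features, and similarity-clustered
server aggregation — as an R library plus a single-process federated
simulator.

## The problem

In privacy-sensitive graph learning (molecular toxicity panels, drug
side-effect profiles), each site holds its own collection of attributed
graphs `x` with multi-label annotations `y ∈ {0,1}^C`, and the sites
cannot pool raw data. Plain federated averaging (FedAvg) of locally
trained graph neural networks degrades when (a) label prevalences differ
across clients and (b) the graph populations themselves are structurally
heterogeneous. `fedgat` implements a method that attacks both at once.
The global objective is the sample-weighted federated risk

```
min_W  Σ_k (M^k / |M|) L_k(W)
```

with three additions to the plain pipeline:

1. **Client-specific label semantics.** Per-client label frequencies
   `f_k` are smoothed and normalised, `w_k = (f_k + ε) / Σ_j (f_j + ε)`,
   and scale pluggable label embeddings, `l̃_k = w_k l_k`. A weighted
   label semantic graph (cosine-similarity edges, multi-scale
   neighborhoods at 1/2/3 hops) is encoded by a masked multi-scale graph
   attention autoencoder into a label context embedding `F`.
2. **Spectral structure features.** Each graph's unnormalised Laplacian
   `L = D − A` is truncated-eigendecomposed; the top-`M` eigenvectors,
   flattened to a fixed length, join the classifier input. The
   per-client mean of these features — privatised by the Gaussian
   mechanism with `σ = Δf/ε` (ε = 10 by default) — is all the server
   ever sees of a client's structure.
3. **Clustered aggregation.** The server builds the cosine similarity
   matrix `S_ij` of the privatised summaries, groups clients by spectral
   clustering, federated-averages within groups, and fuses group models
   with trace gates `β_p = trace(S_Gp) / Σ_q trace(S_Gq)`.

The local classifier is a three-layer multi-head graph attention network
(`LeakyReLU(a·[Wh_i ‖ Wh_j])` attention, softmax-normalised over
neighborhoods), mean-pooling readout, and a classifier MLP over
`concat(x_pool, flatten(F), g)` with independent sigmoid outputs and
per-label binary cross-entropy. All neural components run on a small
in-package reverse-mode autodiff tape, so analytic gradients are checked
against finite differences in the test suite.

A synthetic-data module generates federated datasets with planted
structural client groups (Erdős–Rényi vs Barabási–Albert families),
Dirichlet-skewed label prevalences, and structure-derived labels, so the
whole pipeline runs and is tested without any download.

## Worked example

```r
library(fedgat)

# reference synthetic conditions: 8 clients, 2 structural families,
# 60 graphs/client, 6 structure-derived labels, Dirichlet(0.3) skew
gen <- generate_synthetic(synthetic_spec(), seed = 42)
gen$dataset
#> <fedgat_dataset> K = 8 clients, C = 6 labels, 480 graphs
#>   shard sizes: 60, 60, 60, 60, 60, 60, 60, 60

prevalence_report(gen$dataset)   # per-client label skew
#> # A tibble: 8 × 7
#>   client_id    L01    L02   L03    L04    L05   L06
#> 1 client01  0.833  0.55   0.433 0.3    0.317  0.467
#> 2 client02  0.0667 0.0667 0.9   0.0333 0.0667 0.583
#> ...

# can the server see the planted structure through the DP noise?
cfg <- fedgat_config()
sums <- lapply(gen$dataset$shards, shard_spectral_summary,
               config = cfg, seed = 1)
cluster_clients(similarity_matrix(sums), n_groups = 2)
#> <fedgat_groups> 2 group(s):
#>   G1: 1, 3, 5, 7        # exactly the planted ER / BA families
#>   G2: 2, 4, 6, 8

# 10 communication rounds at reduced width (minutes on one core)
cfg <- fedgat_config(
  labels = list(embedding_dim = 16),
  ae = list(epochs = 60L, hidden_dim = 8L, heads = 2L),
  backbone = list(hidden = c(16L, 16L), heads = c(2L, 2L, 1L),
                  head_hidden = 32L),
  federation = list(rounds = 10L, eval_every = 5L))
run <- run_federation(gen$dataset, cfg, seed = 7)
run$final_eval
#> <fedgat_eval> n = 120 graphs
#>   AUC(macro) 0.8063  mAP 0.6952
#>   C-P 0.6194  C-R 0.4100  C-F1 0.4296
#>   O-P 0.7378  O-R 0.4672  O-F1 0.5721  (threshold 0.50)

glance(run)    # one-row tibble of the final metrics
tidy(run)      # long per-round history, ready for ggplot2
ggplot2::autoplot(run)
```

Macro AUC 0.81 against the 0.5 chance floor on held-out graphs after 10
rounds: the held-out set pools every client's test split, each scored
with its own label context embedding. The grouping output shows the
server recovering the two planted graph families from the privatised
spectral summaries alone.

Ablation switches mirror the method's components:
`fedgat_config(ablate = list(weighted = TRUE))` (uniform label weights),
`graph` (zeroed label context), `multiscale` (scale-1 only), `asyagg`
(plain sample-weighted FedAvg server).

A thin CLI over the same functions lives at `inst/cli/fedgat.R`
(`gen-data`, `run`, `evaluate`, `ablate`; YAML configs).

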