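# endocor

Cross-tissue endocrine co-correlation analysis with estrogen-state
stratification.

Hypothalamic somatostatin neurons respond to both reproductive hormones
and adiposity signals, raising the question of *which peripheral tissues
they communicate with, and whether that changes with estrogen signaling*.
`endocor` answers the desk-side half of that question for multi-tissue
expression cohorts (many tissues, sparse per-donor availability): it
infers a per-individual estrogen-signaling state from an
estrogen-responsive gene signature, stratifies the cohort into high and
low bins, and measures cross-tissue communication as the biweight
midcorrelation between peripheral hormone/ligand/secreted-protein/feeding
gene programs and hypothalamic neuron-derived target genes, separately
per stratum.

The core statistic is the biweight midcorrelation: with
`u_i = (x_i − med(x)) / (9·MAD(x))` (raw MAD, no consistency constant),
weights `a_i = (1 − u_i²)²·1[|u_i| < 1]` and
`x̃_i = (x_i − med(x))·a_i`,

```
bicor(x, y) = Σ x̃_i ỹ_i / (‖x̃‖·‖ỹ‖)
```

so individuals far from the median are down-weighted and a single outlier
donor cannot fabricate a cross-tissue correlation. Strata are then
compared per functional category with a tie-corrected Kruskal–Wallis test
across tissue × stratum cells, BH-adjusted Welch contrasts per tissue,
and a profile-similarity statistic (bicor between the strata's aligned
coefficient vectors; negative values mean the strata use different
tissue channels).

A synthetic multi-tissue cohort generator with known ground truth (latent
estrogen state, configurable per-tissue/per-stratum coupling, sparse
donor-tissue availability) makes every stage testable without any
external download.

## Worked example

Run the full pipeline on a simulated cohort (300 individuals, six
tissues, the default stratum-dependent coupling pattern):

```r
library(endocor)
cfg <- pipeline_config(mode = "simulate", out_dir = "runs/demo", seed = 7)
res <- run_pipeline(cfg)
cat(readLines(res$paths$summary_text), sep = "\n")
```

Output (abridged):

```
Cross-tissue co-correlation run summary
categories analysed: 4
tissues kept: adipose_subcutaneous, adipose_visceral, skeletal_muscle, stomach
tissue dropped: small_intestine (insufficient matching; min per-stratum matched n = 19 < 30)

category secreted: Kruskal-Wallis H = 16.1 (df = 7), p = 0.02421
  adipose_subcutaneous: high>low (stat 2.596, adj p 0.02013)
  adipose_visceral: high>low (stat 3.259, adj p 0.005145)
  skeletal_muscle: low>high (stat -1.815, adj p 0.07104)
  stomach: low>high (stat -2.311, adj p 0.029)
  profile similarity high vs low: r = 0.2692, p = 5.945e-10 (n = 512)

overall profile similarity: r = 0.2806, p = 2.226e-38 (n = 2048)

seed: 7
```

Reading it: the small intestine is set aside because too few simulated
donors have both that tissue and hypothalamus (the sparse-matching
scenario); in the kept tissues the high-estrogen stratum shows stronger
adipose-to-hypothalamus co-correlation while the low stratum couples more
through skeletal muscle and stomach — exactly the pattern the generator
was configured to embed. The profile similarity is positive here because
both strata share the same signal-bearing gene pairs; it turns negative
when the strata's tissue channels are made opposing (see the acceptance
script's `opposing_profile_similarity_mean_bicor`).

Every intermediate is written to the run directory as TSV
(`estrogen_states.tsv`, `records_<tissue>.tsv`, `tissue_screen.tsv`) plus
`summary.json` / `summary.txt`, and each stage can be re-run standalone
from those files (`stage_estrogen()`, `stage_correlate()`, …). A thin
CLI wraps the same stages:

```sh
exec/endocor run-all --config demo.yaml --seed 7
```

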