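# cernet

Inference and analysis of miRNA-mediated competing-endogenous-RNA (ceRNA)
networks, with survival modelling of lncRNA risk signatures.

## The problem

Under the ceRNA hypothesis, transcripts that share miRNA response elements
compete for a common miRNA pool: a lncRNA that sponges a miRNA de-represses
that miRNA's mRNA targets. In matched expression profiles this predicts a
distinctive correlation pattern for a lncRNA–miRNA–mRNA triplet — the lncRNA
and mRNA positively correlated with each other, both negatively correlated
with the shared miRNA. `cernet` is for researchers who have (i) matched
miRNA / lncRNA / mRNA expression matrices over the same patients, (ii)
validated miRNA→target catalogs, and optionally (iii) clinical follow-up,
and who want to go from those inputs to a characterized ceRNA network and a
prognostic lncRNA signature.

## What it computes

**Crosstalk inference.** For each lncRNA–mRNA pair the sample Pearson
correlation

&nbsp;&nbsp;&nbsp;&nbsp;*r* = 1/(n−1) Σᵢ [(xᵢ−x̄)/σₓ] · [(yᵢ−ȳ)/σᵧ]

is compared against the 99th percentile of the full pairwise distribution
(or a fixed cutoff). Pairs above threshold that share ≥ 1 catalog miRNA are
*candidates*; candidates where some shared miRNA satisfies r < 0 (two-sided
p < 0.05) against **both** partners are *functional*, and integrate into an
undirected ceRNA network with per-edge triplet provenance.

**Network analysis.** Global statistics (clustering coefficient, path
length, diameter, density, heterogeneity), per-node centralities, and
empirical significance against 1000 degree-preserving double-edge-swap
random networks, including the small-world index
σ = (CC/CC_r)/(CPL/CPL_r). Per-class top-5% hubs, MCODE dense-module
mining, hypergeometric gene-set enrichment and neighbor-based
(guilt-by-association) lncRNA function inference.

**Prognosis.** Multivariate Cox fitting of signature lncRNAs; the risk score
Σᵢ Wᵢ·Expᵢ dichotomized at the cohort median; Kaplan–Meier curves with
two-sided log-rank tests and hazard ratios; univariate/multivariate Cox
covariate tables; stratified analyses; time-dependent ROC (KM-based
cumulative/dynamic estimator); hierarchical-clustering patient splits.

**Synthetic cohorts.** A generator that plants ceRNA triplets with the
assumed correlation structure and proportional-hazards survival with known
lncRNA coefficients, so the whole pipeline is testable without any external
download.

## Worked example

```r
library(cernet)

cohort <- generate_cohort(synthetic_spec(seed = 1))   # 200 patients
inf <- infer_cerna_network(cohort$set, cohort$mirna_mrna,
                           cohort$mirna_lncrna, cerna_edges = TRUE)
glance(inf$network)
#>   condition n_nodes n_mirna n_lncrna n_mrna n_edges
#> 1 global         80      40       20     20     100

rand <- randomization_test(inf$network, replicates = 200, seed = 1001)
topology_summary(inf$network, randomization = rand)[, 1:6]
#>   condition n_nodes n_edges clustering_coefficient characteristic_path_length small_world_index
#> 1 global         80     100              0.833                      1.17               462

model <- fit_risk_model(cohort$set$lncrna, cohort$set$clinical,
                        signature_ids = c("lnc001", "lnc002"))
tidy(model)
#>   lncrna_id coefficient    HR
#> 1 lnc001          0.563 1.76
#> 2 lnc002         -0.534 0.586

scores <- risk_scores(model, cohort$set$lncrna)
surv <- km_logrank(dichotomize(scores, model$cutoff), cohort$set$clinical)
surv
#> <survival_comparison>
#>   low: n=100, median OS=81.66 months
#>   high: n=100, median OS=24.27 months
#>   log-rank chisq=31.440 (df=1), p=2.06e-08

time_dependent_roc(scores, cohort$set$clinical, eval_time = 60)
#> <td_roc> AUC = 0.761 at t = 60 months
```

The planted Cox coefficients were ±0.6; the fit recovers 0.56/−0.53. The
high-risk group's median survival (24 vs 82 months) and the 60-month AUC of
0.76 reflect the planted hazard structure. `autoplot()` methods draw the KM
curves and ROC; `run_pipeline()` executes all stages from a YAML config and
writes the report bundle (triplets, networks, topology, hubs, modules,
risk tables) to disk.

The methods vignette (`vignettes/cerna-networks.Rmd`) documents the model,
every tunable parameter, the null-model and MCODE details, and what the
synthetic cohort does and does not emulate.

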