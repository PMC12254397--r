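# Example screening run configuration.
# Columns named here must exist in the input TSV header.
input: mediscreen-output/cohort.tsv
traits: null            # null = every numeric column that is not id/confounder/exposure/mediator
mediators: [activity]
confounders: [age, sex]
strata: [combined, female, male]
estimands: [TE, NDE, NIE]
library: [gam, glmnet, glm_interaction, xgboost]
K: 10
cross_fit: true
delta: 0.025            # propensity truncation bound
winsor: 0               # per-tail winsorization fraction (0 = off)
fdr: 0.05
family_mode: per-analysis
special_codes: [-1, -3] # mediator non-response sentinels removed before NDE/NIE
seed: 1
out_dir: mediscreen-output/screen
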