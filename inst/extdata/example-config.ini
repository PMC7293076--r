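# Example staghunt run configuration. Any key omitted here keeps the
# preset/default value; see ?loadConfig.

[world]
n_boars = 9
n_stags = 9
trial_steps = 20000

[payoffs]
boar_coop = 125
stag_coop = 250
solo = 0

[evolution]
population_size = 20
n_elites = 10
n_partners = 5
trials_per_pair = 5
scheme = elitist

[mutation]
per_gene_prob = 0.005
sd = 0.2
duplication_prob = 0.05
deletion_prob = 0.005
duplication_enabled = true

[protocol]
preset = complex-asym
scale = paper
n_replicates = 30
base_seed = 1
pre_generations = 3000
post_generations = 6000
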