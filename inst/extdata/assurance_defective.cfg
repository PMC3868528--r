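# assurance-defective scenario: 15% of meioses never engage the chromosome,
# weak interference, elevated conversion, nondisjunction of achiasmate
# bivalents with a partially effective back-up segregation system.
# mean_CO is the per-engaged-meiosis mean, chosen so the population map
# length measured over all tetrads (achiasmate subpopulation included)
# comes out near 117 cM (~2.3 crossovers per meiosis).
n_tetrads = 3000
co_model = counting
interference_m = 1
mean_CO = 2.75
obligate_CO = TRUE
assurance_fail_q = 0.15
conversion_prob = 0.009
backup_efficiency_b = 0.9
spore_death_rate = 0.295
seed = 2027
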