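# reference scenario: efficient assurance, strong interference; a small
# residual achiasmate fraction (~0.9% non-exchange tetrads) of which about
# half nondisjoin, giving ~0.4% disomic tetrads
n_tetrads = 3000
co_model = counting
interference_m = 4
mean_CO = 2.632
obligate_CO = TRUE
assurance_fail_q = 0.009
conversion_prob = 0.005
backup_efficiency_b = 0.53
spore_death_rate = 0.04
seed = 2026
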