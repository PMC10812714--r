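# Default simulated-study run: two-group Balding-Nichols data (12-diploid
# test population vs 33-diploid control, F = 0.05, 50,000 SNPs on 10 Mb)
# with five planted 200-kb sweeps at strength 0.95 in the test population.
seed: 7
test_population: BG
simulate:
  seed: 7
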