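# Demo configuration: full synthetic-data run of the admixture-chronology
# pipeline, sized to finish in a few minutes on one CPU.
seed: 7
output_dir: admixchron_demo

simulate:
  n_snps_per_chrom: 1200
  n_chroms: 10
  chrom_length: 1.0
  alpha_autosome: 0.4
  alpha_X: 0.25
  admixture_generations: 30
  n_admixed: 16
  n_source1: 10
  n_source2: 10
  n_outgroup: 10
  include_x: true
  missing_rate: 0.05
  pseudo_haploid: true

blocks:
  size_cm: 5

fstats:
  targets: [Admixed]
  baseline: SourceEA
  pop_c: SourcePAP
  pop_d: RightEA

qpadm:
  target: Admixed
  sources: [SourceEA, SourcePAP]
  rights: [RightDeep1, RightEA, RightPAP, RightDeep2]
  sex_bias: true

pca:
  reference_pops: [SourceEA, SourcePAP, RightEA, RightPAP]

dating:
  target_pop: Admixed
  source1: SourceEA
  source2: SourcePAP
  binsize: 0.001
  mindis: 0.005
  maxdis: 1.0

calibration:
  curves: toy
  toy: {slope: 1.0, wiggle_amp: 0.0, reservoir_offset: 500, sigma_14c: 15}
  # a bone dated ~2800 calBP under the toy mixed curve (dR -140, 50% marine)
  measurement: {age_14c: 2980, sigma: 40}
  delta_r: {mean: -140, sd: 35}
  marine_fraction: {mean: 0.5, sd: 0.1}

chronology:
  generation_interval: {mean: 28.4, sd: 0.7}
  threshold: 3200
  n_draws: 200000

sensitivity:
  delta_r:
    - {mean: -250, sd: 50}
    - {mean: -140, sd: 35}
    - {mean: -52, sd: 22}
    - {mean: 168, sd: 43}
  marine_fraction: [0.0, 0.2, 0.5, 1.0]
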