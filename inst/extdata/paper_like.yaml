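# Default "study-like" generator scenario. Every key is optional and
# mirrors an argument of generator_config(); omitted keys keep the
# package defaults shown here.
n_deaths: 2000
prevalence_true_indigenous: 0.02
report_sensitivity:        # P(record of a true member flags yes)
  death: 0.76              # death-registration reporting level
  APD: 0.88                # admitted-patient survey estimate
  PDC: 0.68                # perinatal linked-records estimate
  EDDC: 0.80               # unmeasured; placeholder
  RBDM: 0.80               # unmeasured; placeholder
report_fp_rate:            # P(record of a non-member flags yes)
  death: 0.0
  APD: 0.0
  EDDC: 0.0
  PDC: 0.0
  RBDM: 0.0
missing_rate:              # P(a non-yes flag is recorded as missing)
  death: 0.01
  APD: 0.01
  EDDC: 0.05
  PDC: 0.01
  RBDM: 0.01
stay_intensity: 1.2        # mean hospital stays, mid-age, before multipliers
episodes_extra_mean: 0.15  # mean extra transfer-linked episodes per stay
ed_intensity: 0.8          # mean ED attendances before multipliers
birth_record_probability: 0.9
mother_record_probability: 0.1
false_link_rate: 0.004     # reported linkage quality: 4/1000 false links
missed_link_rate: 0.005    # < 5/1000 missed links
seed: 1
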