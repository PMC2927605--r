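# Baseline risk-factor structure of a synthetic cohort of Australian women
# born 1921-26 (ALSWH-like). Category shares are the complete-case Survey 1
# distributions; references follow the conventions: modal category for
# nominal factors, declared best-survival end category for ordinal factors.
factors:
  - name: country_of_birth
    scale: nominal
    reference: Australia
    missing_rate: 0.070
    categories:
      Australia: 0.771
      Other English speaking: 0.135
      Other: 0.094
  - name: qualification
    scale: ordinal
    reference: University
    missing_rate: 0.016
    categories:
      University: 0.042
      Certificate/Diploma: 0.081
      Trade/Apprenticeship: 0.037
      Any high school: 0.522
      No formal qualification: 0.318
  - name: bmi
    scale: nominal
    reference: Acceptable
    missing_rate: 0.110
    categories:
      Acceptable: 0.502
      Overweight: 0.331
      Obese: 0.135
      Underweight: 0.032
  - name: physical_activity
    scale: nominal
    reference: Low to very high
    missing_rate: 0.016
    categories:
      Low to very high: 0.724
      None or very low: 0.276
  - name: alcohol
    scale: ordinal
    reference: Low-risk drinker
    missing_rate: 0.016
    categories:
      Low-risk drinker: 0.342
      Non-drinker: 0.336
      Rarely drinks: 0.288
      Risky or high-risk drinker: 0.034
  - name: smoking
    scale: nominal
    reference: Never smoker
    missing_rate: 0.074
    categories:
      Never smoker: 0.629
      Ex-smoker: 0.299
      Smoker: 0.072
  - name: self_reported_health
    scale: ordinal
    reference: Excellent
    missing_rate: 0.016
    categories:
      Excellent: 0.065
      Very good: 0.279
      Good: 0.393
      Fair: 0.225
      Poor: 0.038
strata:
  labels: [city, rural, remote]
  population_shares: [0.64, 0.26, 0.10]
  sampling_factors: [1.0, 2.0, 2.0]
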