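# Default synthetic cohort specification.
#
# Class-conditional structure of a reference cohort of 108 breast-cancer
# patients treated with neoadjuvant chemotherapy (43 pCR, 65 non-pCR):
# conditional probabilities of the IHC categoricals given response class and
# class-conditional means/SDs of the MTRasym / ADC histogram features.
# Features reported as median(IQR) in the reference are approximated as
# normal with mean = median, sd = IQR / 1.349.
n_patients: 108
prevalence: 0.39814815     # 43 / 108
rho: 0.8                   # exchangeable correlation within a feature block
seed: 1
categorical:
  er_positive:   {p_pcr: 0.25581395, p_nonpcr: 0.66153846}   # 11/43, 43/65
  pr_positive:   {p_pcr: 0.23255814, p_nonpcr: 0.52307692}   # 10/43, 34/65
  her2_positive: {p_pcr: 0.60465116, p_nonpcr: 0.21538462}   # 26/43, 14/65
  ki67_high:     {p_pcr: 0.97674419, p_nonpcr: 0.83076923}   # 42/43, 54/65
  node_positive: {p_pcr: 0.60465116, p_nonpcr: 0.61538462}   # 26/43, 40/65
  hg3:           {p_pcr: 0.27906977, p_nonpcr: 0.30769231}   # 12/43, 20/65
  postmenopausal: {p_pcr: 0.53488372, p_nonpcr: 0.49230769}  # 23/43, 32/65
  subtype:
    p_pcr:    {luminal_a: 0.02325581, luminal_b: 0.25581395,
               her2_enriched: 0.41860465, tn: 0.30232558}    # 1,11,18,13 /43
    p_nonpcr: {luminal_a: 0.04615385, luminal_b: 0.61538462,
               her2_enriched: 0.07692308, tn: 0.26153846}    # 3,40,5,17 /65
features:
  mtr_p5:   {mean_pcr: 0.83, sd_pcr: 2.22, mean_nonpcr: -0.54, sd_nonpcr: 2.62, block: mtr}
  mtr_p10:  {mean_pcr: 1.29, sd_pcr: 2.05, mean_nonpcr: 0.06,  sd_nonpcr: 2.23, block: mtr}
  mtr_p15:  {mean_pcr: 1.59, sd_pcr: 1.94, mean_nonpcr: 0.44,  sd_nonpcr: 2.03, block: mtr}
  mtr_p25:  {mean_pcr: 2.00, sd_pcr: 1.80, mean_nonpcr: 0.93,  sd_nonpcr: 1.89, block: mtr}
  mtr_p50:  {mean_pcr: 2.63, sd_pcr: 1.63, mean_nonpcr: 1.74,  sd_nonpcr: 1.77, block: mtr}
  mtr_p75:  {mean_pcr: 3.20, sd_pcr: 1.55, mean_nonpcr: 2.44,  sd_nonpcr: 1.78, block: mtr}
  mtr_p85:  {mean_pcr: 3.50, sd_pcr: 1.56, mean_nonpcr: 2.81,  sd_nonpcr: 1.84, block: mtr}
  mtr_mean: {mean_pcr: 2.55, sd_pcr: 1.69, mean_nonpcr: 1.64,  sd_nonpcr: 1.82, block: mtr}
  mtr_rmse: {mean_pcr: 3.02, sd_pcr: 1.17, mean_nonpcr: 2.57,  sd_nonpcr: 1.15, block: mtr}
  # median(IQR) rows, normal approximation sd = IQR/1.349
  mtr_iqr:  {mean_pcr: 1.04, sd_pcr: 0.556, mean_nonpcr: 1.35, sd_nonpcr: 0.704, block: mtr}
  adc_p1:   {mean_pcr: -0.15, sd_pcr: 0.467, mean_nonpcr: -0.36, sd_nonpcr: 0.482, block: adc}
  adc_p10:  {mean_pcr: 0.13,  sd_pcr: 0.563, mean_nonpcr: 0.26,  sd_nonpcr: 0.549, block: adc}
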