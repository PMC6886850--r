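# Model inputs for the aspirin primary-prevention Markov model.
# Costs are 2019 USD (1 USD = 6.61 CNY; the conversion is metadata only).
# dist: distribution family used in probabilistic sensitivity analysis;
#       "fixed" parameters are never sampled (low/high kept for scenario
#       scans where applicable).
currency: "USD, base year 2019 (1 USD = 6.61 CNY)"
parameters:
  # -- annual event rates in diabetes patients not taking aspirin --
  - {name: rate_mi,              base: 0.0031, low: 0.0025, high: 0.0037, dist: beta,      units: events per person-year}
  - {name: rate_stroke,          base: 0.0042, low: 0.0038, high: 0.0050, dist: beta,      units: events per person-year}
  - {name: rate_gi_bleed,        base: 0.0018, low: 0.0014, high: 0.0022, dist: beta,      units: events per person-year}
  # -- odds ratios, aspirin vs no aspirin --
  - {name: or_mi,                base: 0.98,   low: 0.93,   high: 1.04,   dist: lognormal, units: odds ratio}
  - {name: or_stroke,            base: 0.88,   low: 0.73,   high: 1.06,   dist: lognormal, units: odds ratio}
  - {name: or_gi_bleed,          base: 1.57,   low: 1.37,   high: 1.80,   dist: lognormal, units: odds ratio}
  # all-cause death OR: diabetes-subgroup meta-analysis point estimate 0.98
  # (the trials-restricted alternative is 0.94); range as published
  - {name: or_death,             base: 0.98,   low: 0.85,   high: 1.04,   dist: lognormal, units: odds ratio}
  # -- adherence and rate scaling --
  - {name: discontinuation,      base: 0.30,   low: 0.24,   high: 0.36,   dist: beta,      units: proportion}
  - {name: adjusting_factor,     base: 1.0,    low: 0.5,    high: 2.0,    dist: fixed,     units: multiplier on clinical event rates}
  # -- post-event transition probabilities --
  - {name: p_death_mi_year1,     base: 0.188,  low: 0.150,  high: 0.240,  dist: beta,      units: annual probability}
  - {name: p_death_stroke_year1, base: 0.144,  low: 0.115,  high: 0.173,  dist: beta,      units: annual probability}
  - {name: p_death_post_event,   base: 0.07,   low: 0.05,   high: 0.09,   dist: beta,      units: annual probability}
  - {name: p_death_gi_bleed,     base: 0.03,   low: 0.024,  high: 0.036,  dist: beta,      units: case fatality}
  - {name: hosp_days_gi_bleed,   base: 15,     low: 13,     high: 18,     dist: uniform,   units: days}
  # -- utilities and disutilities --
  - {name: u_dm,                 base: 0.876,  low: 0.701,  high: 1.0,    dist: uniform,   units: utility}
  - {name: du_gi_bleed,          base: 0.25,   low: 0.188,  high: 0.313,  dist: uniform,   units: disutility}
  - {name: du_post_mi,           base: 0.139,  low: 0.111,  high: 0.167,  dist: uniform,   units: disutility}
  - {name: du_post_stroke,       base: 0.215,  low: 0.172,  high: 0.258,  dist: uniform,   units: disutility}
  - {name: du_aspirin,           base: 0.001,  low: 0.0008, high: 0.0012, dist: uniform,   units: disutility}
  # -- costs (2019 USD) --
  - {name: cost_aspirin_month,   base: 2.4,    low: 1.9,    high: 2.9,    dist: lognormal, units: USD per month}
  - {name: cost_gi_bleed,        base: 3443,   low: 2754,   high: 4132,   dist: lognormal, units: USD per event}
  - {name: cost_mi,              base: 4346,   low: 3477,   high: 5216,   dist: lognormal, units: USD per event}
  - {name: cost_stroke,          base: 1508,   low: 1446,   high: 2860,   dist: lognormal, units: USD per event}
  - {name: cost_post_mi_year,    base: 500,    low: 317,    high: 683,    dist: lognormal, units: USD per year}
  - {name: cost_post_stroke_year, base: 556,   low: 490,    high: 909,    dist: lognormal, units: USD per year}
  # -- analysis settings (never sampled) --
  - {name: discount_rate,        base: 0.03,   low: 0.03,   high: 0.03,   dist: fixed,     units: annual rate}
  - {name: wtp,                  base: 30000,  low: 30000,  high: 30000,  dist: fixed,     units: USD per QALY}
  - {name: horizon,              base: 40,     low: 40,     high: 40,     dist: fixed,     units: yearly cycles}
  - {name: start_age,            base: 60,     low: 60,     high: 60,     dist: fixed,     units: years}
# Age-specific annual all-cause death probability (2017 life table,
# diabetes cohort). The last band is open-ended.
mortality:
  - {age_lo: 60, age_hi: 64, p: 0.0133}
  - {age_lo: 65, age_hi: 69, p: 0.0234}
  - {age_lo: 70, age_hi: 74, p: 0.0356}
  - {age_lo: 75, age_hi: 79, p: 0.0529}
  - {age_lo: 80, age_hi: 84, p: 0.1159}
  - {age_lo: 85, age_hi: .inf, p: 0.2263}
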