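# shared constants (defined first in collation order)

DAYS_PER_YEAR <- 365.25

SLOPE_CLASSES <- c("improved", "stable", "declining")

COMORBIDITY_FLAGS <- c("diabetes", "hypertension", "cardiovascular_disease",
                       "hyperlipidemia", "peripheral_artery_disease",
                       "cerebrovascular_disease", "chronic_lung_disease",
                       "hepatitis_c", "hiv", "dementia")

PHENOTYPE_LEVELS <- c("HIPT", "IIMNT", "LIFNT", "HIFNT")

DEFAULT_ADJUSTMENT <- c("age_at_t0", "race", "sex", COMORBIDITY_FLAGS, "t0_egfr")
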