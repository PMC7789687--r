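# Variable registry for the synthetic cohort. Names are fixed: the imputation
# presets, the report writers and the CSV reader all key on them.

PHQ_ITEMS <- paste0("phq", 1:9)
PCL_ITEMS <- paste0("pcl", 1:17)
PF_ITEMS  <- paste0("pf", 1:10)
ALC_ITEMS <- paste0("alc", 1:5)
DEMO_VARS <- c("sex", "age_group", "race_eth", "marital", "education")
WAVES     <- c("W1", "W2")

SMOKING_LEVELS <- c("never", "former", "current")
# sleep bands follow National Sleep Foundation style grouping: <=5h, 6h, 7-9h, >=10h
SLEEP_LEVELS   <- c("le5", "h6", "h7to9", "ge10")
SLEEP_REF      <- "h7to9"

DEMO_LEVELS <- list(
  sex       = c("male", "female"),
  age_group = c("<25", "25-34", "35-44", "45+"),
  race_eth  = c("white", "black", "hispanic", "other"),
  marital   = c("married", "never_married", "formerly_married"),
  education = c("high_school", "some_college", "college_plus")
)

# DSM-IV PCL-C symptom clusters: items 1-5 intrusion, 6-12 avoidance/numbing,
# 13-17 hyperarousal.
PCL_INTRUSION   <- 1:5
PCL_AVOIDANCE   <- 6:12
PCL_HYPERAROUSAL <- 13:17

# factor-valued cohort columns and their canonical levels (used when reading
# a cohort back from CSV)
cohort_factor_levels <- function() {
  c(DEMO_LEVELS, list(smoking = SMOKING_LEVELS, sleep_cat = SLEEP_LEVELS))
}
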