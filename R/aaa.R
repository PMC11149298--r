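## Package-wide constants (loaded first).

## The 13 canonical model variables.
CANONICAL_VARS <- c(
  "creatinine", "urine_output", "hematocrit", "hemoglobin", "bicarbonate",
  "bun", "chloride", "glucose", "heart_rate", "platelets", "potassium",
  "sodium", "wbc"
)

## Event-marker rows allowed in an event table besides the 13 variables.
EVENT_MARKERS <- c("rrt")

## Endpoint taxonomy.
PAKI3_CLASSES <- c("transient", "T72", "D48", "RRT24")

## NA padding between concatenated stays; also the largest rolling window.
PAD_HOURS <- 48L
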