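## Constants shared across modules (file named to load first).

# Bottom-level ATC code: anatomical letter, 2 digits, 2 letters, 2 digits.
ATC_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
# ICPC-2 rubric: chapter letter + 2 digits.
ICPC2_PATTERN <- "^[A-Z][0-9]{2}$"
# GTIN: 8-14 digits.
GTIN_PATTERN <- "^[0-9]{8,14}$"

PIM_LIST_IDS <- c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7")
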