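## drug_knowledge: GTIN-keyed product facts (package size, unit strength,
## typical daily dose) supporting dose and duration-of-use semantics.

PRODUCT_COLS <- c("gtin", "atc", "package_units", "unit_strength_mg",
                  "typical_daily_dose_units")

#' Validate a drug-product table
#'
#' @param products data.frame with columns `gtin`, `atc`, `package_units`,
#'   `unit_strength_mg`, `typical_daily_dose_units`.
#' @return The table as a keyed data.table.
#' @export
pim_products <- function(products) {
  products <- as.data.frame(products)
  missing_cols <- setdiff(PRODUCT_COLS, names(products))
  if (length(missing_cols)) {
    pim_stop(paste("product table lacks column(s):",
                   paste(missing_cols, collapse = ", ")), "pim_validation_error")
  }
  dt <- data.table::as.data.table(products[, PRODUCT_COLS])
  dt[, `:=`(gtin = as.character(gtin), atc = as.character(atc),
            package_units = as.numeric(package_units),
            unit_strength_mg = as.numeric(unit_strength_mg),
            typical_daily_dose_units = as.numeric(typical_daily_dose_units))]
  ok <- with(dt, is_gtin(gtin) & is_atc(atc) & package_units >= 1 &
               unit_strength_mg > 0 & typical_daily_dose_units > 0)
  if (any(!ok)) {
    pim_stop(sprintf("invalid product row(s): %s",
                     paste(which(!ok), collapse = ", ")),
             "pim_validation_error")
  }
  if (anyDuplicated(dt$gtin)) {
    pim_stop("duplicate gtin in product table", "pim_validation_error")
  }
  data.table::setkey(dt, gtin)
  dt
}

#' Read a product table from CSV
#'
#' Expected header: `gtin,atc,package_units,unit_strength_mg,typical_daily_dose_units`.
#'
#' @param path CSV file path.
#' @return A validated product data.table.
#' @export
read_products <- function(path) {
  if (!file.exists(path)) {
    pim_stop(paste("product file not found:", path), "pim_io_error")
  }
  pim_products(utils::read.csv(path, colClasses = "character"))
}

#' Typical daily dose of a prescription, in mg/day
#'
#' `unit_strength_mg * typical_daily_dose_units` for the prescription's GTIN.
#' `NA` when the GTIN is missing or unknown; dose-conditioned criteria then
#' never fire (missing data are non-triggering).
#'
#' @param gtin character vector of GTINs (may contain `NA`).
#' @param products validated product table ([pim_products()]).
#' @return numeric vector of mg/day, `NA` where undefined.
#' @export
daily_dose_mg <- function(gtin, products) {
  m <- match(as.character(gtin), products$gtin)
  products$unit_strength_mg[m] * products$typical_daily_dose_units[m]
}

#' Days of supply covered by one package
#'
#' `ceiling(package_units / typical_daily_dose_units)` for the prescription's
#' GTIN; `default_days` when the GTIN is missing or unknown. Every known
#' product covers at least 1 day.
#'
#' @param gtin character vector of GTINs (may contain `NA`).
#' @param products validated product table.
#' @param default_days coverage assumed for unknown GTINs (default 30).
#' @return integer vector of days.
#' @export
coverage_days <- function(gtin, products, default_days = 30) {
  m <- match(as.character(gtin), products$gtin)
  d <- as.integer(ceiling(products$package_units[m] /
                            products$typical_daily_dose_units[m]))
  d[is.na(d)] <- as.integer(default_days)
  d
}

#' Built-in synthetic product table
#'
#' A synthetic GTIN registry covering every substance used by the shipped
#' demo rule file plus common background medication. GTINs are fabricated
#' (prefix 7680...), package sizes and strengths are plausible but invented;
#' this is a stand-in for national registry data, suitable for synthetic
#' cohorts and tests only.
#'
#' @return A validated product data.table.
#' @export
demo_products <- function() {
  spec <- rbind(
    # atc, strength mg, units/package, units/day
    c("A02BC01", 20, 30, 1),      # omeprazole
    c("A02BC02", 20, 30, 1),      # pantoprazole
    c("A02BC02", 40, 30, 1),
    c("A02BC05", 40, 30, 1),      # esomeprazole
    c("N05BA06", 1, 50, 1),       # lorazepam
    c("N05BA06", 2.5, 30, 1),
    c("N05BA08", 3, 30, 1),       # bromazepam (== PRISCUS demo threshold)
    c("N05BA08", 6, 30, 1),
    c("N05BB01", 25, 30, 1),      # hydroxyzine
    c("N05CF01", 3.75, 30, 1),    # zopiclone (== NORGEP demo threshold)
    c("N05CF01", 7.5, 30, 1),
    c("N05CF02", 5, 30, 1),       # zolpidem (== PRISCUS/EU(7) demo threshold)
    c("N05CF02", 10, 30, 1),      # (== Laroche demo threshold)
    c("N05CF02", 12.5, 30, 1),
    c("M01AE01", 400, 30, 3),     # ibuprofen
    c("M01AE01", 600, 30, 3),
    c("M01AB05", 50, 30, 2),      # diclofenac
    c("M01AE52", 500, 20, 2),     # naproxen + esomeprazole
    c("M01AH05", 90, 30, 1),      # etoricoxib
    c("M01AB11", 60, 30, 2),      # acemetacin
    c("M01AX25", 800, 30, 1),     # chondroitin sulfate
    c("N06AA06", 25, 30, 1),      # trimipramine
    c("N06AA09", 25, 30, 1),      # amitriptyline
    c("N06AX05", 100, 30, 1),     # trazodone
    c("N06AX11", 30, 30, 1),      # mirtazapine
    c("N02AA01", 10, 30, 2),      # morphine
    c("N02AA55", 10, 30, 2),      # oxycodone + naloxone
    c("N02AX02", 50, 30, 2),      # tramadol
    c("N02AJ13", 37.5, 30, 3),    # tramadol + paracetamol
    c("N05AH04", 25, 30, 1),      # quetiapine
    c("J01XE01", 100, 20, 2),     # nitrofurantoin
    c("N03AX16", 75, 56, 2),      # pregabalin
    c("N03AX12", 300, 90, 3),     # gabapentin
    c("N06DX02", 120, 30, 1),     # ginkgo folium
    c("N06BX03", 800, 60, 2),     # piracetam
    c("A06AB08", 7.5, 30, 1),     # sodium picosulfate
    c("A06AA01", 15, 30, 1),      # liquid paraffin
    c("A07DA03", 2, 60, 2),       # loperamide
    c("A10BB12", 2, 30, 1),       # glimepiride
    c("N04BC05", 0.18, 30, 1),    # pramipexole
    c("R06AA09", 25, 20, 1),      # doxylamine
    c("B01AA03", 3, 30, 1),       # warfarin
    c("B01AF01", 20, 28, 1),      # rivaroxaban
    # background (never a PIM trigger in the demo rules)
    c("C07AB02", 50, 30, 1),      # metoprolol
    c("C09AA05", 5, 28, 1),       # ramipril
    c("C10AA05", 20, 30, 1),      # atorvastatin
    c("B01AC06", 100, 30, 1),     # acetylsalicylic acid
    c("A10BA02", 500, 60, 2),     # metformin
    c("C03CA01", 40, 30, 1),      # furosemide
    c("C08CA01", 5, 30, 1),       # amlodipine
    c("N02BE01", 500, 20, 3),     # paracetamol
    c("H03AA01", 0.1, 100, 1),    # levothyroxine
    c("R03AC02", 0.1, 200, 2)     # salbutamol
  )
  df <- data.frame(
    atc = spec[, 1],
    unit_strength_mg = as.numeric(spec[, 2]),
    package_units = as.numeric(spec[, 3]),
    typical_daily_dose_units = as.numeric(spec[, 4]),
    stringsAsFactors = FALSE
  )
  df$gtin <- sprintf("76809%08d", seq_len(nrow(df)))
  pim_products(df[, PRODUCT_COLS])
}

#' Substance labels for ATC codes used in the demo material
#'
#' @return named character vector (name = ATC code, value = substance label).
#' @export
atc_labels <- function() {
  c(
    A02BC01 = "Omeprazole", A02BC02 = "Pantoprazole", A02BC05 = "Esomeprazole",
    N05BA06 = "Lorazepam", N05BA08 = "Bromazepam", N05BB01 = "Hydroxyzine",
    N05CF01 = "Zopiclone", N05CF02 = "Zolpidem",
    M01AE01 = "Ibuprofen", M01AB05 = "Diclofenac",
    M01AE52 = "Naproxen + esomeprazole", M01AH05 = "Etoricoxib",
    M01AB11 = "Acemetacin", M01AX25 = "Chondroitin sulfate",
    N06AA06 = "Trimipramine", N06AA09 = "Amitriptyline",
    N06AX05 = "Trazodone", N06AX11 = "Mirtazapine",
    N02AA01 = "Morphine", N02AA55 = "Oxycodone + naloxone",
    N02AX02 = "Tramadol", N02AJ13 = "Tramadol + paracetamol",
    N05AH04 = "Quetiapine", J01XE01 = "Nitrofurantoin",
    N03AX16 = "Pregabalin", N03AX12 = "Gabapentin",
    N06DX02 = "Ginkgo folium", N06BX03 = "Piracetam",
    A06AB08 = "Sodium picosulfate", A06AA01 = "Liquid paraffin",
    A07DA03 = "Loperamide", A10BB12 = "Glimepiride",
    N04BC05 = "Pramipexole", R06AA09 = "Doxylamine",
    B01AA03 = "Warfarin", B01AF01 = "Rivaroxaban",
    C07AB02 = "Metoprolol", C09AA05 = "Ramipril", C10AA05 = "Atorvastatin",
    B01AC06 = "Acetylsalicylic acid", A10BA02 = "Metformin",
    C03CA01 = "Furosemide", C08CA01 = "Amlodipine", N02BE01 = "Paracetamol",
    H03AA01 = "Levothyroxine", R03AC02 = "Salbutamol"
  )
}
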