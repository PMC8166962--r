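# Small in-code fixtures shared across test files.

# Hand-built four-table dataset: 5 reports, two drugs, one focal PT.
tiny_dataset <- function() {
  demo <- data.frame(
    case_id = paste0("C", 1:5),
    sex = c("male", "female", "female", "male", "unknown"),
    age_band = c("60s", "70s", "50s", "60s", "40s"),
    report_period = c("2019", "2019", "2020", "2020", "2020"),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    case_id = c("C1", "C1", "C2", "C3", "C4", "C4"),
    drug_seq = c(1L, 2L, 1L, 1L, 1L, 2L),
    product_name = c("oxaliplatin", "oxaliplatin", "oxaliplatin",
                     "paclitaxel", "paclitaxel", "bevacizumab"),
    role_code = c("suspected", "suspected", "suspected", "suspected",
                  "concomitant", "suspected"),
    start_date = c("20190110", "20190301", "20190601", "202003",
                   "20200401", "20200105"),
    end_date = c("", "", "20190830", "", "", ""),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    case_id = c("C1", "C2", "C3", "C4", "C5"),
    pt_code = c(10029331L, 10029331L, 10029331L, 10019211L, 10029331L),
    pt_name = c(rep("peripheral neuropathy", 3), "headache",
                "peripheral neuropathy"),
    onset_date = c("20190124", "20190815", "20200410", "20200501",
                   "20200301"),
    outcome = c("recovered", "not_recovered", "improved", "recovered",
                "unknown"),
    stringsAsFactors = FALSE)
  hist <- data.frame(
    case_id = c("C1", "C2"),
    disease_name = c("colorectal cancer", "gastric cancer"),
    stringsAsFactors = FALSE)
  new_srs_dataset(demo, drug, reac, hist)
}

tiny_vocab <- function() {
  data.frame(
    product_name = c("oxaliplatin", "paclitaxel", "nab-paclitaxel",
                     "bevacizumab"),
    canonical_name = c("oxaliplatin", "sb-paclitaxel", "nab-paclitaxel",
                       "bevacizumab"),
    atc_code = c("L01XA03", "L01CD01", "L01CD01", "L01XC07"),
    stringsAsFactors = FALSE)
}

FOCAL_PT <- 10029331L

# Default single-drug generator config used by several property tests.
one_drug_config <- function(n = 50000L, multiplier = 26, seed = 1L,
                            exposure = 0.014, background = 0.003,
                            alpha = 50, beta = 0.8, ...) {
  sim_config(n, background,
             drugs = list(drug_spec("drugA", "L01XX99", exposure, multiplier,
                                    alpha, beta)),
             seed = seed, ...)
}

# Analysis set straight from a generated dataset.
sim_analysis_set <- function(cfg) {
  ds <- generate_dataset(cfg)
  assemble_analysis_set(ds, sim_vocabulary(cfg), cfg$pt_code)
}
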