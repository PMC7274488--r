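# Shared builders for the test suite.

fixture_path <- function(name) {
  system.file("extdata", name, package = "thyromr", mustWork = TRUE)
}

load_phenotyping_fixture <- function() {
  list(
    participants = read.csv(fixture_path("synthetic_fixture_participants.csv"),
                            stringsAsFactors = FALSE),
    diagnoses = read.csv(fixture_path("synthetic_fixture_diagnoses.csv"),
                         stringsAsFactors = FALSE)
  )
}

# Summary-stat rows with chosen per-variant Wald ratios and weights:
# beta_exp = 1 so ratio = beta_out and weight = 1 / se_out^2.
rows_with_ratios <- function(ratios, weights) {
  out <- data.frame(
    variant_id = sprintf("v%02d", seq_along(ratios)),
    effect_allele = "A", other_allele = "G",
    beta_exp = 1, se_exp = 1e-6,
    beta_out = ratios, se_out = 1 / sqrt(weights),
    harmonized = TRUE, stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

# Small strong-instrument panel for simulation-heavy tests.
test_panel <- function(m = 50, seed = 42) {
  variant_panel("BMI", n_variants = m, seed = seed)
}

status_of <- function(assignment, id) {
  assignment$status[assignment$participant_id == id]
}

reason_of <- function(assignment, id) {
  assignment$exclusion_reason[assignment$participant_id == id]
}
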