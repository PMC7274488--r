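#' Construct and validate a table of instrument variants
#'
#' A variant-weight table holds one row per genetic instrument: its
#' identifier, effect and other allele, per-allele effect on the trait
#' (standard-deviation units for continuous traits, log-odds for binary
#' liabilities), and effect-allele frequency. Weights are taken from
#' external discovery GWAS and are inputs, never estimated here.
#'
#' @param variant_id Character vector of unique variant identifiers.
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @param beta Per-allele effect of the effect allele on the trait.
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param trait Trait label (e.g. `"BMI"`, `"T2DM"`, `"FA"`); recycled.
#' @return A `data.frame` of class `variant_spec` with the columns above.
#' @examples
#' variant_spec(c("rs1", "rs2"), c("A", "G"), c("G", "T"),
#'              beta = c(0.03, 0.05), eaf = c(0.4, 0.2), trait = "BMI")
#' @export
variant_spec <- function(variant_id, effect_allele, other_allele, beta, eaf,
                         trait = "trait") {
  spec <- data.frame(
    variant_id = as.character(variant_id),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta = as.numeric(beta),
    eaf = as.numeric(eaf),
    trait = as.character(trait),
    stringsAsFactors = FALSE
  )
  validate_variant_spec(spec)
}

validate_variant_spec <- function(spec) {
  needed <- c("variant_id", "effect_allele", "other_allele", "beta", "eaf",
              "trait")
  assert_that(all(needed %in% names(spec)),
              "variant spec lacks columns: %s",
              paste(setdiff(needed, names(spec)), collapse = ", "))
  assert_that(!anyDuplicated(spec$variant_id),
              "duplicated variant ids: %s",
              paste(unique(spec$variant_id[duplicated(spec$variant_id)]),
                    collapse = ", "))
  assert_that(all(spec$eaf > 0 & spec$eaf < 1),
              "effect-allele frequencies must lie strictly in (0, 1)")
  bases <- c("A", "C", "G", "T")
  assert_that(all(spec$effect_allele %in% bases) &&
                all(spec$other_allele %in% bases),
              "alleles must be single bases A/C/G/T")
  assert_that(all(spec$effect_allele != spec$other_allele),
              "effect and other allele must differ for every variant")
  class(spec) <- c("variant_spec", "data.frame")
  spec
}

#' Default instrument panels for the study traits
#'
#' Generates a reproducible panel of independent biallelic variants for a
#' trait, mirroring the instrument counts used in the analyses: 73 variants
#' for BMI, 14 for favourable adiposity, and intermediate counts for the
#' other traits. Discovery GWAS weights and frequencies are not public
#' inputs here, so frequencies are drawn uniform on (0.05, 0.95) and
#' per-allele weights uniform on a range sized so the panel explains
#' roughly 1.5% of exposure variance — enough for a strong instrument
#' (first-stage F well above 10) at biobank sample sizes.
#'
#' @param trait One of `"BMI"`, `"WHR"`, `"adjWHR"`, `"T2DM"`, `"FA"`.
#' @param n_variants Number of variants; defaults to the trait's panel size.
#' @param seed Integer seed for the draw.
#' @return A [variant_spec()] table.
#' @export
variant_panel <- function(trait = c("BMI", "WHR", "adjWHR", "T2DM", "FA"),
                          n_variants = NULL, seed = 1L) {
  trait <- match.arg(trait)
  defaults <- c(BMI = 73L, WHR = 48L, adjWHR = 48L, T2DM = 38L, FA = 14L)
  if (is.null(n_variants)) n_variants <- defaults[[trait]]
  assert_that(is_count(n_variants) && n_variants >= 1, "n_variants must be >= 1")
  draws <- with_seed(seed, {
    list(eaf = stats::runif(n_variants, 0.05, 0.95),
         # beta range scaled with 1/sqrt(n_variants) so panel variance
         # sum(beta^2 * 2p(1-p)) is ~1.5% regardless of panel size
         beta = stats::runif(n_variants,
                             0.010 * sqrt(73 / n_variants),
                             0.035 * sqrt(73 / n_variants)),
         alleles = t(replicate(n_variants, sample(c("A", "C", "G", "T"), 2))))
  })
  eaf <- draws$eaf; beta <- draws$beta; alleles <- draws$alleles
  variant_spec(
    variant_id = sprintf("rs%s_%03d", tolower(trait), seq_len(n_variants)),
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    beta = beta, eaf = eaf, trait = trait
  )
}

#' Orient variant weights to the trait-increasing allele
#'
#' Rows with a negative weight are flipped: alleles swapped, the weight
#' negated, and the frequency complemented. Genotype dosages for flipped
#' variants must be re-coded as `2 - dosage`; [compute_weighted_grs()] does
#' this when given the flip map returned here.
#'
#' @param spec A [variant_spec()] table.
#' @return The spec with all betas positive and a logical `flipped` column.
#' @export
orient_to_increasing_allele <- function(spec) {
  spec <- validate_variant_spec(spec)
  flip <- spec$beta < 0
  if (any(flip)) {
    ea <- spec$effect_allele[flip]
    spec$effect_allele[flip] <- spec$other_allele[flip]
    spec$other_allele[flip] <- ea
    spec$beta[flip] <- -spec$beta[flip]
    spec$eaf[flip] <- 1 - spec$eaf[flip]
  }
  spec$flipped <- flip
  assert_that(all(spec$beta > 0),
              "zero-weight variants cannot be oriented; drop them upstream")
  spec
}

#' Read / write variant-weight tables
#'
#' Tab-delimited text with columns `variant_id`, `effect_allele`,
#' `other_allele`, `beta`, `eaf`, `trait`.
#'
#' @param path File path.
#' @param spec A [variant_spec()] table (for writing).
#' @return `read_variant_weights()` returns a validated [variant_spec()].
#' @export
read_variant_weights <- function(path) {
  validate_variant_spec(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_variant_weights
#' @export
write_variant_weights <- function(spec, path) {
  utils::write.table(as.data.frame(spec)[c("variant_id", "effect_allele",
                                           "other_allele", "beta", "eaf",
                                           "trait")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
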