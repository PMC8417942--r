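#' Default per-country cohort structure
#'
#' Demographic skeleton of a 12-country healthy-adult gut-microbiome cohort
#' assembled from public repositories: very unbalanced country groups
#' (20 to 1,822 samples), per-country age means and SDs, sex ratios and BMI
#' category frequencies including missingness. Used as the default
#' `country_params` of [synthetic_spec()].
#'
#' @return A data.frame with one row per country: `country`, `n`,
#'   `age_mean`, `age_sd`, `p_female`, `p_male`, `p_sex_missing`, and BMI
#'   category probabilities `p_underweight`, `p_normal`, `p_overweight`,
#'   `p_obese`, `p_bmi_missing`.
#' @export
default_country_params <- function() {
  d <- data.frame(
    country = c("Brazil", "Canada", "China", "Denmark", "France", "Germany",
                "Italy", "NewZealand", "Spain", "Tanzania", "UK", "USA"),
    n = c(20L, 1269L, 171L, 107L, 465L, 70L, 40L, 131L, 47L, 22L, 273L, 1822L),
    age_mean = c(30.1, 25.9, 43.3, 55.4, 62.0, 38.1, 39.3, 36.9, 40.9, 36.1, 51.3, 41.7),
    age_sd = c(5.0, 5.1, 12.4, 8.1, 10.5, 8.3, 13.6, 12.6, 14.5, 13.3, 13.2, 16.7),
    female = c(18, 659, 81, 73, 249, 0, 26, 82, 31, 8, 122, 847),
    male = c(2, 610, 90, 34, 216, 70, 14, 49, 16, 14, 149, 965),
    sex_missing = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 10),
    underweight = c(0, 0, 8, 0, 4, 0, 1, 0, 0, 0, 8, 38),
    normal = c(15, 973, 33, 1, 228, 29, 26, 101, 2, 0, 180, 1059),
    overweight = c(4, 296, 32, 0, 182, 29, 2, 30, 0, 0, 69, 495),
    obese = c(1, 0, 0, 0, 38, 12, 0, 0, 0, 0, 16, 95),
    bmi_missing = c(0, 0, 98, 106, 13, 0, 11, 0, 45, 22, 0, 135),
    stringsAsFactors = FALSE
  )
  out <- d[, c("country", "n", "age_mean", "age_sd")]
  out$p_female <- d$female / d$n
  out$p_male <- d$male / d$n
  out$p_sex_missing <- d$sex_missing / d$n
  out$p_underweight <- d$underweight / d$n
  out$p_normal <- d$normal / d$n
  out$p_overweight <- d$overweight / d$n
  out$p_obese <- d$obese / d$n
  out$p_bmi_missing <- d$bmi_missing / d$n
  out
}

#' Specification for a synthetic microbiome cohort
#'
#' Describes a multi-country, multi-study cohort: unbalanced country groups,
#' study-specific taxon panels (taxa a study did not measure are structural
#' zeros for all of its samples), Dirichlet compositional abundances with an
#' optional power-law concentration profile, and planted multiplicative
#' country-taxon effects acting on the Dirichlet concentrations.
#'
#' @param country_params Per-country data.frame in the layout of
#'   [default_country_params()]; its `n` column gives `samples_per_country`.
#' @param n_taxa Number of genera (default 1341).
#' @param n_studies Number of studies; each country is served by 1-3
#'   country-exclusive studies, so `n_countries <= n_studies <=
#'   3 * n_countries` (default 19).
#' @param panel_fraction Fraction of taxa measured by each study, in (0, 1].
#' @param base_concentration Dirichlet concentration vector of length
#'   `n_taxa`; the default `0.5 * rank^-0.7` yields the heavy dominance and
#'   many near-zero entries typical of genus tables.
#' @param taxon_dispersion Standard deviation of the lognormal noise
#'   multiplying each sample's concentration vector taxon-wise (default
#'   0.5). Plain Dirichlet sampling understates the taxon-level variance of
#'   real genus tables and couples all taxa through a single gradient; the
#'   lognormal perturbation adds the overdispersion and decorrelation seen
#'   in real data. 0 disables it.
#' @param planted_effects data.frame with columns `country`, `taxon`
#'   (taxon identifier), `effect` (multiplier >= 1 applied to that taxon's
#'   concentration for samples of that country). Default: none.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(country_params = default_country_params(),
                           n_taxa = 1341L,
                           n_studies = 19L,
                           panel_fraction = 0.6,
                           base_concentration = NULL,
                           taxon_dispersion = 0.5,
                           planted_effects = NULL,
                           seed = 1L) {
  stopifnot(taxon_dispersion >= 0)
  stopifnot(is.data.frame(country_params), nrow(country_params) >= 1,
            all(c("country", "n", "age_mean", "age_sd") %in% colnames(country_params)))
  n_countries <- nrow(country_params)
  if (anyDuplicated(country_params$country)) stop("duplicate country names")
  if (n_studies < n_countries || n_studies > 3L * n_countries)
    stop("n_studies must be between n_countries and 3 * n_countries")
  if (panel_fraction <= 0 || panel_fraction > 1) stop("panel_fraction must be in (0, 1]")
  if (is.null(base_concentration))
    base_concentration <- 0.5 * seq_len(n_taxa)^(-0.7)
  if (length(base_concentration) != n_taxa || any(base_concentration <= 0))
    stop("base_concentration must be a positive vector of length n_taxa")
  probs <- country_params[, grep("^p_", colnames(country_params)), drop = FALSE]
  if (ncol(probs) && any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sex_sum <- country_params$p_female + country_params$p_male + country_params$p_sex_missing
  bmi_sum <- country_params$p_underweight + country_params$p_normal +
    country_params$p_overweight + country_params$p_obese + country_params$p_bmi_missing
  if (any(abs(sex_sum - 1) > 1e-8) || any(abs(bmi_sum - 1) > 1e-8))
    stop("per-country sex and BMI probabilities must each sum to 1")
  if (is.null(planted_effects))
    planted_effects <- data.frame(country = character(), taxon = character(),
                                  effect = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("country", "taxon", "effect") %in% colnames(planted_effects)))
  taxa <- paste0("g", seq_len(n_taxa))
  bad_cty <- setdiff(planted_effects$country, country_params$country)
  if (length(bad_cty)) stop("planted effect references unknown country: ",
                            paste(bad_cty, collapse = ", "))
  bad_tax <- setdiff(planted_effects$taxon, taxa)
  if (length(bad_tax)) stop("planted effect references unknown taxon: ",
                            paste(bad_tax, collapse = ", "))
  if (nrow(planted_effects) && any(planted_effects$effect < 1))
    stop("planted effect sizes must be >= 1")
  structure(list(country_params = country_params,
                 n_taxa = as.integer(n_taxa),
                 n_studies = as.integer(n_studies),
                 panel_fraction = panel_fraction,
                 base_concentration = base_concentration,
                 taxon_dispersion = taxon_dispersion,
                 planted_effects = planted_effects,
                 taxa = taxa,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic cohort spec:", nrow(x$country_params), "countries,",
      sum(x$country_params$n), "samples,", x$n_taxa, "taxa,",
      x$n_studies, "studies,", nrow(x$planted_effects), "planted effect(s)\n")
  invisible(x)
}

rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # tiny shapes can underflow every gamma draw to zero
    g[] <- 1
    s <- length(g)
  }
  g / s
}

generate_internal <- function(spec, studies_by_country) {
  cp <- spec$country_params
  n_countries <- nrow(cp)
  taxa <- spec$taxa

  # country -> study assignment
  study_ids <- sprintf("ST%02d", seq_len(spec$n_studies))
  if (studies_by_country) {
    base <- seq_len(n_countries)
    extra <- spec$n_studies - n_countries
    slots <- rep(base, 2L) # each country may host up to 2 extra studies
    owner <- c(base, if (extra > 0) sample(slots, extra) else integer(0))
  } else {
    owner <- rep(NA_integer_, spec$n_studies)
  }

  # fixed per-study taxon panel
  panel_size <- max(1L, ceiling(spec$panel_fraction * spec$n_taxa))
  panels <- lapply(seq_len(spec$n_studies), function(i) {
    if (panel_size >= spec$n_taxa) seq_len(spec$n_taxa)
    else sort(sample.int(spec$n_taxa, panel_size))
  })

  n_total <- sum(cp$n)
  sample_ids <- sprintf("S%05d", seq_len(n_total))
  country_of <- rep(cp$country, cp$n)
  country_idx <- rep(seq_len(n_countries), cp$n)

  # per-sample study: country-exclusive pool, or the whole pool for the
  # exchangeable null
  study_of <- integer(n_total)
  for (i in seq_len(n_total)) {
    pool <- if (studies_by_country) which(owner == country_idx[i]) else seq_len(spec$n_studies)
    study_of[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }

  # per-country concentration vectors with planted effects applied
  alpha_by_country <- matrix(rep(spec$base_concentration, n_countries),
                             nrow = n_countries, byrow = TRUE)
  pe <- spec$planted_effects
  if (nrow(pe)) {
    for (k in seq_len(nrow(pe))) {
      ci <- match(pe$country[k], cp$country)
      ti <- match(pe$taxon[k], taxa)
      alpha_by_country[ci, ti] <- alpha_by_country[ci, ti] * pe$effect[k]
    }
  }

  values <- matrix(0, nrow = n_total, ncol = spec$n_taxa,
                   dimnames = list(sample_ids, taxa))
  for (i in seq_len(n_total)) {
    a <- alpha_by_country[country_idx[i], ]
    if (spec$taxon_dispersion > 0)
      a <- a * stats::rlnorm(spec$n_taxa, 0, spec$taxon_dispersion)
    comp <- rdirichlet_row(a)
    panel <- panels[[study_of[i]]]
    row <- numeric(spec$n_taxa)
    row[panel] <- comp[panel]
    s <- sum(row)
    if (s == 0) row[panel] <- 1 / length(panel) else row <- row / s
    values[i, ] <- row
  }

  # host metadata from the per-country distributions
  age <- numeric(n_total)
  sex <- character(n_total)
  bmi_value <- numeric(n_total)
  bmi_ranges <- list(underweight = c(16, 18.5), normal = c(18.5, 25),
                     overweight = c(25, 30), obese = c(30, 40))
  for (i in seq_len(n_total)) {
    ci <- country_idx[i]
    a <- stats::rnorm(1L, cp$age_mean[ci], cp$age_sd[ci])
    age[i] <- max(18, a)
    sex[i] <- sample(c("Female", "Male", "Missing"), 1L,
                     prob = c(cp$p_female[ci], cp$p_male[ci], cp$p_sex_missing[ci]))
    cat_i <- sample(c("underweight", "normal", "overweight", "obese", "Missing"), 1L,
                    prob = c(cp$p_underweight[ci], cp$p_normal[ci],
                             cp$p_overweight[ci], cp$p_obese[ci], cp$p_bmi_missing[ci]))
    bmi_value[i] <- if (cat_i == "Missing") NA_real_ else
      stats::runif(1L, bmi_ranges[[cat_i]][1L], bmi_ranges[[cat_i]][2L])
  }
  metadata <- data.frame(
    sample_id = sample_ids,
    country = country_of,
    study_id = study_ids[study_of],
    age = round(age, 1),
    sex = sex,
    bmi_value = bmi_value,
    bmi_category = bin_bmi(bmi_value),
    stringsAsFactors = FALSE
  )
  list(abundance = values, metadata = metadata)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [synthetic_spec()]: each country is served by
#' 1-3 country-exclusive studies; each study measures a fixed random panel
#' of `panel_fraction * n_taxa` taxa (off-panel taxa are structural zeros);
#' each sample's composition is Dirichlet with the country's concentration
#' vector (base concentrations times any planted effects), restricted to the
#' study panel and renormalized; host metadata (age, sex, BMI) follow the
#' per-country distributions of the spec. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `abundance` (row-normalized matrix, samples x taxa)
#'   and `metadata` (data.frame in the [load_metadata()] layout).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_internal(spec, studies_by_country = TRUE))
}

#' Generate an exchangeable-null cohort
#'
#' Like [generate_dataset()] but with country labels assigned independently
#' of composition: no planted effects are allowed, and samples draw their
#' study (hence taxon panel) uniformly from the full study pool rather than
#' from country-exclusive studies. Under this null the country labels are
#' exchangeable with respect to the abundances, which is what type-I-error
#' calibration of the enrichment test requires.
#'
#' @param spec A [synthetic_spec()] with empty `planted_effects`.
#' @return Same structure as [generate_dataset()].
#' @export
null_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (nrow(spec$planted_effects))
    stop("null_dataset requires a spec with no planted effects")
  withr::with_seed(spec$seed, generate_internal(spec, studies_by_country = FALSE))
}

#' Serialize a synthetic spec to a flat JSON config
#'
#' @param spec A [synthetic_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jsonlite::write_json(unclass(spec)[c("country_params", "n_taxa", "n_studies",
                                       "panel_fraction", "base_concentration",
                                       "taxon_dispersion", "planted_effects",
                                       "seed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synthetic spec from its JSON config
#'
#' @param path Path written by [write_synthetic_spec()].
#' @return A validated [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pe <- cfg$planted_effects
  if (is.null(pe) || !NROW(pe))
    pe <- data.frame(country = character(), taxon = character(),
                     effect = numeric(), stringsAsFactors = FALSE)
  synthetic_spec(country_params = as.data.frame(cfg$country_params),
                 n_taxa = cfg$n_taxa, n_studies = cfg$n_studies,
                 panel_fraction = cfg$panel_fraction,
                 base_concentration = cfg$base_concentration,
                 taxon_dispersion = cfg$taxon_dispersion,
                 planted_effects = as.data.frame(pe),
                 seed = cfg$seed)
}

#' Write an abundance matrix in the package's tab-separated layout
#' @param x Abundance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata in the package's tab-separated layout
#' @param metadata Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata[, c("sample_id", "country", "study_id", "age", "sex", "bmi_value")]
  colnames(out)[colnames(out) == "bmi_value"] <- "bmi"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
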