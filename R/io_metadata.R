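#' Read a genus-level abundance table
#'
#' Reads a tab-separated abundance matrix: first row taxon (genus) names,
#' first column sample identifiers, remaining cells non-negative real
#' abundances (relative abundances or raw counts; no rescaling is applied at
#' load time, see [normalize_relative()]).
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @return A numeric matrix, rows = samples, columns = taxa, with unique
#'   dimnames.
#' @seealso [normalize_relative()], [load_metadata()]
#' @export
load_abundance <- function(path) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("abundance table needs a sample-ID column and at least one taxon")
  sample_ids <- as.character(raw[[1L]])
  taxon_ids <- colnames(raw)[-1L]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  dup_t <- unique(taxon_ids[duplicated(taxon_ids)])
  if (length(dup_t)) stop("duplicate taxon identifier(s): ", paste(dup_t, collapse = ", "))
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- list(sample_ids, taxon_ids)
  validate_abundance(values)
  values
}

#' Validate an abundance matrix
#'
#' @param x Numeric matrix, rows = samples, columns = taxa.
#' @return `x` invisibly; errors describe the offending cell or identifier.
#' @export
validate_abundance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("abundance table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table must carry sample and taxon identifiers as dimnames")
  if (anyDuplicated(rownames(x))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate taxon identifiers")
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing abundance at sample '%s', taxon '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  invisible(x)
}

#' Total-sum scale abundances to relative abundances
#'
#' Divides every row with a nonzero total by that total, so each sample sums
#' to 1. All-zero rows are left unchanged and reported with a warning;
#' downstream distance computation rejects them explicitly. The operation is
#' idempotent.
#'
#' @param x Numeric abundance matrix (samples x taxa), non-negative.
#' @return Row-normalized matrix of the same shape.
#' @export
normalize_relative <- function(x) {
  validate_abundance(x)
  totals <- rowSums(x)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero abundance row(s) left unchanged: ",
            paste(rownames(x)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  x / totals
}

#' Read per-sample host metadata
#'
#' Expects a tab-separated file with columns `sample_id`, `country`,
#' `study_id`, `age`, `sex`, `bmi`. Empty strings and `NA` denote missing
#' values. Sex is normalised to `Female` / `Male` / `Missing`; the BMI
#' category is derived from the numeric BMI with [bin_bmi()].
#'
#' @param path Path to the metadata file.
#' @return A data.frame with columns sample_id, country, study_id, age
#'   (numeric, `NA` when missing), sex, bmi_value, bmi_category.
#' @export
load_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("sample_id", "country", "study_id", "age", "sex", "bmi")
  missing_cols <- setdiff(required, colnames(raw))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  sex <- as.character(raw$sex)
  sex[is.na(sex)] <- "Missing"
  bad_sex <- setdiff(unique(sex), c("Female", "Male", "Missing"))
  if (length(bad_sex)) stop("unrecognised sex level(s): ", paste(bad_sex, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(raw$sample_id),
    country = as.character(raw$country),
    study_id = as.character(raw$study_id),
    age = as.numeric(raw$age),
    sex = sex,
    bmi_value = as.numeric(raw$bmi),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$age) & out$age < 0)) stop("negative age in metadata")
  out$bmi_category <- bin_bmi(out$bmi_value)
  out
}

#' Categorize BMI values
#'
#' WHO-convention half-open bins: underweight `[0, 18.5)`, normal
#' `[18.5, 25)`, overweight `[25, 30)`, obese `[30, Inf)`. Missing values map
#' to `"Missing"`.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2), `NA` allowed.
#' @return Character vector of categories.
#' @export
bin_bmi <- function(bmi) {
  if (!is.numeric(bmi)) stop("bmi must be numeric")
  if (any(!is.na(bmi) & bmi <= 0)) stop("non-positive BMI value")
  out <- as.character(cut(bmi, breaks = c(0, 18.5, 25, 30, Inf),
                          labels = c("underweight", "normal", "overweight", "obese"),
                          right = FALSE))
  out[is.na(out)] <- "Missing"
  out
}

#' Drop countries below a minimum sample size
#'
#' Retains every sample whose country has at least `min_n` samples (a country
#' with exactly `min_n` passes; only smaller countries are excluded).
#'
#' @param metadata Metadata data.frame as returned by [load_metadata()].
#' @param min_n Minimum per-country sample count (default 20).
#' @return The filtered metadata data.frame.
#' @export
filter_countries <- function(metadata, min_n = 20L) {
  stopifnot(min_n >= 1)
  counts <- table(metadata$country)
  keep <- names(counts)[counts >= min_n]
  if (!length(keep)) stop("no country passes filter (min_n = ", min_n, ")")
  metadata[metadata$country %in% keep, , drop = FALSE]
}

#' Dummy code categorical metadata
#'
#' One 0/1 indicator column per observed non-missing level of each requested
#' variable. Samples with a missing value get all-zero indicators for that
#' variable, which keeps them in the network while removing them from that
#' variable's enrichment signal.
#'
#' @param metadata Metadata data.frame.
#' @param variables Subset of `c("country", "sex", "bmi_category")`.
#' @return Numeric 0/1 matrix, rows = samples (named by sample_id), columns
#'   named `"<variable>=<level>"`.
#' @export
dummy_code <- function(metadata, variables = c("country", "sex", "bmi_category")) {
  allowed <- c("country", "sex", "bmi_category")
  bad <- setdiff(variables, allowed)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  cols <- list()
  for (v in variables) {
    vals <- as.character(metadata[[v]])
    vals[is.na(vals)] <- "Missing"
    levs <- sort(setdiff(unique(vals), "Missing"))
    for (lev in levs) cols[[paste0(v, "=", lev)]] <- as.numeric(vals == lev)
  }
  out <- do.call(cbind, cols)
  if (is.null(out)) out <- matrix(numeric(0), nrow = nrow(metadata), ncol = 0)
  rownames(out) <- metadata$sample_id
  out
}

#' Summarize a cohort per country
#'
#' Per-country and pooled sample counts, age mean and SD (computed over
#' non-missing ages, reported to 1 decimal), sex counts (Female / Male /
#' Missing) and BMI category counts (including Missing). Mirrors the layout
#' of a demographic summary table, one row per country plus a `Total` row.
#'
#' @param metadata Metadata data.frame.
#' @return A data.frame with columns country, n, age_mean, age_sd,
#'   sex_Female, sex_Male, sex_Missing, bmi_underweight, bmi_normal,
#'   bmi_overweight, bmi_obese, bmi_Missing.
#' @export
cohort_summary <- function(metadata) {
  if (!nrow(metadata)) stop("metadata is empty")
  one <- function(df, label) {
    age <- df$age[!is.na(df$age)]
    data.frame(
      country = label,
      n = nrow(df),
      age_mean = round(mean(age), 1),
      age_sd = round(stats::sd(age), 1),
      sex_Female = sum(df$sex == "Female"),
      sex_Male = sum(df$sex == "Male"),
      sex_Missing = sum(df$sex == "Missing"),
      bmi_underweight = sum(df$bmi_category == "underweight"),
      bmi_normal = sum(df$bmi_category == "normal"),
      bmi_overweight = sum(df$bmi_category == "overweight"),
      bmi_obese = sum(df$bmi_category == "obese"),
      bmi_Missing = sum(df$bmi_category == "Missing"),
      stringsAsFactors = FALSE
    )
  }
  countries <- sort(unique(metadata$country))
  rows <- lapply(countries, function(cty) one(metadata[metadata$country == cty, ], cty))
  out <- do.call(rbind, c(rows, list(one(metadata, "Total"))))
  rownames(out) <- NULL
  out
}

#' Pool per-country summary rows into cohort totals
#'
#' Combines per-country rows of a demographic table (sample size, age mean
#' and SD, level counts) into pooled statistics without access to the
#' underlying per-sample data: the pooled mean is the sample-size weighted
#' mean, and the pooled SD recovers the total sum of squares from the
#' per-group means and SDs,
#' \deqn{SS = \sum_i (n_i - 1) s_i^2 + \sum_i n_i (m_i - \bar m)^2,}
#' so that the pooled SD is \eqn{\sqrt{SS / (N - 1)}}. Count columns are
#' summed.
#'
#' @param summary_table A data.frame with columns `n`, `age_mean`, `age_sd`
#'   and any number of count columns (prefixed `sex_` / `bmi_`), one row per
#'   country (no `Total` row).
#' @return A one-row data.frame in the same layout, `country = "Total"`,
#'   age statistics rounded to 1 decimal.
#' @export
pool_cohort_rows <- function(summary_table) {
  n <- summary_table$n
  m <- summary_table$age_mean
  s <- summary_table$age_sd
  N <- sum(n)
  pooled_mean <- sum(n * m) / N
  ss <- sum((n - 1) * s^2) + sum(n * (m - pooled_mean)^2)
  pooled_sd <- sqrt(ss / (N - 1))
  count_cols <- grep("^(sex|bmi)_", colnames(summary_table), value = TRUE)
  out <- data.frame(country = "Total", n = N,
                    age_mean = round(pooled_mean, 1),
                    age_sd = round(pooled_sd, 1),
                    stringsAsFactors = FALSE)
  for (cc in count_cols) out[[cc]] <- sum(summary_table[[cc]])
  out
}

#' Write a cohort summary as a tab-separated table
#'
#' @param summary_table Output of [cohort_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary_table, path) {
  utils::write.table(summary_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
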