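#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Metadata columns every sample table carries, in canonical order.
META_COLS <- c("sample_id", "group", "age", "bmi", "activity", "menarche_age")

#' Covariates recorded for every sample
#'
#' Age (years), body-mass index (kg/m^2), a physical-activity score and age
#' of menarche (years) — the confounders that metabolite levels are
#' residualised against before any correlation analysis.
#'
#' @return Character vector of covariate column names.
#' @export
cohort_covariates <- function() c("age", "bmi", "activity", "menarche_age")

#' Construct a sample table
#'
#' A sample table is a tibble of samples (rows) by metadata plus metabolite
#' concentrations (columns), with a parallel per-entry status matrix
#' recording whether each concentration was quantified, censored below the
#' limit of detection (LOD), missing, or imputed. Below-LOD and missing
#' entries hold `NA` in the value columns; the status matrix is the source
#' of truth for why.
#'
#' @param data Data frame with columns `sample_id`, `group` (values `"pre"`
#'   or `"post"`), the four [cohort_covariates()], and one numeric column
#'   per metabolite.
#' @param status Character matrix (samples x metabolites) with entries in
#'   `"quantified"`, `"below_lod"`, `"missing"`, `"imputed_lod"`,
#'   `"imputed_mean"`. Defaults to `"quantified"` where the value is
#'   non-missing and `"missing"` elsewhere.
#' @return A `sample_table` (a tibble subclass).
#' @export
sample_table <- function(data, status = NULL) {
  data <- as_tibble(data)
  missing_meta <- setdiff(META_COLS, names(data))
  if (length(missing_meta) > 0) {
    abort(paste0("sample table lacks metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  if (!all(data$group %in% c("pre", "post"))) {
    abort("group labels must be 'pre' or 'post'")
  }
  mets <- setdiff(names(data), META_COLS)
  if (length(mets) == 0) abort("sample table has no metabolite columns")
  vals <- as.matrix(data[mets])
  if (!is.numeric(vals)) abort("metabolite columns must be numeric")
  if (is.null(status)) {
    status <- matrix(ifelse(is.na(vals), "missing", "quantified"),
                     nrow = nrow(vals), dimnames = list(NULL, mets))
  }
  stopifnot(nrow(status) == nrow(data), ncol(status) == length(mets))
  colnames(status) <- mets
  new_sample_table(data[c(META_COLS, mets)], status)
}

new_sample_table <- function(data, status) {
  out <- as_tibble(data)
  attr(out, "status") <- status
  class(out) <- c("sample_table", class(tibble()))
  out
}

#' Metabolite names of a sample table
#' @param x A `sample_table`.
#' @return Character vector of metabolite column names.
#' @export
metabolites <- function(x) setdiff(names(x), META_COLS)

#' Concentration matrix of a sample table
#' @param x A `sample_table`.
#' @return Numeric matrix (samples x metabolites); censored and missing
#'   entries are `NA`.
#' @export
metabolite_matrix <- function(x) {
  m <- as.matrix(as_tibble(x)[metabolites(x)])
  rownames(m) <- x$sample_id
  m
}

#' Per-entry status matrix of a sample table
#' @param x A `sample_table`.
#' @return Character matrix aligned with [metabolite_matrix()].
#' @export
status_matrix <- function(x) attr(x, "status")

# Replace the value matrix (and optionally status), preserving metadata.
set_values <- function(x, values, status = NULL) {
  mets <- colnames(values)
  meta <- as_tibble(x)[META_COLS]
  out <- bind_cols(meta, as_tibble(values))
  new_sample_table(out, status %||% status_matrix(x)[, mets, drop = FALSE])
}

#' @export
print.sample_table <- function(x, ...) {
  st <- status_matrix(x)
  cat(sprintf("# A sample_table: %d samples x %d metabolites (pre: %d, post: %d)\n",
              nrow(x), length(metabolites(x)),
              sum(x$group == "pre"), sum(x$group == "post")))
  if (!is.null(st)) {
    cat(sprintf("# entries below LOD: %d, missing: %d\n",
                sum(st == "below_lod"), sum(st == "missing")))
  }
  NextMethod()
}

#' Write a sample table to CSV
#'
#' Below-LOD entries are written as the literal token `<LOD`; missing
#' entries as an empty field. Imputed entries are written as their numeric
#' value. First columns are `sample_id, group, age, bmi, activity,
#' menarche_age`, then one column per metabolite.
#'
#' @param x A `sample_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  st <- status_matrix(x)
  vals <- metabolite_matrix(x)
  chr <- matrix(as.character(vals), nrow = nrow(vals),
                dimnames = dimnames(vals))
  chr[st == "below_lod"] <- "<LOD"
  chr[st == "missing"] <- ""
  chr[is.na(chr)] <- ""
  out <- bind_cols(as_tibble(x)[META_COLS], as_tibble(chr))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a sample table from CSV
#'
#' Inverse of [write_sample_table()]: `<LOD` tokens become below-LOD
#' entries, empty fields become missing entries.
#'
#' @param path CSV file path.
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  missing_meta <- setdiff(META_COLS, names(raw))
  if (length(missing_meta) > 0) {
    abort(paste0("CSV lacks column(s): ", paste(missing_meta, collapse = ", ")))
  }
  mets <- setdiff(names(raw), META_COLS)
  chr <- as.matrix(raw[mets])
  status <- matrix("quantified", nrow(chr), ncol(chr),
                   dimnames = list(NULL, mets))
  status[chr == "<LOD"] <- "below_lod"
  status[chr == ""] <- "missing"
  vals <- suppressWarnings(matrix(as.numeric(chr), nrow(chr),
                                  dimnames = list(NULL, mets)))
  meta <- raw[META_COLS]
  meta$age <- as.numeric(meta$age)
  meta$bmi <- as.numeric(meta$bmi)
  meta$activity <- as.numeric(meta$activity)
  meta$menarche_age <- as.numeric(meta$menarche_age)
  new_sample_table(bind_cols(meta, as_tibble(vals)), status)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
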