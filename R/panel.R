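#' Construct a provider panel
#'
#' A provider panel holds patient-level continuous outcomes nested within
#' providers (e.g. dialysis facilities), plus optional patient covariates used
#' for risk adjustment. It is the input to every IUR/PIUR computation.
#'
#' @param data a data.frame with one row per patient.
#' @param id_col name of the provider identifier column (default
#'   `"provider_id"`).
#' @param y_col name of the raw outcome column (default `"y"`). Large values
#'   are read as poor outcomes.
#' @param covariates character vector of covariate column names (default none).
#' @return An object of class `provider_panel`: a `data.table` with columns
#'   `provider_id` (character), `y`, the covariate columns, and (after
#'   [risk_adjust()]) `y_adj`; attributes `covariates` and `sizes`.
#' @examples
#' pp <- provider_panel(data.frame(provider_id = rep(c("a", "b"), each = 3),
#'                                 y = rnorm(6)))
#' provider_sizes(pp)
#' @export
provider_panel <- function(data, id_col = "provider_id", y_col = "y",
                           covariates = character()) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(id_col, y_col, covariates), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dt <- data.table::data.table(
    provider_id = as.character(data[[id_col]]),
    y = as.numeric(data[[y_col]])
  )
  for (cv in covariates) dt[[cv]] <- as.numeric(data[[cv]])
  if (any(!nzchar(dt$provider_id)) || anyNA(dt$provider_id))
    stop("provider_id must be non-empty and non-missing")
  bad <- which(!is.finite(dt$y))
  if (length(bad))
    stop("non-finite outcome in rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  for (cv in covariates) {
    bad <- which(!is.finite(dt[[cv]]))
    if (length(bad))
      stop("non-finite covariate '", cv, "' in rows: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (length(unique(dt$provider_id)) < 2L)
    stop("a provider panel needs at least 2 providers")
  data.table::setkey(dt, provider_id)
  data.table::setattr(dt, "covariates", covariates)
  data.table::setattr(dt, "class", c("provider_panel", class(dt)))
  dt
}

#' Read a provider panel from delimited text
#'
#' Reads a CSV or TSV file (delimiter chosen by extension: `.tsv`/`.txt` with
#' tabs, otherwise comma) with a header row and columns `provider_id`, `y`,
#' plus any declared covariate columns.
#'
#' @param path file path.
#' @param covariates character vector of covariate column names.
#' @return a [provider_panel()].
#' @export
read_panel <- function(path, covariates = character()) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("provider_id", "y", covariates)
  for (col in intersect(need, names(df))) {
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stop("missing values in column '", col, "' at data rows: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  provider_panel(df, covariates = covariates)
}

#' @export
print.provider_panel <- function(x, ...) {
  sz <- provider_sizes(x)
  cat("provider_panel:", length(sz), "providers,", nrow(x), "patients\n")
  cat("  sizes: min", min(sz), "median", stats::median(sz), "max", max(sz), "\n")
  cv <- attr(x, "covariates")
  if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
  cat("  risk-adjusted:", if ("y_adj" %in% names(x)) "yes" else "no", "\n")
  invisible(x)
}

#' Per-provider sample sizes
#'
#' @param panel a [provider_panel()].
#' @return named integer vector of patient counts n_i, one per provider.
#' @export
provider_sizes <- function(panel) {
  tab <- table(panel$provider_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Number of providers
#' @param panel a [provider_panel()].
#' @return integer count m.
#' @export
n_providers <- function(panel) length(unique(panel$provider_id))

# Adjusted outcome accessor; errors if risk adjustment has not run.
adjusted_y <- function(panel) {
  if (!"y_adj" %in% names(panel))
    stop("panel is not risk-adjusted; call risk_adjust() first")
  panel$y_adj
}

# Ensure the panel carries y_adj: estimate beta (within-provider) and mu if
# needed. Used by high-level drivers so pipelines on covariate-free simulated
# panels work without an explicit risk_adjust() call.
ensure_adjusted <- function(panel) {
  if ("y_adj" %in% names(panel)) return(panel)
  beta <- estimate_beta_fixed_effects(panel)
  mu <- center_mu(panel, beta)
  risk_adjust(panel, variance_components(mu = mu, beta = beta))
}

# Covariate matrix (0-column matrix when the panel has no covariates).
covariate_matrix <- function(panel) {
  cv <- attr(panel, "covariates")
  if (!length(cv)) return(matrix(numeric(0), nrow = nrow(panel), ncol = 0L))
  as.matrix(panel[, cv, with = FALSE])
}
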