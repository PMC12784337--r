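#' Declare the role and measurement level of one variable
#'
#' A mixed-measurement-level dataset is described by one `variable_spec` per
#' column: its role (predictor or response) and its measurement level.
#' Responses may be numeric, binary or ordinal; predictors may additionally be
#' nominal.  Discrete variables carry their number of categories and, for
#' ordinal variables, the category order.
#'
#' @param name column name in the data table.
#' @param role `"predictor"` or `"response"`.
#' @param level `"numeric"`, `"binary"`, `"nominal"` or `"ordinal"`.
#' @param n_categories number of categories (`C`); 0 for numeric, 2 for binary.
#' @param order optional character vector of category labels in increasing
#'   order (ordinal variables only); defaults to `as.character(1:n_categories)`.
#'
#' @return an object of class `variable_spec`.
#' @export
#' @examples
#' variable_spec("age", "predictor", "numeric")
#' variable_spec("trust", "response", "binary")
#' variable_spec("edu", "predictor", "ordinal", n_categories = 9)
variable_spec <- function(name, role = c("predictor", "response"),
                          level = c("numeric", "binary", "nominal", "ordinal"),
                          n_categories = NULL, order = NULL) {
  role <- match.arg(role)
  level <- match.arg(level)
  if (level == "numeric") {
    if (!is.null(n_categories) && n_categories != 0)
      stop("numeric variable '", name, "' must have n_categories = 0")
    n_categories <- 0L
  } else if (level == "binary") {
    if (!is.null(n_categories) && n_categories != 2)
      stop("binary variable '", name, "' must have n_categories = 2")
    n_categories <- 2L
  } else {
    if (is.null(n_categories) || n_categories < 2)
      stop(level, " variable '", name, "' needs n_categories >= 2")
    n_categories <- as.integer(n_categories)
  }
  if (role == "response" && level == "nominal")
    stop("response '", name, "' declared nominal; responses must be numeric, binary or ordinal")
  if (level == "ordinal") {
    if (is.null(order)) order <- as.character(seq_len(n_categories))
    if (length(order) != n_categories)
      stop("category order for '", name, "' has length ", length(order),
           ", expected ", n_categories)
  } else {
    order <- if (n_categories > 0) as.character(seq_len(n_categories)) else character(0)
  }
  structure(list(name = as.character(name), role = role, level = level,
                 n_categories = n_categories, order = order),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: %s %s", x$name, x$level, x$role))
  if (x$n_categories > 0) cat(sprintf(" (C = %d)", x$n_categories))
  cat("\n")
  invisible(x)
}

is_discrete <- function(spec) spec$level %in% c("binary", "nominal", "ordinal")

#' Assemble and validate a mixed-measurement-level dataset
#'
#' Validates a rectangular table against a list of [variable_spec()]s and
#' returns a `mixed_data` object holding the raw predictor matrix `X`, the
#' raw response matrix `Y` and the specs.  Category codes must be 1-based
#' integers in `1..C` (binary responses coded 0/1), every declared category
#' must occur at least once, and missing cells are rejected.  Columns of
#' `table` not covered by a spec are dropped with a warning.
#'
#' @param table a data frame with one row per observation.
#' @param specs a list of [variable_spec()] objects.
#' @return an object of class `mixed_data` with elements `X`, `Y`, `specs`
#'   (split into `$predictors` and `$responses`) and `N`.
#' @export
mixed_data <- function(table, specs) {
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  stopifnot(is.data.frame(table), length(specs) >= 2)
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate variable names in specs")
  missing_cols <- setdiff(nm, names(table))
  if (length(missing_cols))
    stop("columns not found in table: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(table), nm)
  if (length(extra))
    warning("dropping columns not covered by the variable specs: ",
            paste(extra, collapse = ", "))
  table <- table[nm]
  N <- nrow(table)
  if (N < 2) stop("need at least 2 observations")

  for (s in specs) {
    v <- table[[s$name]]
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("missing value in column '", s$name, "', row ", i,
           " (missing data are not supported)")
    }
    if (!is.numeric(v))
      stop("column '", s$name, "' is not numeric; code categories as integers")
    if (is_discrete(s)) {
      codes <- normalize_codes(v, s)
      if (any(codes != round(codes)))
        stop("column '", s$name, "' contains non-integer category codes")
      if (any(codes < 1 | codes > s$n_categories))
        stop("column '", s$name, "' contains codes outside 1..",
             s$n_categories, " (first offending row ",
             which(codes < 1 | codes > s$n_categories)[1], ")")
      absent <- setdiff(seq_len(s$n_categories), unique(codes))
      if (length(absent))
        stop("column '", s$name, "': declared category ", absent[1],
             " never occurs")
    } else {
      if (s$role == "predictor" && stats::sd(v) == 0)
        stop("numeric predictor '", s$name, "' is constant")
    }
  }

  roles <- vapply(specs, `[[`, "", "role")
  pred_specs <- specs[roles == "predictor"]
  resp_specs <- specs[roles == "response"]
  if (!length(pred_specs)) stop("no predictor variables declared")
  if (!length(resp_specs)) stop("no response variables declared")

  X <- as.matrix(table[vapply(pred_specs, `[[`, "", "name")])
  Y <- as.matrix(table[vapply(resp_specs, `[[`, "", "name")])
  structure(list(X = X, Y = Y,
                 specs = list(predictors = pred_specs, responses = resp_specs),
                 N = N),
            class = "mixed_data")
}

# binary responses arrive as 0/1; internally every discrete variable uses
# codes 1..C, so shift binary *responses* up by one.  Binary predictors are
# accepted as either 0/1 or 1/2.
normalize_codes <- function(v, spec) {
  if (spec$level == "binary" && all(v %in% c(0, 1))) v + 1 else v
}

#' @export
print.mixed_data <- function(x, ...) {
  cat(sprintf("<mixed_data> N = %d, P = %d predictors, R = %d responses\n",
              x$N, ncol(x$X), ncol(x$Y)))
  lev <- function(ss) table(factor(vapply(ss, `[[`, "", "level"),
                                   c("numeric", "binary", "nominal", "ordinal")))
  cat("  predictors:", paste(names(lev(x$specs$predictors)),
                             lev(x$specs$predictors), sep = "=", collapse = " "), "\n")
  cat("  responses: ", paste(names(lev(x$specs$responses)),
                             lev(x$specs$responses), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a dataset and its variable configuration from disk
#'
#' The data file is a CSV with a header row; the configuration is a JSON or
#' YAML list of entries `{name, role, level, n_categories, order}`.
#'
#' @param data_file path to the CSV data table.
#' @param config_file path to the JSON (`.json`) or YAML (`.yml`/`.yaml`)
#'   variable configuration.
#' @return a [mixed_data()] object.
#' @export
read_mixed_data <- function(data_file, config_file) {
  table <- utils::read.csv(data_file, check.names = FALSE)
  entries <- if (grepl("\\.json$", config_file, ignore.case = TRUE)) {
    jsonlite::read_json(config_file, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(config_file)
  }
  specs <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (is.null(e$name) || is.null(e$role) || is.null(e$level))
      stop("config entry ", i, " must have fields name, role and level")
    variable_spec(e$name, e$role, e$level,
                  n_categories = e$n_categories,
                  order = if (!is.null(e$order)) as.character(unlist(e$order)))
  })
  mixed_data(table, specs)
}

#' Write a dataset and its variable configuration to disk
#'
#' @param data a [mixed_data()] object.
#' @param data_file,config_file output paths (CSV and JSON).
#' @return invisibly, the paths written.
#' @export
write_mixed_data <- function(data, data_file, config_file) {
  tab <- as.data.frame(cbind(data$X, data$Y), check.names = FALSE)
  utils::write.csv(tab, data_file, row.names = FALSE)
  entries <- lapply(c(data$specs$predictors, data$specs$responses), function(s)
    list(name = s$name, role = s$role, level = s$level,
         n_categories = s$n_categories,
         order = if (s$level == "ordinal") s$order))
  jsonlite::write_json(entries, config_file, auto_unbox = TRUE, null = "null")
  invisible(c(data_file, config_file))
}

#' Indicator (dummy) matrix of a coded categorical variable
#'
#' Expands length-N category codes into the N x C 0/1 indicator matrix `G`
#' with exactly one 1 per row, together with the per-category frequencies.
#'
#' @param codes integer codes in `1..n_categories`.
#' @param n_categories number of categories C.
#' @return a list with elements `G` (N x C matrix) and `frequencies`
#'   (length-C counts).
#' @export
build_indicator <- function(codes, n_categories) {
  codes <- as.integer(codes)
  if (any(codes < 1 | codes > n_categories))
    stop("codes outside 1..", n_categories)
  freq <- tabulate(codes, nbins = n_categories)
  if (any(freq == 0))
    stop("category ", which(freq == 0)[1],
         " is empty; its quantification would be undefined")
  G <- matrix(0, length(codes), n_categories)
  G[cbind(seq_along(codes), codes)] <- 1
  list(G = G, frequencies = freq)
}

#' Standardize a numeric variable to mean 0, variance 1
#'
#' Uses the population (divide-by-N) variance convention; the same convention
#' applies to the rescaling of quantified variables so that every column of
#' the transformed predictor matrix is standardized in the same sense.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return the standardized vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  mu <- mean(values)
  s <- sqrt(mean((values - mu)^2))
  if (s == 0) stop("cannot standardize a constant column")
  (values - mu) / s
}
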