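#' Fit a discretization map for continuous predictors
#'
#' Continuous predictors are cut into `k` equal-frequency bins on the
#' observed training values (cutpoints at the 1/k, ..., (k-1)/k empirical
#' quantiles). A predictor whose schema declares fixed clinical `cutpoints`
#' (e.g. BMI classes at 20/25/30) keeps those instead. Binary and
#' categorical predictors pass through unchanged.
#'
#' Bin convention: bin j is the half-open interval (cut_{j-1}, cut_j], with
#' the lowest bin closed below at -Inf — a value equal to a cutpoint falls
#' in the lower-indexed bin.
#'
#' @param table a [cohort_table()]; cutpoints are computed from its rows only
#'   (pass the training rows to avoid test-set leakage).
#' @param k bins per continuous predictor, `>= 2` (default 3, giving the
#'   low / middle / high pattern used for clinical thresholds).
#' @param vars predictors to consider (default all).
#' @return A `discretization_map`: named list with `cutpoints` per continuous
#'   predictor and `levels` per pass-through predictor.
#' @export
fit_discretization <- function(table, k = 3, vars = predictor_names(table)) {
  stopifnot(k >= 2)
  map <- list()
  for (nm in vars) {
    sc <- table$schema[[nm]]
    if (is.null(sc)) stop_nbc("unknown predictor '%s'", nm)
    if (sc$kind != "continuous") {
      map[[nm]] <- list(kind = "passthrough", levels = sc$levels)
      next
    }
    if (!is.null(sc$cutpoints)) {
      map[[nm]] <- list(kind = "cut", cutpoints = as.numeric(sc$cutpoints), fixed = TRUE)
      next
    }
    x <- table$data[[nm]]
    x <- x[!is.na(x)]
    if (length(unique(x)) < k)
      stop_nbc("continuous column '%s' has fewer than %d distinct observed values", nm, k)
    q <- stats::quantile(x, probs = seq_len(k - 1) / k, names = FALSE, type = 7)
    if (anyDuplicated(q))
      stop_nbc("column '%s' is too concentrated for %d equal-frequency bins (tied cutpoints)", nm, k)
    map[[nm]] <- list(kind = "cut", cutpoints = as.numeric(q), fixed = FALSE)
  }
  structure(map, class = "discretization_map")
}

bin_labels <- function(ncut) as.character(seq_len(ncut + 1L))

# right-closed binning: findInterval on (-x) would flip order; use a direct scan
assign_bins <- function(x, cuts) {
  # bin j = (cut_{j-1}, cut_j]; values above the last cut go to the top bin
  b <- rep.int(length(cuts) + 1L, length(x))
  for (j in rev(seq_along(cuts))) b[x <= cuts[j]] <- j
  b[is.na(x)] <- NA_integer_
  b
}

#' Apply a discretization map to a cohort table
#'
#' Replaces each mapped continuous column by ordinal bin codes (`"1"` =
#' lowest), updating the schema so downstream stages see a fully categorical
#' table. Missing values stay missing; categorical columns are untouched
#' (applying a map twice is a no-op).
#'
#' @param table a [cohort_table()].
#' @param map a map from [fit_discretization()].
#' @return A [cohort_table()] with categorical codes for mapped columns.
#' @export
apply_discretization <- function(table, map) {
  data <- table$data
  schema <- table$schema
  for (nm in names(map)) {
    entry <- map[[nm]]
    if (entry$kind == "passthrough") next
    v <- data[[nm]]
    if (is.null(v)) stop_nbc("mapped column '%s' absent from table", nm)
    if (!is.numeric(v)) {
      if (table$schema[[nm]]$kind != "continuous") next  # already discretized
      stop_nbc("column '%s' is not numeric; cannot apply cutpoints", nm)
    }
    lv <- bin_labels(length(entry$cutpoints))
    data[[nm]] <- ifelse(is.na(v), NA_character_, lv[assign_bins(v, entry$cutpoints)])
    sc <- schema[[nm]]
    sc$kind <- "categorical"
    sc$levels <- lv
    sc$ordered <- TRUE
    schema[[nm]] <- sc
  }
  structure(list(data = data, schema = schema), class = "cohort_table")
}

#' Serialize / deserialize a discretization map as JSON
#' @param map a `discretization_map`.
#' @param path file path; with `NULL` the JSON string is returned.
#' @return `write_discretization`: the path (or JSON string), invisibly.
#' @export
write_discretization <- function(map, path = NULL) {
  obj <- lapply(map, function(e)
    if (e$kind == "cut") list(cutpoints = e$cutpoints, fixed = isTRUE(e$fixed))
    else list(levels = e$levels))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname write_discretization
#' @export
read_discretization <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  map <- lapply(obj, function(e)
    if (!is.null(e$cutpoints)) list(kind = "cut", cutpoints = as.numeric(e$cutpoints),
                                    fixed = isTRUE(e$fixed))
    else list(kind = "passthrough", levels = as.character(e$levels)))
  structure(map, class = "discretization_map")
}
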