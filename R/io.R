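#' Write a cohort table (and its schema) to disk
#'
#' One unambiguous CSV dialect: UTF-8, comma separator, `.` decimal, header
#' row, missing cells as empty strings, outcome column named `outcome` with
#' values 0/1. Numerics are written with 17 significant digits so a write /
#' read cycle reproduces the table exactly. The companion schema file (YAML
#' or JSON by extension) declares each column's kind, category levels and
#' any fixed cutpoints.
#'
#' @param table a [cohort_table()].
#' @param path CSV output path.
#' @param schema_path optional schema output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, schema_path = NULL) {
  df <- table$data
  for (nm in names(df)) if (is.double(df[[nm]])) {
    v <- formatC(df[[nm]], digits = 17, format = "g")
    v[is.na(df[[nm]])] <- NA
    df[[nm]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(schema_path)) write_schema(table$schema, schema_path)
  invisible(path)
}

#' @rdname write_cohort
#' @param schema a cohort schema (named list per column).
#' @export
write_schema <- function(schema, schema_path) {
  obj <- lapply(schema, function(sc) {
    e <- list(kind = sc$kind)
    if (sc$kind != "continuous") e$levels <- as.list(as.character(sc$levels))
    if (!is.null(sc$cutpoints)) e$cutpoints <- as.list(as.numeric(sc$cutpoints))
    e
  })
  if (grepl("\\.ya?ml$", schema_path)) yaml::write_yaml(obj, schema_path)
  else writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE),
                  schema_path)
  invisible(schema_path)
}

read_schema <- function(schema_path) {
  obj <- if (grepl("\\.ya?ml$", schema_path)) yaml::read_yaml(schema_path)
         else jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  lapply(obj, function(e) list(kind = e$kind,
                               levels = if (!is.null(e$levels)) as.character(unlist(e$levels)),
                               cutpoints = if (!is.null(e$cutpoints)) as.numeric(unlist(e$cutpoints))))
}

#' Read a cohort table from CSV plus schema
#'
#' Inverse of [write_cohort()]: empty cells become missing, columns are
#' typed per the schema, and every cell of a categorical column must belong
#' to its declared level set (violations raise an error naming the row and
#' column). Row order is preserved.
#'
#' @param csv_path CSV file written in the package dialect.
#' @param schema_path schema file (YAML or JSON), or a schema list.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(csv_path, schema_path) {
  if (!file.exists(csv_path)) stop_nbc("cohort file '%s' does not exist", csv_path)
  schema <- if (is.character(schema_path)) {
    if (!file.exists(schema_path)) stop_nbc("schema file '%s' does not exist", schema_path)
    read_schema(schema_path)
  } else schema_path
  df <- utils::read.csv(csv_path, colClasses = "character", na.strings = "",
                        check.names = FALSE)
  if (!"outcome" %in% names(df)) stop_nbc("cohort file lacks the mandatory 'outcome' column")
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop_nbc("schema declares column(s) absent from the CSV: %s",
             paste(missing_cols, collapse = ", "))
  df$outcome <- parse_numeric(df$outcome, "outcome")
  for (nm in setdiff(names(df), "outcome")) {
    sc <- schema[[nm]]
    if (is.null(sc)) stop_nbc("column '%s' not covered by the schema", nm)
    if (sc$kind == "continuous") df[[nm]] <- parse_numeric(df[[nm]], nm)
  }
  cohort_table(df, schema)
}

parse_numeric <- function(v, nm) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad))
    stop_nbc("cannot parse value '%s' at row %d, column '%s' as a number", v[bad[1]], bad[1], nm)
  out
}

#' Write the standard report file set for a pipeline run
#'
#' Emits, under `out_dir`: `table2_presence.csv` (variable-by-split presence
#' matrix with consensus counts and final-model flags), `table3_diagnostics.csv`
#' (per-split test diagnostics plus mean and SD rows), `table4_posterior_odds.csv`
#' (the evidence table), `table5_logits.csv` (one column block per logit
#' variant, when supplied), `final_model.json`, `final_model.dot` and
#' `run_log.txt`. All outputs are deterministic, so a re-run with the same
#' seed reproduces the files byte for byte.
#'
#' @param results list as returned by [nbcmm()] (elements `ensemble`,
#'   `consensus`, `final`), optionally with `logits` from
#'   [run_logit_benchmark()] and `seed`.
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_nbc("cannot create output directory '%s'", out_dir)
  ens <- results$ensemble; final <- results$final
  files <- character(0)
  fp <- function(f) file.path(out_dir, f)

  pres <- as.data.frame(ens$presence * 1L)
  pres <- cbind(variable = rownames(ens$presence), pres,
                consensus_count = ens$consensus_counts,
                in_final = as.integer(rownames(ens$presence) %in% final$selected))
  utils::write.csv(pres[rowSums(ens$presence) > 0 | pres$in_final == 1, ],
                   fp("table2_presence.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, fp("table2_presence.csv"))

  mets <- c("sensitivity", "specificity", "accuracy", "ppv", "npv", "auc")
  t3 <- do.call(rbind, lapply(seq_along(ens$splits), function(s) {
    r <- ens$splits[[s]]$test_report
    data.frame(split = as.character(s), t(vapply(mets, function(k) r[[k]], numeric(1))))
  }))
  agg <- ens$aggregate
  t3 <- rbind(t3,
              data.frame(split = "mean", t(stats::setNames(agg$mean, mets))),
              data.frame(split = "sd", t(stats::setNames(agg$sd, mets))))
  num <- vapply(t3, is.numeric, logical(1))
  t3[num] <- lapply(t3[num], round, 3)
  utils::write.csv(t3, fp("table3_diagnostics.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, fp("table3_diagnostics.csv"))

  utils::write.csv(final$po_table, fp("table4_posterior_odds.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, fp("table4_posterior_odds.csv"))

  if (!is.null(results$logits)) {
    t5 <- do.call(rbind, lapply(results$logits, function(lv) {
      d <- lv$diagnostics
      data.frame(variant = lv$variant,
                 predictors = paste(lv$predictors, collapse = ";"),
                 n_used = lv$n_used, n_total = lv$n_total,
                 chi2 = round(lv$chi2, 2), chi2_p = signif(lv$chi2_p, 4),
                 pseudo_r2_pct = round(100 * lv$pseudo_r2, 2),
                 sensitivity = round(d$sensitivity, 2),
                 specificity = round(d$specificity, 2),
                 ppv = round(d$ppv, 2), npv = round(d$npv, 2),
                 log_lik = round(lv$log_lik, 2),
                 aic = round(lv$aic, 2), bic = round(lv$bic, 2),
                 proportion_used_pct = round(100 * lv$proportion_used, 2),
                 correct_pct = round(lv$correct_pct, 2),
                 floor_pct = round(lv$floor_pct, 2),
                 converged = lv$converged)
    }))
    utils::write.csv(t5, fp("table5_logits.csv"), row.names = FALSE, quote = FALSE)
    files <- c(files, fp("table5_logits.csv"))
  }

  write_nbc_model(final$model, fp("final_model.json"))
  writeLines(nbc_to_dot(final$model), fp("final_model.dot"))
  files <- c(files, fp("final_model.json"), fp("final_model.dot"))

  log <- c(sprintf("nbcmerge %s", as.character(utils::packageVersion("nbcmerge"))),
           sprintf("R %s.%s", R.version$major, R.version$minor),
           sprintf("seed: %s", results$seed %||% ens$scheme$seed),
           sprintf("partitions: %d splits, train %d, test %d",
                   ens$scheme$n_splits, ens$scheme$train_n, ens$scheme$test_n),
           sprintf("alpha: %g, bins: %d", ens$alpha, ens$k),
           sprintf("candidates: %d", length(ens$candidates)),
           sprintf("consensus pool (>=%s models): %s",
                   results$min_models %||% 4, paste(results$consensus, collapse = ", ")),
           sprintf("final model: %s", paste(final$selected, collapse = ", ")))
  writeLines(log, fp("run_log.txt"))
  files <- c(files, fp("run_log.txt"))
  invisible(files)
}
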