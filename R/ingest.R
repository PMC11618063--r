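#' Read a meta-analytic effect-size table
#'
#' Reads a delimited text file of effect-size estimates and standardizes it
#' into the column layout used throughout the package: one row per effect
#' with its estimate `es`, standard error `se`, sampling variance `var`,
#' z statistic `z = es/se`, and study / meta-analysis membership.
#'
#' Exactly one of `var_col` and `se_col` must resolve to a column; the other
#' quantity is back-filled (`var = se^2`, `se = sqrt(var)`). Cells that do
#' not parse as numbers become `NA`, never zero, and are removed later by
#' [filter_effects()]. Row order is preserved.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param es_col,var_col,se_col,study_col,meta_col Column names in the file
#'   holding the effect estimate, sampling variance, standard error, study
#'   identifier and meta-analysis identifier. `var_col` or `se_col` may be
#'   `NULL` (but not both).
#' @param type_col,label_col Optional columns: effect-size metric
#'   (SMD/lnRR/Zr/other) and a free-text study label used for duplicate
#'   detection across meta-analyses.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` read as tab, otherwise comma).
#' @return A tibble with columns `meta_id`, `study_id`, `effect_id`,
#'   `effect_type`, `study_label` (if mapped), `es`, `se`, `var`, `z`.
#' @seealso [filter_effects()], [deduplicate_studies()], [compute_weights()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("ma,study,yi,vi", "m1,s1,0.5,0.0625", "m1,s2,-0.2,0.04"), f)
#' load_effects(f, es_col = "yi", var_col = "vi",
#'              study_col = "study", meta_col = "ma")
load_effects <- function(path,
                         es_col = "es",
                         var_col = "var",
                         se_col = NULL,
                         study_col = "study_id",
                         meta_col = "meta_id",
                         type_col = NULL,
                         label_col = NULL,
                         delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "replimix_io_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    show_col_types = FALSE
  )
  if (nrow(raw) == 0) {
    abort("input file contains no data rows", class = "replimix_empty_input")
  }

  need <- c(es = es_col, study = study_col, meta = meta_col)
  for (nm in names(need)) {
    if (!need[[nm]] %in% names(raw)) {
      abort(
        paste0("required column '", need[[nm]], "' (", nm, ") not found in ", path),
        class = "replimix_schema_error"
      )
    }
  }
  if (is.null(var_col) && is.null(se_col)) {
    abort("one of var_col or se_col must be supplied",
          class = "replimix_schema_error")
  }
  has_var <- !is.null(var_col) && var_col %in% names(raw)
  has_se <- !is.null(se_col) && se_col %in% names(raw)
  if (!has_var && !has_se) {
    abort(
      paste0("neither variance column '", var_col %||% "", "' nor SE column '",
             se_col %||% "", "' found in ", path),
      class = "replimix_schema_error"
    )
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    meta_id = as.character(raw[[meta_col]]),
    study_id = as.character(raw[[study_col]]),
    effect_id = as.character(seq_len(nrow(raw))),
    es = num(raw[[es_col]])
  )
  if (!is.null(type_col) && type_col %in% names(raw)) {
    out$effect_type <- normalize_effect_type(raw[[type_col]])
  } else {
    out$effect_type <- NA_character_
  }
  if (!is.null(label_col) && label_col %in% names(raw)) {
    out$study_label <- as.character(raw[[label_col]])
  }
  if (has_var) {
    out$var <- num(raw[[var_col]])
    out$se <- rep(NA_real_, nrow(out))
    ok <- !is.na(out$var) & out$var >= 0
    out$se[ok] <- sqrt(out$var[ok])
    if (has_se) {
      miss <- is.na(out$var)
      out$se[miss] <- num(raw[[se_col]])[miss]
      out$var[miss] <- out$se[miss]^2
    }
  } else {
    out$se <- num(raw[[se_col]])
    out$var <- out$se^2
  }
  out$z <- out$es / out$se
  dplyr::relocate(out, "meta_id", "study_id", "effect_id", "effect_type",
                  "es", "se", "var", "z")
}

normalize_effect_type <- function(x) {
  x <- trimws(as.character(x))
  key <- tolower(x)
  dplyr::case_when(
    key %in% c("smd", "d", "g", "hedges g", "cohen d") ~ "SMD",
    key %in% c("lnrr", "rr", "log response ratio") ~ "lnRR",
    key %in% c("zr", "z_r", "fisher z", "fisher zr") ~ "Zr",
    is.na(key) | key == "" ~ NA_character_,
    TRUE ~ "other"
  )
}

#' Remove effects with unusable sampling variances or estimates
#'
#' Drops records whose sampling variance is missing, zero or negative, and
#' records with a missing effect estimate, then refreshes per-study effect
#' counts and cluster weights. A z statistic only exists where `se > 0`, so
#' these rows carry no usable information for the mixture fit.
#'
#' @param data Effect table from [load_effects()] (or any tibble with
#'   `es`, `var`, `study_id` columns).
#' @return Filtered tibble with recomputed `n_study` and `weight` columns;
#'   the per-rule removal counts are attached as attribute `"removal_log"`
#'   (see [removal_log()]).
#' @export
filter_effects <- function(data) {
  stopifnot(all(c("es", "var", "study_id") %in% names(data)))
  missing_var <- is.na(data$var)
  zero_var <- !missing_var & data$var == 0
  negative_var <- !missing_var & data$var < 0
  missing_es <- is.na(data$es) & !(missing_var | zero_var | negative_var)
  bad <- missing_var | zero_var | negative_var | is.na(data$es)

  log <- tibble::tibble(
    rule = c("missing_var", "zero_var", "negative_var", "missing_es"),
    n_removed = c(sum(missing_var), sum(zero_var), sum(negative_var),
                  sum(missing_es))
  )
  out <- data[!bad, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no records remain after variance/estimate filtering",
          class = "replimix_empty_result")
  }
  out <- compute_weights(out)
  attr(out, "removal_log") <- log
  out
}

#' Per-rule removal counts from the last filtering step
#'
#' @param data A tibble returned by [filter_effects()].
#' @return A tibble with columns `rule` and `n_removed`.
#' @export
removal_log <- function(data) {
  log <- attr(data, "removal_log")
  if (is.null(log)) {
    abort("no removal log attached; was filter_effects() applied?",
          class = "replimix_no_log")
  }
  log
}

#' Drop studies duplicated across meta-analyses
#'
#' Different meta-analyses routinely extract effects from the same primary
#' study; keeping both copies would break the assumption that studies are
#' independent units. Studies are matched on a normalized key (case-folded,
#' whitespace-collapsed) built from `key_col`; when the same key appears
#' under more than one `meta_id`, only the first occurrence in row order is
#' kept and all records of later occurrences are dropped.
#'
#' @param data Effect table (typically after [filter_effects()]).
#' @param key_col Column to build the duplicate key from; defaults to
#'   `study_label` when present, otherwise `study_id`.
#' @return Deduplicated tibble with recomputed `n_study` and `weight`.
#' @export
deduplicate_studies <- function(data, key_col = NULL) {
  stopifnot(all(c("study_id", "meta_id") %in% names(data)))
  if (is.null(key_col)) {
    key_col <- if ("study_label" %in% names(data)) "study_label" else "study_id"
  }
  if (!key_col %in% names(data)) {
    abort(paste0("dedup key column '", key_col, "' not found"),
          class = "replimix_schema_error")
  }
  key <- normalize_key(data[[key_col]])
  # first meta-analysis (in row order) in which each key appears
  first_meta <- tapply(data$meta_id, key, function(m) m[[1]])
  keep <- data$meta_id == unname(first_meta[key]) | is.na(key)
  out <- data[keep, , drop = FALSE]
  compute_weights(out)
}

normalize_key <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  x[x == ""] <- NA_character_
  x
}

#' Attach inverse cluster-size weights
#'
#' Weights every effect inversely to the number of effects contributed by
#' its study, `w_ij = 1/n_j`, so each study carries total weight 1 and the
#' weighted sample behaves like a J-study sample regardless of how many
#' effects individual studies report.
#'
#' @param data Effect table with a `study_id` column.
#' @return The table with refreshed `n_study` (effects in the study) and
#'   `weight` (`1/n_study`) columns; `sum(weight)` equals the number of
#'   distinct studies.
#' @export
compute_weights <- function(data) {
  stopifnot("study_id" %in% names(data))
  data |>
    dplyr::group_by(.data$study_id) |>
    dplyr::mutate(n_study = dplyr::n(), weight = 1 / .data$n_study) |>
    dplyr::ungroup()
}
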