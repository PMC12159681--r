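#' Load the packaged normative table store
#'
#' Reads the machine-readable normative tables shipped with the package (one
#' CSV per source table with a JSON sidecar carrying the citation, kind and
#' units) plus any user-supplied extra tables in the same format, and builds
#' the lookup structures used by [select_reference()] and [classify()].
#'
#' @param dir directory of table files; default the packaged store.
#' @param extra_dir optional directory of additional user tables, appended
#'   after the packaged ones.
#' @return a `cmr_registry` with elements `parameters`, `ranges` (one data
#'   frame across all range tables), `lms` (named list of [lms_model]s),
#'   `regression` (named list of [regression_z_model]s), `centiles` (named
#'   list of [centile_table]s) and `meta` (sidecar list).
#' @export
load_registry <- function(dir = NULL, extra_dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", "tables", package = "cmrref", mustWork = TRUE)
  dirs <- c(dir, extra_dir)
  reg <- list(parameters = NULL, ranges = NULL, lms = list(),
              regression = list(), centiles = list(), meta = list())
  for (d in dirs) {
    pf <- file.path(d, "parameters.csv")
    if (file.exists(pf)) {
      p <- utils::read.csv(pf, stringsAsFactors = FALSE)
      reg$parameters <- rbind(reg$parameters, p)
    }
    for (jf in sort(list.files(d, pattern = "\\.json$", full.names = TRUE))) {
      meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
      csv <- sub("\\.json$", ".csv", jf)
      if (!file.exists(csv))
        stop_domain("missing CSV for sidecar ", basename(jf))
      tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
      reg$meta[[meta$table]] <- meta
      reg <- add_table(reg, meta, tab)
    }
  }
  if (anyDuplicated(reg$parameters$id))
    stop_domain("duplicate parameter ids in registry")
  class(reg) <- "cmr_registry"
  reg
}

add_table <- function(reg, meta, tab) {
  kind <- meta$kind
  if (kind == "ranges") {
    tab$table_id <- meta$table
    tab$citation <- meta$citation
    reg$ranges <- rbind(reg$ranges, tab)
  } else if (kind == "lms") {
    for (sex in unique(tab$sex)) {
      rows <- tab[tab$sex == sex, , drop = FALSE]
      key <- paste(meta$table, sex, sep = ".")
      m <- lms_model(rows[, c("cov_value", "L", "M", "S")],
                     covariate = meta$covariate, sex = sex,
                     parameter_id = meta$parameter_id, units = meta$units,
                     citation = meta$citation,
                     precision = as.integer(meta$precision %||% 0L))
      cc <- intersect(c("c03", "c10", "c25", "c50", "c75", "c90", "c97"),
                      names(rows))
      if (length(cc) && any(!is.na(rows[[cc[1]]]))) {
        m$printed_centiles <- rows[, c("cov_value", cc,
                                       "centiles_consistent")]
      }
      reg$lms[[key]] <- m
    }
  } else if (kind == "regression") {
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      key <- paste(meta$table, i, sep = ".")
      reg$regression[[key]] <- regression_z_model(
        r$intercept, r$slope, r$transform,
        sd_residuals = if (is.na(r$sd_residuals) || r$sd_residuals == "")
          NA_real_ else as.numeric(r$sd_residuals),
        parameter_id = r$parameter_id, site = r$site, units = r$units,
        citation = meta$citation)
    }
  } else if (kind == "centiles") {
    for (pid in unique(tab$parameter_id)) {
      for (sex in unique(tab$sex)) {
        rows <- tab[tab$parameter_id == pid & tab$sex == sex, , drop = FALSE]
        if (!nrow(rows)) next
        key <- paste(meta$table, pid, sex, sep = ".")
        reg$centiles[[key]] <- centile_table(
          rows, covariate = meta$covariate, sex = sex, parameter_id = pid,
          units = meta$units, citation = meta$citation)
      }
    }
  } else stop_domain("unknown table kind: ", kind)
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cmr_registry <- function(x, ...) {
  cat(sprintf(paste0("CMR normative registry: %d parameters, %d range rows, ",
                     "%d LMS models, %d regression models, %d centile tables\n"),
              nrow(x$parameters) %||% 0L, nrow(x$ranges) %||% 0L,
              length(x$lms), length(x$regression), length(x$centiles)))
  invisible(x)
}

#' Construct a measurement record
#'
#' One patient measurement with the covariates the normative tables
#' condition on.
#'
#' @param parameter_id registry parameter key.
#' @param value measured value in parameter units (finite).
#' @param sex `"male"`, `"female"` or `NA`.
#' @param age age in years (>= 0), optional.
#' @param height_cm,weight_kg anthropometrics, optional.
#' @param bsa_m2 body surface area; derived by [bsa()] from height and weight
#'   when absent.
#' @param ethnicity,field_strength,convention optional stratifiers
#'   (`field_strength` in tesla; `convention` one of `"papillary_in_mass"`,
#'   `"papillary_in_volume"`, `"not_applicable"`).
#' @param bsa_formula formula used when BSA must be derived.
#' @return a `measurement_record`.
#' @export
measurement_record <- function(parameter_id, value, sex = NA, age = NA,
                               height_cm = NA, weight_kg = NA, bsa_m2 = NA,
                               ethnicity = NA, field_strength = NA,
                               convention = NA,
                               bsa_formula = c("dubois", "mosteller")) {
  stopifnot(is.character(parameter_id), length(parameter_id) == 1L)
  if (!is_num1(value)) stop_domain("`value` must be a finite number")
  if (!is.na(age) && age < 0) stop_domain("`age` must be non-negative")
  if (is.na(bsa_m2) && !is.na(height_cm) && !is.na(weight_kg))
    bsa_m2 <- bsa(height_cm, weight_kg, match.arg(bsa_formula))
  structure(list(parameter_id = parameter_id, value = value, sex = sex,
                 age = age, height_cm = height_cm, weight_kg = weight_kg,
                 bsa_m2 = bsa_m2, ethnicity = ethnicity,
                 field_strength = field_strength, convention = convention),
            class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("Measurement: %s = %g (sex %s, age %s)\n", x$parameter_id,
              x$value, x$sex, format(x$age)))
  invisible(x)
}

# covariate value of a record for a given covariate name (NA when absent)
record_covariate <- function(record, covariate) {
  switch(covariate,
         age_years = record$age,
         height_cm = record$height_cm,
         bsa_m2 = record$bsa_m2,
         NA_real_)
}

# stratum specificity: most-specific-wins precedence
# sex+age+ethnicity > sex+age > sex > all, with matched field strength and
# matched group each adding further specificity.
specificity <- function(sex_specific, age_bounded, eth_specific,
                        fs_specific = FALSE, group_matched = FALSE) {
  4L * eth_specific + 2L * age_bounded + 1L * sex_specific +
    8L * fs_specific + 16L * group_matched
}

range_candidates <- function(record, reg, table, group) {
  r <- reg$ranges
  if (is.null(r) || !nrow(r)) return(NULL)
  r <- r[r$parameter_id == record$parameter_id, , drop = FALSE]
  if (!is.null(table)) r <- r[r$table_id == table, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  keep <- logical(nrow(r)); score <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    row <- r[i, ]
    sex_ok <- row$sex == "all" ||
      (!is.na(record$sex) && row$sex == record$sex)
    # printed age bands are closed on paper ("20-29"); implemented half-open
    # [lo, hi + 1) for contiguity
    lo <- suppressWarnings(as.numeric(row$age_lo))
    hi <- suppressWarnings(as.numeric(row$age_hi))
    age_ok <- if (is.na(record$age)) is.na(lo) && is.na(hi)
              else (is.na(lo) || record$age >= lo) &&
                   (is.na(hi) || record$age < hi + 1)
    eth_ok <- row$ethnicity == "all" ||
      (!is.na(record$ethnicity) && row$ethnicity == record$ethnicity)
    fs_given <- !is.na(row$field_strength) && row$field_strength != ""
    fs_ok <- !fs_given ||
      (!is.na(record$field_strength) &&
         abs(as.numeric(row$field_strength) -
               as.numeric(record$field_strength)) < 0.26)
    grp_given <- !is.na(row$group) && row$group != ""
    grp_ok <- !grp_given ||
      (!is.null(group) && grepl(group, row$group, fixed = TRUE))
    conv_ok <- is.na(record$convention) ||
      row$convention %in% c("not_applicable", record$convention)
    keep[i] <- sex_ok && age_ok && eth_ok && fs_ok && grp_ok && conv_ok
    score[i] <- specificity(row$sex != "all",
                            !is.na(lo) && !is.na(hi),
                            row$ethnicity != "all",
                            fs_given, grp_given && grp_ok)
  }
  r <- r[keep, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  lapply(seq_len(nrow(r)), function(i)
    list(kind = "range", score = score[keep][i], obj = r[i, ],
         id = r$row_id[i], table = r$table_id[i]))
}

model_candidates <- function(record, reg, table, store, kind) {
  out <- list()
  for (key in names(store)) {
    m <- store[[key]]
    tab <- sub("\\..*$", "", key)
    if (!is.null(table) && tab != table) next
    if (m$parameter_id != record$parameter_id) next
    sex_ok <- is.null(m$sex) || m$sex == "all" ||
      (!is.na(record$sex) && m$sex == record$sex)
    if (!sex_ok) next
    if (kind %in% c("lms", "centile")) {
      cv <- record_covariate(record, m$covariate)
      g <- if (kind == "lms") m$grid else m$rows
      if (is.na(cv) || cv < min(g$cov_value) || cv > max(g$cov_value)) next
      score <- specificity(!is.null(m$sex) && m$sex != "all", TRUE, FALSE)
    } else {  # regression: needs BSA
      if (is.na(record$bsa_m2)) next
      age_ok <- is.na(record$age) || record$age < 19
      if (!age_ok) next
      score <- specificity(FALSE, TRUE, FALSE)
    }
    out[[length(out) + 1L]] <- list(kind = kind, score = score, obj = m,
                                    id = key, table = tab)
  }
  out
}

#' Select the applicable normative reference for a measurement
#'
#' Routes a measurement record to the most specific applicable entry across
#' all stores (reference ranges, LMS models, regression models, centile
#' tables). Stratum precedence is most-specific-wins:
#' sex+age+ethnicity over sex+age over sex over unstratified, with a matched
#' field strength or cohort group more specific still. Rows carrying a
#' cohort/technique `group` tag (athlete class, vendor/sequence) are only
#' eligible when `group` is supplied. Among equally specific survivors of
#' different kinds, distributional models win (LMS, then regression, then
#' centile table, then plain range); equal specificity within a kind is a
#' configuration error naming the competing entries.
#'
#' @param record a [measurement_record].
#' @param registry a `cmr_registry`.
#' @param table optionally force a named table (e.g. `"table41"`).
#' @param group optional cohort/technique selector matched as a fixed
#'   substring against the rows' group tag.
#' @return the selected entry: a list with `kind` (`"range"`, `"lms"`,
#'   `"regression"`, `"centile"`), `obj`, `id` and `table`; or a
#'   `cmr_no_reference` marker when nothing applies.
#' @export
select_reference <- function(record, registry, table = NULL, group = NULL) {
  stopifnot(inherits(record, "measurement_record"),
            inherits(registry, "cmr_registry"))
  known <- c(registry$parameters$id,
             registry$ranges$parameter_id,
             vapply(registry$lms, `[[`, "", "parameter_id"),
             vapply(registry$regression, `[[`, "", "parameter_id"),
             vapply(registry$centiles, `[[`, "", "parameter_id"))
  if (!record$parameter_id %in% known)
    stop_domain("unknown parameter_id: ", record$parameter_id)
  cand <- c(range_candidates(record, registry, table, group),
            model_candidates(record, registry, table, registry$lms, "lms"),
            model_candidates(record, registry, table, registry$regression,
                             "regression"),
            model_candidates(record, registry, table, registry$centiles,
                             "centile"))
  if (!length(cand))
    return(structure(list(parameter_id = record$parameter_id),
                     class = "cmr_no_reference"))
  scores <- vapply(cand, `[[`, integer(1), "score")
  cand <- cand[scores == max(scores)]
  if (length(cand) > 1L) {
    kinds <- vapply(cand, `[[`, "", "kind")
    pref <- c("lms", "regression", "centile", "range")
    best_kind <- pref[min(match(kinds, pref))]
    cand <- cand[kinds == best_kind]
  }
  if (length(cand) > 1L)
    stop_domain("ambiguous reference selection for '", record$parameter_id,
                "': equally specific entries ",
                paste(vapply(cand, `[[`, "", "id"), collapse = ", "),
                "; disambiguate with `table` or `group`")
  cand[[1]]
}

classification_result <- function(status, z = NA_real_, centile = NA_real_,
                                  range_used = NA_character_,
                                  provenance = NA_character_,
                                  predicted = NA_real_, band = NA_character_) {
  structure(list(status = status, z = z, centile = centile,
                 range_used = range_used, provenance = provenance,
                 predicted = predicted, band = band),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Classification: %s", x$status))
  if (!is.na(x$z)) cat(sprintf(", z = %.2f", x$z))
  if (!is.na(x$centile)) cat(sprintf(", centile = %.1f", x$centile))
  if (!is.na(x$band)) cat(sprintf(", band %s", x$band))
  if (!is.na(x$provenance)) cat(sprintf("  [%s]", x$provenance))
  cat("\n")
  invisible(x)
}

#' Classify a measurement against the normative registry
#'
#' Selects a reference with [select_reference()] and compares the measured
#' value: for plain ranges the status is by the printed limits (values equal
#' to a limit are within range — the sources do not state inclusivity, so
#' inclusive limits are this package's documented convention) with
#' `z = (value - mean) / sd` when a mean and SD are available; for LMS models
#' the z-score and centile come from the growth-model transform, with status
#' by the z = +/-2 convention of the printed tables; regression models give
#' `z = (measured - predicted) / residual SD`; centile tables give a band,
#' with status by the outermost printed centile columns.
#'
#' @inheritParams select_reference
#' @return a `classification_result` with fields `status` (`below_range`,
#'   `within_range`, `above_range`, `no_reference`), `z`, `centile`,
#'   `range_used`, `provenance`, `predicted` and `band`.
#' @export
#' @examples
#' reg <- load_registry()
#' rec <- measurement_record("lvef", 50, sex = "male", age = 50)
#' classify(rec, reg)
classify <- function(record, registry, table = NULL, group = NULL) {
  sel <- select_reference(record, registry, table = table, group = group)
  if (inherits(sel, "cmr_no_reference"))
    return(classification_result("no_reference"))
  x <- record$value
  if (sel$kind == "range") {
    row <- sel$obj
    status <- if (x < row$lower) "below_range"
              else if (x > row$upper) "above_range" else "within_range"
    z <- if (!is.na(row$distribution) && row$distribution == "median_iqr")
      NA_real_
    else if (!is.na(row$mean) && !is.na(row$sd) && row$sd > 0)
      (x - row$mean) / row$sd
    else NA_real_
    return(classification_result(status, z = z,
                                 range_used = sel$id,
                                 provenance = row$citation))
  }
  if (sel$kind == "lms") {
    m <- sel$obj
    par <- lms_interpolate(m, record_covariate(record, m$covariate))
    z <- lms_z(x, par$L, par$M, par$S)
    status <- if (z < -2) "below_range" else if (z > 2) "above_range"
              else "within_range"
    return(classification_result(status, z = z,
                                 centile = 100 * stats::pnorm(z),
                                 range_used = sel$id,
                                 provenance = m$citation))
  }
  if (sel$kind == "regression") {
    m <- sel$obj
    rz <- regression_z(x, record$bsa_m2, m)
    status <- if (is.na(rz$z)) "no_reference"
              else if (rz$z < -2) "below_range"
              else if (rz$z > 2) "above_range" else "within_range"
    return(classification_result(status, z = rz$z,
                                 centile = if (is.na(rz$z)) NA_real_
                                           else 100 * stats::pnorm(rz$z),
                                 range_used = sel$id,
                                 provenance = m$citation,
                                 predicted = rz$predicted))
  }
  # centile table
  m <- sel$obj
  cb <- centile_band(m, record_covariate(record, m$covariate), x)
  status <- if (startsWith(cb$band, "<")) "below_range"
            else if (startsWith(cb$band, ">")) "above_range"
            else "within_range"
  classification_result(status, centile = cb$centile, range_used = sel$id,
                        provenance = m$citation, band = cb$band)
}

#' Classify a table of measurements
#'
#' Vectorized wrapper over [classify()]: takes a data frame (or CSV path)
#' with columns `parameter_id`, `value` and optional `sex`, `age`,
#' `height_cm`, `weight_kg`, `bsa_m2`, `ethnicity`, `field_strength`,
#' `convention`, `group`, `table`, and returns one classification row per
#' input row. Per-row failures are captured in an `error` column rather than
#' aborting the batch.
#'
#' @param x data frame or CSV file path.
#' @param registry a `cmr_registry`.
#' @return data frame with `status`, `z`, `centile`, `band`, `range_used`,
#'   `provenance` and `error` columns appended.
#' @export
classify_measurements <- function(x, registry) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x), all(c("parameter_id", "value") %in% names(x)))
  get <- function(row, nm) if (nm %in% names(x)) row[[nm]] else NA
  out <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    res <- tryCatch({
      rec <- measurement_record(row$parameter_id, row$value,
                                sex = get(row, "sex"), age = get(row, "age"),
                                height_cm = get(row, "height_cm"),
                                weight_kg = get(row, "weight_kg"),
                                bsa_m2 = get(row, "bsa_m2"),
                                ethnicity = get(row, "ethnicity"),
                                field_strength = get(row, "field_strength"),
                                convention = get(row, "convention"))
      tb <- get(row, "table"); gp <- get(row, "group")
      cl <- classify(rec, registry,
                     table = if (is.na(tb)) NULL else tb,
                     group = if (is.na(gp)) NULL else gp)
      data.frame(status = cl$status, z = cl$z, centile = cl$centile,
                 band = cl$band, range_used = cl$range_used,
                 provenance = cl$provenance, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(status = NA_character_, z = NA_real_, centile = NA_real_,
                 band = NA_character_, range_used = NA_character_,
                 provenance = NA_character_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    res
  })
  cbind(x, do.call(rbind, out))
}
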