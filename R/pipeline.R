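#' Read study summaries from CSV
#'
#' Expected columns: `study_id`, `parameter_id`, `n`, `mean`, `sd`, plus
#' optional stratum columns (`sex`, `age_lo`, `age_hi`, `ethnicity`).
#'
#' @param path CSV file.
#' @return data frame.
#' @export
read_study_summaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "parameter_id", "n", "mean", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_domain("study summary CSV is missing columns: ",
                paste(miss, collapse = ", "))
  df
}

#' Run a pipeline command
#'
#' Single programmatic entry point behind the command-line wrapper. Every
#' emitted number is produced by the package's exported functions; outputs
#' are returned invisibly and optionally serialized (JSON for scalar
#' results, CSV for tabular ones) at full precision.
#'
#' @param command one of `"pool"`, `"classify"`, `"zscore"`, `"derive"`,
#'   `"pwv"`, `"simulate"`, `"tables"`.
#' @param input input path (CSV or JSON, per command); for `"pwv"` a
#'   character vector of two waveform CSVs (`time_ms, velocity`).
#' @param out optional output path.
#' @param level,decimals,variant reference-range options for `"pool"`.
#' @param registry registry used by `"classify"`/`"zscore"`/`"tables"`;
#'   defaults to the packaged store.
#' @param delta_x centerline length in m for `"pwv"`.
#' @param method transit-time method for `"pwv"`.
#' @param simulate_what,simulate_args generator selector and arguments for
#'   `"simulate"` (`"aggregates"`, `"lms"`, `"flow"`, `"fractal"`).
#' @param seed seed forwarded to generators.
#' @return the command's result, invisibly.
#' @export
run_pipeline <- function(command = c("pool", "classify", "zscore", "derive",
                                     "pwv", "simulate", "tables"),
                         input = NULL, out = NULL, level = 0.95,
                         decimals = NA, variant = "normal", registry = NULL,
                         delta_x = NULL, method = "upslope_intersect",
                         simulate_what = "aggregates",
                         simulate_args = list(), seed = NULL) {
  command <- match.arg(command)
  if (command %in% c("classify", "zscore", "tables") && is.null(registry))
    registry <- load_registry()
  res <- switch(command,
    pool = {
      df <- read_study_summaries(input)
      est <- pool_random_effects(df)
      rng <- frequentist_reference_range(est, level = level,
                                         decimals = decimals,
                                         variant = variant)
      list(estimate = unclass(est), range = unclass(rng))
    },
    classify = {
      classify_measurements(input, registry)
    },
    zscore = {
      # same engine as classify; kept as a separate verb for scripts that
      # only want the z/centile columns
      classify_measurements(input, registry)
    },
    derive = {
      q <- jsonlite::read_json(input, simplifyVector = TRUE)
      derive_quantities(q)
    },
    pwv = {
      stopifnot(length(input) == 2L, !is.null(delta_x))
      rd <- function(p) {
        w <- utils::read.csv(p, stringsAsFactors = FALSE)
        flow_curve(w[[1]], w[[2]], site = basename(p))
      }
      pair <- aorta_path_pair(rd(input[1]), rd(input[2]), delta_x)
      pwv(pair, method = method)
    },
    simulate = {
      args <- c(simulate_args, list(seed = seed))
      switch(simulate_what,
             aggregates = do.call(gen_study_aggregates, args),
             lms = do.call(gen_lms_population, args),
             flow = do.call(gen_flow_pair, args),
             fractal = do.call(gen_fractal_image,
                               simulate_args),
             stop_domain("unknown simulate case: ", simulate_what))
    },
    tables = {
      verify_tables(registry)
    })
  if (!is.null(out)) {
    if (is.data.frame(res)) {
      utils::write.csv(res, out, row.names = FALSE)
    } else {
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
  }
  invisible(res)
}

# named-quantity dispatcher behind the `derive` command: computes every
# derived quantity whose inputs are present
derive_quantities <- function(q) {
  out <- list()
  has <- function(...) all(c(...) %in% names(q))
  if (has("height_cm", "weight_kg")) {
    f <- q$bsa_formula %||% "dubois"
    out$bsa_m2 <- bsa(q$height_cm, q$weight_kg, f)
    out$bsa_formula <- f
  }
  bsa_use <- q$bsa_m2 %||% out$bsa_m2
  if (has("value") && !is.null(bsa_use))
    out$indexed_value <- index_value(q$value, bsa_use)
  if (has("area_4ch", "area_2ch", "length_4ch", "length_2ch")) {
    out$atrial_volume_biplane_ml <- atrial_volume_biplane_ellipsoid(
      q$area_4ch, q$area_2ch, q$length_4ch, q$length_2ch)
    out$atrial_volume_calibrated_ml <- atrial_volume_biplane_calibrated(
      q$area_4ch, q$area_2ch, q$length_4ch, q$length_2ch)
  }
  if (has("area", "length"))
    out$atrial_volume_monoplane_ml <- atrial_volume_monoplane(q$area, q$length)
  if (has("edv", "length_4ch"))
    out$sphericity_index <- sphericity_index(q$edv, q$length_4ch)
  if (has("a_max", "a_min", "p_max", "p_min"))
    out$distensibility_e3_mmhg <- distensibility(q$a_max, q$a_min,
                                                 q$p_max, q$p_min)
  if (has("t1_myo_native", "t1_myo_post", "t1_blood_native", "t1_blood_post",
          "hematocrit"))
    out$ecv <- ecv(q$t1_myo_native, q$t1_myo_post, q$t1_blood_native,
                   q$t1_blood_post, q$hematocrit)
  if (has("t2star")) {
    out$r2star_s1 <- r2star(q$t2star)
    out$iron_mg_g <- iron_concentration(q$t2star)
    out$iron_grade <- as.character(grade_iron(q$t2star,
                                              q$field %||% "1.5T"))
  }
  if (has("mdt", "ea_ratio"))
    out$diastolic_classes <- classify_diastolic(q$mdt, q$ea_ratio)
  if (has("v_max") || has("orifice_area") || has("area_bsa"))
    out$aortic_stenosis <- stage_aortic_stenosis(q$v_max %||% NULL,
                                                 q$orifice_area %||% NULL,
                                                 q$area_bsa %||% NULL)
  out
}

#' Verify the packaged table store
#'
#' Bulk self-checks over the registry: every single-study range row must
#' reproduce its printed limits from `round(mean +/- 2 sd)` at the printed
#' precision, and every LMS row flagged consistent must reproduce its
#' printed centile cells within one unit.
#'
#' @param registry a `cmr_registry` (default: packaged store).
#' @return data frame with one row per check (`table`, `check`, `n_rows`,
#'   `n_pass`).
#' @export
verify_tables <- function(registry = NULL) {
  if (is.null(registry)) registry <- load_registry()
  out <- list()
  r <- registry$ranges
  if (!is.null(r)) {
    ss <- r[r$method == "single_study_mean_2sd" & r$distribution == "normal", ]
    for (tb in unique(ss$table_id)) {
      rows <- ss[ss$table_id == tb, ]
      ok <- vapply(seq_len(nrow(rows)), function(i) {
        rr <- mean_sd_range(rows$mean[i], rows$sd[i],
                            decimals = rows$precision[i])
        isTRUE(rr$lower == rows$lower[i] && rr$upper == rows$upper[i])
      }, logical(1))
      out[[length(out) + 1L]] <- data.frame(
        table = tb, check = "mean_2sd_limits",
        n_rows = nrow(rows), n_pass = sum(ok))
    }
  }
  for (key in names(registry$lms)) {
    m <- registry$lms[[key]]
    pc <- m$printed_centiles
    if (is.null(pc)) next
    rep <- lms_reproduce(m)
    cons <- isTRUE(all(as.logical(pc$centiles_consistent)))
    out[[length(out) + 1L]] <- data.frame(
      table = key,
      check = if (cons) "lms_centiles_within_1" else
        "lms_centiles_within_1 (panel flagged inconsistent in source)",
      n_rows = nrow(rep), n_pass = sum(abs(rep$reproduced - rep$printed) <= 1))
  }
  do.call(rbind, out)
}

# recompute every printed centile cell of an LMS model: z = +/-2 for the
# 3rd/97th (table convention), exact normal quantiles otherwise
lms_reproduce <- function(model) {
  pc <- model$printed_centiles
  stopifnot(!is.null(pc))
  cols <- intersect(c("c03", "c10", "c25", "c50", "c75", "c90", "c97"),
                    names(pc))
  pvals <- as.numeric(sub("^c0?", "", cols)) / 100
  out <- list()
  for (i in seq_len(nrow(pc))) {
    g <- model$grid[model$grid$cov_value == pc$cov_value[i], ]
    for (j in seq_along(cols)) {
      x <- lms_centile(p = pvals[j], L = g$L, M = g$M, S = g$S,
                       extreme_z2 = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        cov_value = pc$cov_value[i], centile = pvals[j],
        printed = pc[[cols[j]]][i],
        reproduced = round_half_away(x, model$precision))
    }
  }
  do.call(rbind, out)
}
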