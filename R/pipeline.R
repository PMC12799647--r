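# Cohort orchestration: run both approach conditions per shoulder, measure
# morphometrics, build the paired outcome table, and produce the full
# statistics report. All randomness flows from the seed in the config.

#' Configuration of a study run
#'
#' @param cohort a [cohort_spec()] for synthetic input, or `NULL` when
#'   `mesh_dir` is given.
#' @param mesh_dir directory of per-shoulder mesh files
#'   (`<id>_humerus.stl`, `<id>_scapula.stl`, `<id>_landmarks.json`; see
#'   [write_cohort_dir()]).
#' @param nail_diameter_mm,nail_length_mm,n_facets nail geometry.
#' @param extensions extension angles of the conditions to simulate
#'   (default `c(0, 30)`, the two study conditions).
#' @param tolerance_mm collision tolerance.
#' @param ci_level,bootstrap_B statistics options.
#' @param seed master seed; recorded in every output artifact.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), mesh_dir = NULL,
                       nail_diameter_mm = 8, nail_length_mm = 150,
                       n_facets = 64L, extensions = c(0, 30),
                       tolerance_mm = 0, ci_level = 0.95,
                       bootstrap_B = 1000L, seed = 1L) {
  if (length(extensions) < 1L) stop("at least one condition required")
  if (!is.null(cohort) && !is.null(mesh_dir))
    stop("give either a cohort spec or a mesh_dir, not both")
  if (!is.null(cohort)) cohort$seed <- seed
  structure(list(cohort = cohort, mesh_dir = mesh_dir,
                 nail_diameter_mm = nail_diameter_mm,
                 nail_length_mm = nail_length_mm, n_facets = n_facets,
                 extensions = extensions, tolerance_mm = tolerance_mm,
                 ci_level = ci_level, bootstrap_B = bootstrap_B,
                 seed = seed),
            class = "run_config")
}

#' Run the full per-shoulder simulation and cohort statistics
#'
#' For every shoulder: simulates each configured arm condition
#' ([run_condition()]) and measures the Acromion Index in the neutral pose
#' ([measure_ai()]). Per-shoulder failures are recorded in an exclusion log
#' and the shoulder is dropped from the statistics, never silently.
#' When the first two conditions are the 0/30-degree study conditions, the
#' paired outcome table and the complete statistics block (rates, McNemar,
#' ARR/NNT, subgroup odds ratios, logistic regression, ROC with bootstrap
#' validation, rank tests) are produced; with a single condition the paired
#' tests are omitted with an explicit notice.
#'
#' @param config a [run_config()].
#' @param progress print per-shoulder progress lines (default FALSE).
#' @return object of class `nail_study`: `per_shoulder` (data frame),
#'   `paired_table`, `stats`, `exclusions`, `config`.
#' @export
run_study <- function(config = run_config(), progress = FALSE) {
  if (!is.null(config$mesh_dir)) {
    cohort <- read_cohort_dir(config$mesh_dir)
  } else {
    cohort <- generate_cohort(config$cohort)
  }
  shoulders <- cohort$shoulders
  meta <- cohort$table
  n <- length(shoulders)
  rows <- list(); excl <- list()
  for (i in seq_len(n)) {
    id <- meta$shoulder_id[i]
    row <- tryCatch({
      sh <- shoulders[[i]]$shoulder
      morph <- measure_ai(sh, shoulder_id = id)
      res <- lapply(config$extensions, function(e)
        run_condition(sh, extension_deg = e,
                      nail_diameter_mm = config$nail_diameter_mm,
                      nail_length_mm = config$nail_length_mm,
                      n_facets = config$n_facets,
                      tolerance_mm = config$tolerance_mm))
      er <- attr(res[[1]], "entry_report")
      out <- data.frame(shoulder_id = id, side = meta$side[i],
                        sex = meta$sex[i], age_years = meta$age_years[i],
                        GA_mm = morph$GA_mm, GH_mm = morph$GH_mm,
                        AI = morph$AI,
                        entry_footprint_mm = er$distance_to_footprint,
                        rule_5mm = er$satisfies_5mm_rule,
                        stringsAsFactors = FALSE)
      for (k in seq_along(config$extensions)) {
        e <- config$extensions[k]
        out[[sprintf("collides_%g", e)]] <- res[[k]]$collides
        out[[sprintf("clearance_%g_mm", e)]] <- res[[k]]$clearance_mm
        out[[sprintf("n_contact_%g", e)]] <- length(res[[k]]$contact_faces_b)
      }
      out
    }, error = function(e) {
      excl[[length(excl) + 1L]] <<- data.frame(
        shoulder_id = id, reason = conditionMessage(e),
        stringsAsFactors = FALSE)
      NULL
    })
    if (progress)
      message(sprintf("  %s: %s", id,
                      if (is.null(row)) "EXCLUDED" else "ok"))
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  per <- do.call(rbind, rows)
  stats <- study_stats(per, extensions = config$extensions,
                       ci_level = config$ci_level,
                       bootstrap_B = config$bootstrap_B,
                       seed = config$seed)
  structure(list(per_shoulder = per,
                 paired_table = stats$paired_table,
                 stats = stats,
                 exclusions = if (length(excl)) do.call(rbind, excl)
                              else data.frame(shoulder_id = character(),
                                              reason = character()),
                 config = config),
            class = "nail_study")
}

#' Cohort statistics from a per-shoulder result table
#'
#' A pure function of the table: re-running it on the serialized CSV
#' reproduces the study's statistics block exactly.
#'
#' @param per data frame as produced by [run_study()] (columns `AI`,
#'   `collides_<e>` per condition, `sex`, `side`, `age_years`).
#' @param extensions the simulated extension angles (default `c(0, 30)`).
#' @param ci_level,bootstrap_B,seed options matching the run config.
#' @return list with the statistics blocks; `NULL` entries where a block is
#'   not computable, with a `notice` explaining why.
#' @export
study_stats <- function(per, extensions = c(0, 30), ci_level = 0.95,
                        bootstrap_B = 1000L, seed = 1L) {
  n <- nrow(per)
  out <- list(n = n, notice = character())
  col1 <- sprintf("collides_%g", extensions[1])
  # morphometrics block
  out$morphometrics <- data.frame(
    metric = c("GA_mm", "GH_mm", "AI"),
    mean = c(mean(per$GA_mm), mean(per$GH_mm), mean(per$AI)),
    sd = c(stats::sd(per$GA_mm), stats::sd(per$GH_mm), stats::sd(per$AI)),
    median = c(stats::median(per$GA_mm), stats::median(per$GH_mm),
               stats::median(per$AI)),
    min = c(min(per$GA_mm), min(per$GH_mm), min(per$AI)),
    max = c(max(per$GA_mm), max(per$GH_mm), max(per$AI)),
    stringsAsFactors = FALSE)
  # per-condition rates
  out$rates <- do.call(rbind, lapply(extensions, function(e) {
    k <- sum(per[[sprintf("collides_%g", e)]])
    ci <- prop_ci(k, n, level = ci_level)
    data.frame(extension_deg = e, collisions = k, n = n, rate = k / n,
               ci_low = ci[1], ci_high = ci[2])
  }))
  if (length(extensions) >= 2L) {
    col2 <- sprintf("collides_%g", extensions[2])
    out$paired_table <- paired_table_from_outcomes(per[[col1]], per[[col2]])
    out$mcnemar <- tryCatch(mcnemar(out$paired_table),
                            error = function(e) NULL)
    if (is.null(out$mcnemar))
      out$notice <- c(out$notice, "no discordant pairs: McNemar omitted")
    ar <- arr_nnt(sum(per[[col1]]), sum(per[[col2]]), n)
    out$arr_nnt <- ar
  } else {
    out$paired_table <- NULL
    out$notice <- c(out$notice,
                    "single condition: paired tests (McNemar, ARR/NNT) omitted")
  }
  # subgroup odds ratios for the reference condition
  sub_or <- function(group, lev) {
    g1 <- per[[group]] == lev
    counts <- c(sum(per[[col1]][g1]), sum(!per[[col1]][g1]),
                sum(per[[col1]][!g1]), sum(!per[[col1]][!g1]))
    if (any(rowSums(matrix(counts, 2, byrow = TRUE)) == 0)) return(NULL)
    suppressWarnings(odds_ratio_2x2(counts, ci_level = ci_level))
  }
  out$or_sex <- if ("sex" %in% names(per)) sub_or("sex", "male") else NULL
  out$or_side <- if ("side" %in% names(per)) sub_or("side", "left") else NULL
  # logistic block
  y <- per[[col1]]
  out$logistic_univariable <- tryCatch(
    suppressWarnings(logistic_fit(y, per[, "AI", drop = FALSE], "AI",
                                  ci_level = ci_level)),
    error = function(e) NULL)
  out$logistic_adjusted <- tryCatch(
    suppressWarnings(logistic_fit(
      y, per[, c("AI", "age_years", "sex", "side")],
      "AI + age_years + sex + side", ci_level = ci_level)),
    error = function(e) NULL)
  out$logistic_interactions <- tryCatch(
    suppressWarnings(logistic_fit(
      y, per[, c("AI", "age_years", "sex")],
      "AI * age_years + AI * sex", ci_level = ci_level)),
    error = function(e) NULL)
  # ROC + bootstrap internal validation
  out$roc <- tryCatch(roc_youden(per$AI, y), error = function(e) NULL)
  if (is.null(out$roc))
    out$notice <- c(out$notice, "one outcome class: ROC omitted")
  if (!is.null(out$roc)) {
    stat <- function(d) {
      r <- roc_youden(d$AI, d[[col1]])
      c(auc = r$auc, threshold = r$threshold, sensitivity = r$sensitivity,
        specificity = r$specificity, ppv = r$ppv, npv = r$npv)
    }
    out$bootstrap <- tryCatch(
      suppressWarnings(bootstrap_validate(per, stat, B = bootstrap_B,
                                          seed = seed, conf = ci_level)),
      error = function(e) NULL)
  }
  # generalizability: AI vs age, AI by sex
  out$ai_age <- tryCatch(rank_tests(per$AI, y = per$age_years)$spearman,
                         error = function(e) NULL)
  out$ai_sex <- if (length(unique(per$sex)) == 2L)
    rank_tests(per$AI, groups = per$sex)$mannwhitney else NULL
  out
}

#' Wilson (default) or Clopper-Pearson confidence interval for a proportion
#' @param k event count.
#' @param n number of trials.
#' @param level confidence level.
#' @param method "wilson" or "clopper-pearson".
#' @return length-2 vector (lower, upper).
#' @export
prop_ci <- function(k, n, level = 0.95, method = c("wilson",
                                                   "clopper-pearson")) {
  method <- match.arg(method)
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, ctr - hw), min(1, ctr + hw))
  } else {
    a <- (1 - level) / 2
    lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
    c(lo, hi)
  }
}

#' @export
print.nail_study <- function(x, ...) {
  cat(format_study_text(x), sep = "\n")
  invisible(x)
}

#' @export
summary.nail_study <- function(object, ...) {
  s <- object$stats
  list(n = s$n, rates = s$rates, mcnemar = s$mcnemar,
       arr_nnt = s$arr_nnt, roc = s$roc)
}

#' Human-readable study report
#' @param study a `nail_study`.
#' @return character vector of report lines.
#' @export
format_study_text <- function(study) {
  s <- study$stats
  L <- c(sprintf("Virtual nailing study: n = %d shoulders (%d excluded)",
                 s$n, nrow(study$exclusions)),
         "", "Morphometrics (mean +- SD, median, range):")
  for (i in seq_len(nrow(s$morphometrics))) {
    m <- s$morphometrics[i, ]
    L <- c(L, sprintf("  %-6s %6.3f +- %.3f, median %.3f, range %.3f-%.3f",
                      m$metric, m$mean, m$sd, m$median, m$min, m$max))
  }
  L <- c(L, "", "Collision rates:")
  for (i in seq_len(nrow(s$rates))) {
    r <- s$rates[i, ]
    L <- c(L, sprintf("  %2g deg extension: %d/%d = %.1f%% (95%% CI %.1f-%.1f)",
                      r$extension_deg, r$collisions, r$n, 100 * r$rate,
                      100 * r$ci_low, 100 * r$ci_high))
  }
  if (!is.null(s$mcnemar))
    L <- c(L, sprintf("  McNemar chi2 = %.2f, p %s (b = %d, c = %d)",
                      s$mcnemar$chi2,
                      format.pval(s$mcnemar$p, digits = 3, eps = 1e-3),
                      s$mcnemar$b, s$mcnemar$c))
  if (!is.null(s$arr_nnt))
    L <- c(L, sprintf("  ARR = %.1f%%, NNT = %.2f", 100 * s$arr_nnt$arr,
                      s$arr_nnt$nnt))
  if (!is.null(s$or_sex))
    L <- c(L, sprintf("  OR male vs female: %.2f (CI %.2f-%.2f), Fisher p = %.2f",
                      s$or_sex$or, s$or_sex$ci_low, s$or_sex$ci_high,
                      s$or_sex$fisher_p))
  if (!is.null(s$or_side))
    L <- c(L, sprintf("  OR left vs right: %.2f (CI %.2f-%.2f), Fisher p = %.2f",
                      s$or_side$or, s$or_side$ci_low, s$or_side$ci_high,
                      s$or_side$fisher_p))
  if (!is.null(s$logistic_univariable)) {
    ai <- s$logistic_univariable$or
    ai <- ai[ai$term == "AI", ]
    L <- c(L, sprintf("  AI logistic OR per +0.10: %.2f (CI %.2f-%.2f)",
                      ai$or_per_0_1, ai$or_per_0_1_ci_low,
                      ai$or_per_0_1_ci_high))
  }
  if (!is.null(s$roc))
    L <- c(L, sprintf("  ROC AUC %.3f; Youden threshold AI >= %.3f (sens %.0f%%, spec %.0f%%)",
                      s$roc$auc, s$roc$threshold, 100 * s$roc$sensitivity,
                      100 * s$roc$specificity))
  if (length(s$notice)) L <- c(L, paste("  NOTE:", s$notice))
  L
}

#' Write study outputs (CSV table, JSON stats, provenance)
#'
#' @param study a `nail_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$per_shoulder,
                   file.path(dir, "per_shoulder.csv"), row.names = FALSE)
  ser <- study$stats
  ser$logistic_univariable <- strip_glm(ser$logistic_univariable)
  ser$logistic_adjusted <- strip_glm(ser$logistic_adjusted)
  ser$logistic_interactions <- strip_glm(ser$logistic_interactions)
  ser$roc$curve <- NULL
  jsonlite::write_json(ser, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  cfgfile <- file.path(dir, "config.json")
  cfg <- study$config
  cfg$cohort$base_params <- unclass(cfg$cohort$base_params)
  cfg$cohort <- unclass(cfg$cohort)
  jsonlite::write_json(unclass(cfg), cfgfile, auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  prov <- list(config_md5 = unname(tools::md5sum(cfgfile)),
               seed = study$config$seed,
               package_version = as.character(utils::packageVersion("nailsim")),
               schema = "nailsim-run-1")
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  writeLines(format_study_text(study), file.path(dir, "report.txt"))
  if (nrow(study$exclusions))
    utils::write.csv(study$exclusions, file.path(dir, "exclusions.csv"),
                     row.names = FALSE)
  invisible(dir)
}

strip_glm <- function(lf) {
  if (is.null(lf)) return(NULL)
  lf$glm <- NULL
  unclass(lf)
}

#' Write a cohort to disk as surface meshes + landmark JSON + ground truth
#'
#' Meshes are written both as PLY (indexed; the landmark JSON refers to its
#' vertex numbering) and as binary STL for interoperability. STL stores an
#' unindexed triangle soup, so landmark vertex indices are only meaningful
#' against the PLY files, which [read_cohort_dir()] uses.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$shoulders)) {
    id <- cohort$table$shoulder_id[i]
    sh <- cohort$shoulders[[i]]$shoulder
    write_mesh(sh$humerus, file.path(dir, paste0(id, "_humerus.ply")))
    write_mesh(sh$scapula, file.path(dir, paste0(id, "_scapula.ply")))
    write_mesh(sh$humerus, file.path(dir, paste0(id, "_humerus.stl")))
    write_mesh(sh$scapula, file.path(dir, paste0(id, "_scapula.stl")))
    jsonlite::write_json(c(sh$landmarks, list(side = sh$side)),
                         file.path(dir, paste0(id, "_landmarks.json")),
                         auto_unbox = FALSE)
  }
  truth <- cbind(cohort$table,
                 do.call(rbind, lapply(cohort$shoulders, function(s)
                   data.frame(GA_true = s$truth$GA_mm,
                              GH_true = s$truth$GH_mm,
                              AI_true = s$truth$AI,
                              clearance_0_true = s$truth$clearance_0_mm,
                              clearance_30_true = s$truth$clearance_30_mm))))
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_dir()]
#' @param dir the directory.
#' @return list with `shoulders` and `table` (as for [generate_cohort()],
#'   without ground truth).
#' @export
read_cohort_dir <- function(dir) {
  lm_files <- sort(list.files(dir, pattern = "_landmarks\\.json$",
                              full.names = TRUE))
  if (!length(lm_files)) stop("no *_landmarks.json files in ", dir)
  ids <- sub("_landmarks\\.json$", "", basename(lm_files))
  shoulders <- list(); rows <- list()
  truth_csv <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_csv))
    utils::read.csv(truth_csv, stringsAsFactors = FALSE) else NULL
  for (i in seq_along(ids)) {
    lm <- jsonlite::read_json(lm_files[i], simplifyVector = TRUE)
    side <- if (!is.null(lm$side)) lm$side[[1]] else "right"
    lm$side <- NULL
    hum <- read_mesh(file.path(dir, paste0(ids[i], "_humerus.ply")))
    sca <- read_mesh(file.path(dir, paste0(ids[i], "_scapula.ply")))
    shoulders[[i]] <- list(shoulder = shoulder_model(
      hum, sca, lapply(lm, as.integer), side = side))
    tr <- if (!is.null(truth)) truth[truth$shoulder_id == ids[i], ] else NULL
    rows[[i]] <- data.frame(
      shoulder_id = ids[i], side = side,
      sex = if (!is.null(tr) && nrow(tr)) tr$sex else NA_character_,
      age_years = if (!is.null(tr) && nrow(tr)) tr$age_years else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(shoulders = shoulders, table = do.call(rbind, rows))
}
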