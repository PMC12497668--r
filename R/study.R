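# Study pipeline: simulate a cohort, compute every ALPS index for both
# methods and all ROI configurations, run the reliability battery, and
# render result tables.

STUDY_ANALYSES <- c("descriptive", "interhemispheric", "inter_config",
                    "inter_method", "icc", "icc_matrix", "bland_altman")

#' Study configuration
#'
#' @param spec A [phantom_spec()] defining the cohort's ground truth.
#' @param n_subjects Number of subjects (default 13, the emulated study's
#'   sample size; at least 5 when ICC analyses are requested).
#' @param configs ROI configuration names to run (default: all eleven).
#' @param seed Master seed; it fans out deterministically to the phantom,
#'   per-subject acquisitions and every Monte Carlo procedure.
#' @param analyses Analyses to run (default all): any of
#'   `"descriptive"`, `"interhemispheric"`, `"inter_config"`,
#'   `"inter_method"`, `"icc"`, `"icc_matrix"`, `"bland_altman"`.
#' @return Object of class `study_config`.
#' @export
study_config <- function(spec = phantom_spec(), n_subjects = 13L,
                         configs = NULL, seed = 20250411L,
                         analyses = STUDY_ANALYSES) {
  configs <- configs %||% ROI_NAMES
  analyses <- match.arg(analyses, STUDY_ANALYSES, several.ok = TRUE)
  if (!all(configs %in% ROI_NAMES)) {
    stopf("unknown configuration(s): %s",
          paste(setdiff(configs, ROI_NAMES), collapse = ", "))
  }
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive integer")
  if (n_subjects < 5 && any(c("icc", "icc_matrix") %in% analyses)) {
    stopf("n_subjects must be >= 5 for ICC analyses")
  }
  structure(list(spec = spec, n_subjects = as.integer(n_subjects),
                 configs = configs, seed = as.integer(seed),
                 analyses = analyses),
            class = "study_config")
}

quiet_wsr_p <- function(a, b) {
  suppressWarnings(wilcoxon_signed_rank(a, b)$p.value)
}

#' Run the full ROI-reliability study
#'
#' Simulates the cohort, fits the tensor (64-direction arm) and the
#' directional ADCs (3-direction arm) per subject, places every ROI
#' configuration in both hemispheres, computes all ALPS indices, and runs
#' the requested analyses: pooled descriptives; interhemispheric Wilcoxon
#' per configuration and method (table1); inter-method Wilcoxon on
#' hemisphere-averaged indices (table2); inter-method ICC(2,1) with F test
#' and CI per configuration (table3); the pairwise inter-configuration ICC
#' matrix per method with category counts; inter-configuration Wilcoxon
#' comparisons per hemisphere and method, from which the "stable"
#' configuration subset is recomputed; and pooled Bland-Altman agreement.
#' Deterministic given the master seed. Configurations that cannot be
#' placed are dropped with a logged reason.
#'
#' @param cfg A [study_config()].
#' @return Object of class `alps_study`; see the components listed above,
#'   plus `results` (every index, traceable to subject, hemisphere,
#'   method and configuration), `placements`, `dropped` and `notes`.
#' @export
run_study <- function(cfg = study_config()) {
  if (!inherits(cfg, "study_config")) stopf("cfg must be a study_config")
  spec <- cfg$spec
  spec$seed <- split_seed(cfg$seed, 11)
  notes <- character()

  cohort <- simulate_cohort(spec, cfg$n_subjects)
  labels <- build_labels(spec)
  slice <- alps_slice(labels)
  placements <- place_study_rois(labels, cfg$configs, slice)
  dropped <- attr(placements, "dropped")
  if (nrow(dropped) > 0) {
    notes <- c(notes, sprintf("dropped %s: %s", dropped$config, dropped$error))
  }

  results <- purrr::map_dfr(cohort$subjects, function(subj) {
    tf <- fit_tensor_loglinear(subj$dwi64)
    adc <- directional_adc(subj$dwi3)
    dplyr::bind_rows(
      subject_alps(tf, placements, "DTI", subject_id = subj$subject),
      subject_alps(adc, placements, "DWI", subject_id = subj$subject)
    )
  })
  kept_configs <- intersect(cfg$configs, unique(results$config))
  results$config <- factor(results$config, levels = kept_configs)

  avg <- hemisphere_average(results)
  out <- list(config = cfg, slice = slice, placements = placements,
              dropped = dropped, results = results,
              hemisphere_averaged = avg)

  if ("descriptive" %in% cfg$analyses) {
    out$descriptives <- pooled_descriptives(results)
  }
  if ("interhemispheric" %in% cfg$analyses) {
    ih <- tidyr::pivot_wider(
      dplyr::select(results, "method", "config", "subject", "hemisphere", "index"),
      names_from = "hemisphere", values_from = "index"
    )
    out$table1 <- dplyr::summarise(
      dplyr::group_by(ih, .data$method, .data$config),
      p = quiet_wsr_p(.data$right, .data$left), .groups = "drop"
    ) |>
      dplyr::mutate(sig = ifelse(.data$p < 0.05, "*", ""))
  }
  if ("inter_method" %in% cfg$analyses) {
    im <- tidyr::pivot_wider(avg, names_from = "method",
                             values_from = "index")
    out$table2 <- dplyr::summarise(
      dplyr::group_by(im, .data$config),
      p = quiet_wsr_p(.data$DTI, .data$DWI), .groups = "drop"
    ) |>
      dplyr::mutate(sig = ifelse(.data$p < 0.05, "*", ""))
  }
  if ("icc" %in% cfg$analyses) {
    out$table3 <- purrr::map_dfr(kept_configs, function(cf) {
      w <- tidyr::pivot_wider(
        dplyr::select(
          dplyr::filter(results, .data$config == cf),
          "subject", "hemisphere", "method", "index"
        ),
        names_from = "method", values_from = "index"
      )
      ic <- icc_2_1(as.matrix(w[, c("DTI", "DWI")]))
      tibble(config = cf, icc = ic$icc, f_p = ic$f_p,
             ci_lower = ic$ci_lower, ci_upper = ic$ci_upper,
             wald_lower = ic$wald_lower, wald_upper = ic$wald_upper,
             category = ic$category,
             sig = ifelse(!is.na(ic$f_p) & ic$f_p < 0.05, "*", ""))
    })
    out$table3$config <- factor(out$table3$config, levels = kept_configs)
  }
  if ("icc_matrix" %in% cfg$analyses) {
    mats <- purrr::map_dfr(c("DTI", "DWI"), function(m) {
      wide <- tidyr::pivot_wider(
        dplyr::select(
          dplyr::filter(results, .data$method == m),
          "subject", "hemisphere", "config", "index"
        ),
        names_from = "config", values_from = "index"
      )
      prs <- combn(kept_configs, 2)
      purrr::map_dfr(seq_len(ncol(prs)), function(j) {
        ic <- icc_2_1(as.matrix(wide[, prs[, j]]))
        tibble(method = m, config_a = prs[1, j], config_b = prs[2, j],
               icc = ic$icc, category = ic$category)
      })
    })
    out$icc_matrix <- mats
    n_pairs <- choose(length(kept_configs), 2)
    out$icc_pair_summary <- purrr::map_dfr(c("DTI", "DWI"), function(m) {
      mm <- mats[mats$method == m, ]
      cat_counts <- table(factor(mm$category,
                                 levels = c("poor", "moderate", "good",
                                            "excellent")))
      tibble(method = m, category = names(cat_counts),
             count = as.integer(cat_counts),
             percent = 100 * as.integer(cat_counts) / n_pairs)
    })
  }
  if ("inter_config" %in% cfg$analyses) {
    out$inter_config <- purrr::map_dfr(c("DTI", "DWI"), function(m) {
      purrr::map_dfr(c("left", "right"), function(h) {
        wide <- tidyr::pivot_wider(
          dplyr::select(
            dplyr::filter(results, .data$method == m, .data$hemisphere == h),
            "subject", "config", "index"
          ),
          names_from = "config", values_from = "index"
        )
        prs <- combn(kept_configs, 2)
        purrr::map_dfr(seq_len(ncol(prs)), function(j) {
          tibble(method = m, hemisphere = h,
                 config_a = prs[1, j], config_b = prs[2, j],
                 p = quiet_wsr_p(wide[[prs[1, j]]], wide[[prs[2, j]]]))
        })
      })
    }) |>
      dplyr::mutate(sig = ifelse(.data$p < 0.05, "*", ""))
  }
  if (all(c("interhemispheric", "inter_method") %in% cfg$analyses)) {
    ih_ok <- dplyr::summarise(
      dplyr::group_by(out$table1, .data$config),
      ok = all(.data$p > 0.05), .groups = "drop"
    )
    im_ok <- dplyr::transmute(out$table2, config = .data$config,
                              ok2 = .data$p > 0.05)
    st <- dplyr::left_join(ih_ok, im_ok, by = "config")
    out$stable_configs <- as.character(st$config[st$ok & st$ok2])
  }
  if ("bland_altman" %in% cfg$analyses) {
    w <- tidyr::pivot_wider(avg, names_from = "method", values_from = "index")
    out$bland_altman <- bland_altman(w$DTI, w$DWI)
  }
  out$notes <- notes
  structure(out, class = "alps_study")
}

#' Pooled descriptive statistics per method
#'
#' Pools every (subject, hemisphere, configuration) index per method and
#' reports mean, median, quartiles and outliers by the 1.5 IQR rule, the
#' box-plot summary used to compare the two methods.
#'
#' @param results Results tibble (from [run_study()] or [subject_alps()]).
#' @return Tibble with one row per method.
#' @export
pooled_descriptives <- function(results) {
  if (nrow(results) == 0) stopf("no results to describe")
  dplyr::summarise(
    dplyr::group_by(results, .data$method),
    n = dplyr::n(),
    mean = mean(.data$index),
    median = median(.data$index),
    q1 = unname(quantile(.data$index, 0.25)),
    q3 = unname(quantile(.data$index, 0.75)),
    min = min(.data$index),
    max = max(.data$index),
    n_outliers = {
      iqr <- quantile(.data$index, 0.75) - quantile(.data$index, 0.25)
      lo <- quantile(.data$index, 0.25) - 1.5 * iqr
      hi <- quantile(.data$index, 0.75) + 1.5 * iqr
      sum(.data$index < lo | .data$index > hi)
    },
    outliers = {
      iqr <- quantile(.data$index, 0.75) - quantile(.data$index, 0.25)
      lo <- quantile(.data$index, 0.25) - 1.5 * iqr
      hi <- quantile(.data$index, 0.75) + 1.5 * iqr
      paste(signif(.data$index[.data$index < lo | .data$index > hi], 6),
            collapse = ";")
    },
    .groups = "drop"
  )
}

#' Render a study report to files
#'
#' Writes each result table as CSV (deterministic bytes: rerunning the
#' same seeded study reproduces identical files), the whole report as
#' JSON, and, optionally, the three standard figures.
#'
#' @param report An `alps_study`.
#' @param dir Output directory (created if missing).
#' @param fmt Any of `"csv"`, `"json"`.
#' @param plots Also write box, ICC-profile and Bland-Altman figures as
#'   PNG.
#' @return Invisible character vector of the files written.
#' @export
render_report <- function(report, dir, fmt = c("csv", "json"),
                          plots = FALSE) {
  if (!inherits(report, "alps_study")) stopf("report must be an alps_study")
  fmt <- match.arg(fmt, c("csv", "json"), several.ok = TRUE)
  if (!all(fmt %in% c("csv", "json"))) stopf("unknown format")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  tables <- list(
    results = report$results,
    descriptives = report$descriptives,
    table1_interhemispheric = report$table1,
    table2_inter_method = report$table2,
    table3_inter_method_icc = report$table3,
    icc_matrix = report$icc_matrix,
    icc_pair_summary = report$icc_pair_summary,
    inter_config = report$inter_config
  )
  if (!is.null(report$bland_altman)) {
    ba <- report$bland_altman
    tables$bland_altman <- tibble(bias = ba$bias, sd_diff = ba$sd_diff,
                                  loa_lower = ba$loa_lower,
                                  loa_upper = ba$loa_upper, n = ba$n)
  }
  tables <- purrr::compact(tables)
  if ("csv" %in% fmt) {
    for (nm in names(tables)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(tables[[nm]], path)
      files <- c(files, path)
    }
  }
  if ("json" %in% fmt) {
    path <- file.path(dir, "report.json")
    payload <- c(
      purrr::map(tables, as.data.frame),
      list(stable_configs = report$stable_configs %||% character(),
           dropped = as.data.frame(report$dropped),
           notes = report$notes, seed = report$config$seed)
    )
    jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                         pretty = TRUE, null = "null")
    files <- c(files, path)
  }
  if (plots) {
    figs <- list(
      box = plot_alps_distribution(report$results),
      icc = if (!is.null(report$table3)) plot_icc_profile(report$table3),
      bland_altman = if (!is.null(report$bland_altman))
        plot_bland_altman(report$bland_altman)
    )
    for (nm in names(purrr::compact(figs))) {
      path <- file.path(dir, paste0(nm, ".png"))
      ggplot2::ggsave(path, figs[[nm]], width = 6, height = 4, dpi = 150)
      files <- c(files, path)
    }
  }
  invisible(files)
}

#' @export
print.alps_study <- function(x, ...) {
  cat(sprintf("<alps_study> %d subjects, %d configurations, seed %d\n",
              x$config$n_subjects, length(unique(x$results$config)),
              x$config$seed))
  if (!is.null(x$descriptives)) {
    d <- x$descriptives
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %s ALPS: mean %.3f, median %.3f [q1 %.3f, q3 %.3f]\n",
                  d$method[i], d$mean[i], d$median[i], d$q1[i], d$q3[i]))
    }
  }
  if (!is.null(x$table3)) {
    cat(sprintf("  inter-method ICC: mean %.3f (range %.3f-%.3f)\n",
                mean(x$table3$icc), min(x$table3$icc), max(x$table3$icc)))
  }
  if (!is.null(x$bland_altman)) {
    cat(sprintf("  Bland-Altman bias %.4f, LOA [%.4f, %.4f]\n",
                x$bland_altman$bias, x$bland_altman$loa_lower,
                x$bland_altman$loa_upper))
  }
  if (!is.null(x$stable_configs)) {
    cat("  stable configurations:",
        paste(x$stable_configs, collapse = ", "), "\n")
  }
  if (nrow(x$dropped) > 0) {
    cat("  dropped:", paste(unique(x$dropped$config), collapse = ", "), "\n")
  }
  invisible(x)
}
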