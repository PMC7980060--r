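#' Assemble a full pipeline run configuration
#'
#' A single configuration drives the end-to-end analysis: generate (or
#' load) a cohort, impute, weight, estimate all requested research
#' questions, pool across imputations, and write reports.
#'
#' @param input `"synthetic"` or a path to a cohort CSV.
#' @param dictionary Path to the data dictionary (YAML/JSON) when
#'   `input` is a file.
#' @param generator A [generator_config()] (used when synthetic).
#' @param causal A [causal_spec()]; defaults to the synthetic layout.
#' @param imputation An [imputation_config()].
#' @param design A [design_spec()] or `NULL`.
#' @param questions Subset of 1:3.
#' @param output_dir Where results are written.
#' @param seed Master seed for the run.
#' @param scale_factor 1 (SD units) or 100 (SD x 100 display).
#' @param standardize Standardize outcomes before estimation.
#' @param sensitivity Optional named list of variants; each entry may
#'   override `confounders_post` (e.g. a reduced post-exposure
#'   adjustment set) and is rerun and written under its own label.
#' @export
run_config <- function(input = "synthetic", dictionary = NULL,
                       generator = generator_config(),
                       causal = NULL,
                       imputation = imputation_config(),
                       design = design_spec(),
                       questions = 1:3,
                       output_dir = tempfile("ipwcde_run_"),
                       seed = generator$seed,
                       scale_factor = 1,
                       standardize = TRUE,
                       sensitivity = NULL) {
  if (length(questions) == 0) stop("`questions` must be nonempty", call. = FALSE)
  stopifnot(all(questions %in% 1:3))
  if (is.null(causal)) causal <- default_causal_spec(generator)
  structure(list(input = input, dictionary = dictionary, generator = generator,
                 causal = causal, imputation = imputation, design = design,
                 questions = sort(unique(questions)), output_dir = output_dir,
                 seed = as.integer(seed), scale_factor = scale_factor,
                 standardize = isTRUE(standardize), sensitivity = sensitivity),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror [run_config()]; `generator`, `imputation`,
#' `design` and `causal` blocks are passed as argument lists to their
#' constructors.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("input", "dictionary", "questions", "output_dir", "seed",
              "scale_factor", "standardize", "sensitivity")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$generator)) {
    g <- y$generator
    # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
    names(g)[names(g) %in% c("FALSE", "no")] <- "n"
    args$generator <- do.call(generator_config, g)
  }
  if (!is.null(y$causal)) args$causal <- do.call(causal_spec, y$causal)
  if (!is.null(y$imputation)) args$imputation <- do.call(imputation_config, y$imputation)
  if (!is.null(y$design)) args$design <- do.call(design_spec, y$design)
  do.call(run_config, args)
}

#' Load and validate an external cohort against a data dictionary
#'
#' Reads the CSV and dictionary, coerces declared types, and validates
#' the result, reporting every schema violation at once rather than the
#' first failure.  The returned cohort carries a per-column missingness
#' summary as attribute `missingness`.
#'
#' @param path Cohort CSV.
#' @param dictionary Path to a YAML/JSON dictionary (column -> role,
#'   type, levels, reference) or an already-parsed list.
#' @export
validate_input <- function(path, dictionary) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  dict <- if (is.character(dictionary)) {
    if (grepl("\\.json$", dictionary, ignore.case = TRUE)) {
      jsonlite::read_json(dictionary, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(dictionary)
    }
  } else {
    dictionary
  }
  dict <- lapply(dict, function(e) { e$levels <- unlist(e$levels); e })
  for (cn in names(dict)) {
    if (!cn %in% names(d)) next
    if (identical(dict[[cn]]$type, "categorical") && !is.null(dict[[cn]]$levels)) {
      lv <- dict[[cn]]$levels
      ok <- is.na(d[[cn]]) | as.character(d[[cn]]) %in% lv
      if (all(ok)) d[[cn]] <- factor(d[[cn]], levels = lv)
      # otherwise leave as character so validate_cohort names the levels
    }
  }
  ct <- cohort_table(d, dict)
  attr(ct, "missingness") <- missingness_summary(ct)
  ct
}

write_effect_tbl <- function(x, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(x), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(x), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(x)
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", label, "] ", conditionMessage(e), call. = FALSE)
  })
}

run_one_variant <- function(cohort_list, config, spec, label, outdir) {
  results <- list()
  for (q in config$questions) {
    per_imp <- stage(paste0("estimate q", q), lapply(cohort_list, function(ci) {
      run_question(ci, spec, q, design = config$design,
                   standardize = config$standardize,
                   scale_factor = config$scale_factor)
    }))
    tab <- if (length(per_imp) >= 2) pool(per_imp) else {
      x <- per_imp[[1]]; x$m <- 1L; x
    }
    fn <- file.path(outdir, sprintf("question%d_%s.csv", q, label))
    write_effect_tbl(tab, fn, sub("\\.csv$", ".json", fn))
    results[[paste0("q", q)]] <- tab
  }
  results
}

#' Run the full analysis pipeline
#'
#' Generate or load -> impute -> weight -> estimate -> pool -> report.
#' Writes per-question pooled estimate tables (CSV + JSON), balance
#' reports, weight summaries and a run manifest into
#' `config$output_dir`.  Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the pooled tables per question (and
#'   per sensitivity variant), balance reports, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$causal

  cohort <- stage("input", {
    if (identical(config$input, "synthetic")) {
      g <- config$generator
      co <- generate_cohort(g, seed = config$seed)
      co <- assign_design(co, g, seed = config$seed)
      co <- apply_missingness(co, g, seed = config$seed)
      co
    } else {
      validate_input(config$input, config$dictionary)
    }
  })
  cohort <- respondents(cohort)

  imps <- stage("imputation", {
    cfg <- config$imputation
    cfg$seed <- config$seed + 3L
    if (anyNA(as.data.frame(cohort)[names(dictionary(cohort))])) {
      impute(cohort, cfg)
    } else {
      list(cohort)
    }
  })

  balance <- stage("balance", {
    first <- if (config$standardize) {
      standardize_outcomes(imps[[1]], spec, scale_factor = config$scale_factor)
    } else {
      imps[[1]]
    }
    fold <- function(ws) if (is.null(config$design)) ws else
      combine_weights(ws, config$design, first)
    list(
      ate = balance_report(first, fold(ate_weights(first, spec)), spec),
      total_effect = balance_report(first, fold(total_effect_weights(first, spec)), spec),
      cde = balance_report(first, fold(cde_weights(first, spec)), spec)
    )
  })
  for (nm in names(balance)) {
    write_balance_report(balance[[nm]],
                         file.path(outdir, paste0("balance_", nm, ".csv")),
                         file.path(outdir, paste0("weights_", nm, ".json")))
  }

  results <- list(main = run_one_variant(imps, config, spec, "main", outdir))

  warnings_log <- character(0)
  for (nm in names(balance)) {
    bad <- balance[[nm]]
    bad <- bad[abs(bad$smd_after) > (attr(bad, "threshold") %||% 0.1), , drop = FALSE]
    if (nrow(bad) > 0) {
      warnings_log <- c(warnings_log, sprintf(
        "residual imbalance (%s): %s", nm,
        paste(unique(paste0(bad$confounder, "@", bad$stratum)), collapse = ", ")))
    }
  }

  if (!is.null(config$sensitivity)) {
    for (vn in names(config$sensitivity)) {
      var <- config$sensitivity[[vn]]
      vspec <- spec
      if (!is.null(var$confounders_post)) vspec$confounders_post <- var$confounders_post
      if (!is.null(var$confounders_pre)) vspec$confounders_pre <- var$confounders_pre
      results[[vn]] <- stage(paste0("sensitivity:", vn),
                             run_one_variant(imps, config, vspec, vn, outdir))
    }
  }

  manifest <- list(
    seed = config$seed,
    questions = config$questions,
    input = config$input,
    n_imputations = length(imps),
    n_respondents = nrow(cohort),
    scale_factor = config$scale_factor,
    adjustment_sets = c(
      list(main = list(confounders_pre = spec$confounders_pre,
                       confounders_post = spec$confounders_post)),
      lapply(config$sensitivity %||% list(), function(v) {
        list(confounders_pre = v$confounders_pre %||% spec$confounders_pre,
             confounders_post = v$confounders_post %||% spec$confounders_post)
      })
    ),
    config_hash = config_hash(config),
    warnings = warnings_log,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ipwcde"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(results = results, balance = balance, manifest = manifest,
                 output_dir = outdir))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}
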