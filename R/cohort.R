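#' Cohort tables and the role dictionary
#'
#' A `cohort_table` is a plain `data.frame` of one row per child together
#' with a *role dictionary*: a named list with one entry per column giving
#' its analysis role and type.  Roles are
#' `exposure`, `mediator`, `confounder_pre`, `confounder_post`, `outcome`,
#' `stratum`, `cluster`, `design_weight`, or `auxiliary`; types are
#' `binary`, `categorical`, or `continuous`.  Categorical entries carry
#' `levels` and a `reference` level.
#'
#' @param data data.frame of person-level records.
#' @param dictionary named list; one entry per analysis column, each a list
#'   with elements `role`, `type`, and for categorical columns `levels`
#'   and `reference`.
#' @return An object of class `cohort_table` (a data.frame with a
#'   `dictionary` attribute).
#' @examples
#' d <- data.frame(x = c(0, 1), y = c(0.2, -0.1))
#' dict <- list(
#'   x = list(role = "exposure", type = "binary"),
#'   y = list(role = "outcome", type = "continuous")
#' )
#' ct <- cohort_table(d, dict)
#' roles(ct)
#' @export
cohort_table <- function(data, dictionary) {
  problems <- validate_cohort(data, dictionary)
  if (length(problems) > 0L) {
    stop("invalid cohort table:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(as.data.frame(data), dictionary = dictionary,
            class = c("cohort_table", "data.frame"))
}

COHORT_ROLES <- c("exposure", "mediator", "confounder_pre", "confounder_post",
                  "outcome", "stratum", "cluster", "design_weight", "auxiliary")
COHORT_TYPES <- c("binary", "categorical", "continuous")

#' Validate a data.frame against a role dictionary
#'
#' Collects *all* violations rather than stopping at the first, so a user
#' can fix a malformed input in one pass.
#'
#' @inheritParams cohort_table
#' @return Character vector of problems; `character(0)` when valid.
#' @export
validate_cohort <- function(data, dictionary) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  if (!is.data.frame(data)) return("`data` is not a data.frame")
  if (is.null(names(dictionary)) || any(names(dictionary) == "")) {
    return("dictionary entries must be named by column")
  }
  for (col in names(dictionary)) {
    entry <- dictionary[[col]]
    if (!col %in% names(data)) {
      note("column `", col, "` declared in dictionary but absent from data")
      next
    }
    if (is.null(entry$role) || !entry$role %in% COHORT_ROLES) {
      note("column `", col, "`: unknown role `", entry$role %||% "<missing>", "`")
    }
    if (is.null(entry$type) || !entry$type %in% COHORT_TYPES) {
      note("column `", col, "`: unknown type `", entry$type %||% "<missing>", "`")
      next
    }
    v <- data[[col]]
    obs <- v[!is.na(v)]
    if (entry$type == "binary" && length(obs) > 0 && !all(obs %in% c(0, 1))) {
      note("column `", col, "`: binary column has values outside {0, 1}")
    }
    if (entry$type == "continuous" && !is.numeric(v)) {
      note("column `", col, "`: continuous column is not numeric")
    }
    if (entry$type == "categorical") {
      lv <- entry$levels
      if (is.null(lv)) {
        note("column `", col, "`: categorical column lacks declared levels")
      } else {
        extra <- setdiff(unique(as.character(obs)), lv)
        if (length(extra) > 0) {
          note("column `", col, "`: undeclared level(s) ",
               paste0("`", extra, "`", collapse = ", "))
        }
        if (!is.null(entry$reference) && !entry$reference %in% lv) {
          note("column `", col, "`: reference `", entry$reference,
               "` not among declared levels")
        }
      }
    }
    if (identical(entry$role, "design_weight") && length(obs) > 0 &&
        (any(!is.finite(obs)) || any(obs <= 0))) {
      note("column `", col, "`: design weights must be positive and finite")
    }
  }
  # cluster nesting: each cluster id must sit inside exactly one stratum
  dcols <- names(dictionary)
  strat <- dcols[vapply(dictionary, function(e) identical(e$role, "stratum"), logical(1))]
  clus  <- dcols[vapply(dictionary, function(e) identical(e$role, "cluster"), logical(1))]
  if (length(strat) == 1 && length(clus) == 1 &&
      all(c(strat, clus) %in% names(data))) {
    tab <- unique(data.frame(s = data[[strat]], cl = data[[clus]]))
    dup <- tab$cl[duplicated(tab$cl)]
    if (length(dup) > 0) {
      note("cluster id(s) ", paste0("`", unique(dup), "`", collapse = ", "),
           " appear in more than one stratum")
    }
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_table <- function(x, ...) {
  dict <- attr(x, "dictionary")
  cat("cohort_table:", nrow(x), "children,", length(dict), "analysis columns\n")
  rl <- vapply(dict, function(e) e$role, character(1))
  for (r in intersect(COHORT_ROLES, unique(rl))) {
    cat(sprintf("  %-15s %s\n", r, paste(names(rl)[rl == r], collapse = ", ")))
  }
  miss <- vapply(names(dict), function(cn) mean(is.na(x[[cn]])), numeric(1))
  if (any(miss > 0)) {
    cat("  missingness: ",
        paste(sprintf("%s %.1f%%", names(miss)[miss > 0], 100 * miss[miss > 0]),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the role dictionary / roles of a cohort table
#' @param x A `cohort_table`.
#' @return `dictionary()`: the role dictionary; `roles()`: named character
#'   vector of roles by column.
#' @export
dictionary <- function(x) attr(x, "dictionary")

#' @rdname dictionary
#' @export
roles <- function(x) {
  vapply(dictionary(x), function(e) e$role, character(1))
}

#' Columns of a cohort table holding a given role
#' @param x A `cohort_table`.
#' @param role One of the dictionary roles.
#' @export
columns_with_role <- function(x, role) {
  rl <- roles(x)
  names(rl)[rl == role]
}

#' Per-column missingness summary
#'
#' @param x A `cohort_table`.
#' @return data.frame with columns `column`, `n_missing`,
#'   `prop_missing` (the analogue of a descriptive "proportion missing"
#'   table for an analytic sample).
#' @export
missingness_summary <- function(x) {
  cols <- names(dictionary(x))
  data.frame(
    column = cols,
    n_missing = vapply(cols, function(cn) sum(is.na(x[[cn]])), integer(1)),
    prop_missing = vapply(cols, function(cn) mean(is.na(x[[cn]])), numeric(1)),
    row.names = NULL
  )
}

#' Write a cohort table to CSV plus a data dictionary
#'
#' The dictionary is serialized to YAML (or JSON if the path ends in
#' `.json`), mapping each column to its role, type, levels and reference
#' level, so the pair round-trips through [validate_input()].
#'
#' @param cohort A `cohort_table`.
#' @param csv_path Path for the CSV data file.
#' @param dict_path Path for the dictionary (`.yaml`/`.yml` or `.json`).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, csv_path, dict_path) {
  utils::write.csv(as.data.frame(cohort)[, union(names(dictionary(cohort)),
                                                 names(cohort))],
                   csv_path, row.names = FALSE)
  dict <- dictionary(cohort)
  if (grepl("\\.json$", dict_path, ignore.case = TRUE)) {
    jsonlite::write_json(dict, dict_path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(dict, dict_path)
  }
  invisible(c(csv = csv_path, dictionary = dict_path))
}

#' Restrict a designed cohort to follow-up respondents
#'
#' Attrition to follow-up is handled by analysing respondents with an
#' inverse-probability-of-response weight folded into the design weight;
#' this helper drops the non-respondents ahead of estimation.
#'
#' @param cohort A `cohort_table` carrying a `responded` column (as added
#'   by [assign_design()]).  Cohorts without the column pass through.
#' @export
respondents <- function(cohort) {
  if (!"responded" %in% names(cohort)) return(cohort)
  keep <- cohort$responded == 1
  out <- cohort[keep, , drop = FALSE]
  attr(out, "dictionary") <- dictionary(cohort)
  class(out) <- class(cohort)
  out
}
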