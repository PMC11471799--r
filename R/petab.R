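# Readers and writers for the on-disk problem layout: a strict, documented
# subset of the PEtab parameter-estimation format — four TSV tables
# (conditions, observables, parameters, measurements) bound by a YAML file.
# The dialect is deliberately narrow so that validation can be exhaustive:
# exact headers, TSV, UTF-8, Unix newlines, floats with 17 significant
# digits, rows sorted by their identifier columns (so repeated writes are
# byte-identical). The measurement time column is in dpf; simulation time
# zero corresponds to 2 dpf.

petab_headers <- list(
  conditions = c("conditionId", "s_on"),
  observables = c("observableId", "observableFormula", "noiseFormula"),
  parameters = c("parameterId", "parameterScale", "lowerBound",
                 "upperBound", "nominalValue", "estimate"),
  measurements = c("observableId", "simulationConditionId", "time",
                   "replicateId", "measurement"))

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_det <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a calibration problem as a PEtab-style directory
#'
#' Serializes the four tables plus the binding \code{problem.yaml}.
#' Serialization is deterministic (sorted identifiers, fixed float format),
#' so writing the same problem twice produces byte-identical files.
#'
#' @param problem a \code{\link{make_problem}} object.
#' @param directory output directory (created if missing).
#' @return A \code{problem_bundle} (invisibly): paths plus the problem.
#' @export
write_problem <- function(problem, directory) {
  stopifnot(inherits(problem, "calibration_problem"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  conds <- problem$conditions[order(problem$conditions$condition_id), ]
  write_tsv_det(data.frame(conditionId = conds$condition_id,
                           s_on = fmt_num(conds$s_on)),
                file.path(directory, "conditions.tsv"))
  obs <- problem$observables[order(problem$observables$observable_id), ]
  write_tsv_det(data.frame(
    observableId = obs$observable_id,
    observableFormula = paste0("s_", obs$observable_id, " * ", obs$species),
    noiseFormula = paste0("sigma_", obs$observable_id)),
    file.path(directory, "observables.tsv"))
  par <- problem$parameters[order(problem$parameters$parameter_id), ]
  write_tsv_det(data.frame(
    parameterId = par$parameter_id, parameterScale = par$scale,
    lowerBound = fmt_num(par$lower), upperBound = fmt_num(par$upper),
    nominalValue = fmt_num(par$nominal),
    estimate = as.integer(par$estimate)),
    file.path(directory, "parameters.tsv"))
  m <- problem$measurements[order(problem$measurements$observable_id,
                                  problem$measurements$condition_id,
                                  problem$measurements$time_dpf,
                                  problem$measurements$replicate), ]
  write_tsv_det(data.frame(
    observableId = m$observable_id, simulationConditionId = m$condition_id,
    time = fmt_num(m$time_dpf), replicateId = as.integer(m$replicate),
    measurement = fmt_num(m$value)),
    file.path(directory, "measurements.tsv"))
  yaml_lines <- c(
    "format_version: 1",
    "parameter_file: parameters.tsv",
    "problems:",
    "- condition_files:",
    "  - conditions.tsv",
    "  measurement_files:",
    "  - measurements.tsv",
    "  observable_files:",
    "  - observables.tsv")
  con <- file(file.path(directory, "problem.yaml"), open = "wb")
  writeLines(yaml_lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(problem_bundle(directory, problem))
}

problem_bundle <- function(directory, problem) {
  structure(list(
    directory = directory,
    files = list(yaml = file.path(directory, "problem.yaml"),
                 conditions = file.path(directory, "conditions.tsv"),
                 observables = file.path(directory, "observables.tsv"),
                 parameters = file.path(directory, "parameters.tsv"),
                 measurements = file.path(directory, "measurements.tsv")),
    problem = problem), class = "problem_bundle")
}

read_table_checked <- function(path, table, problems) {
  expected <- petab_headers[[table]]
  df <- tryCatch(
    utils::read.delim(path, colClasses = "character", check.names = FALSE),
    error = function(e) NULL)
  if (is.null(df)) {
    return(list(df = NULL,
                problems = c(problems, sprintf("%s: unreadable TSV", path))))
  }
  unknown <- setdiff(names(df), expected)
  missing <- setdiff(expected, names(df))
  if (length(unknown)) {
    problems <- c(problems, sprintf("%s: unknown column(s) %s", path,
                                    paste(unknown, collapse = ", ")))
  }
  if (length(missing)) {
    problems <- c(problems, sprintf("%s: missing column(s) %s", path,
                                    paste(missing, collapse = ", ")))
  }
  list(df = if (!length(missing)) df else NULL, problems = problems)
}

parse_numeric_col <- function(df, col, path, problems) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]))
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "%s: non-numeric '%s' value(s) at data row(s) %s", path, col,
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  list(x = x, problems = problems)
}

#' Read a PEtab-style problem directory
#'
#' Parses and validates the YAML plus the four tables written by
#' \code{\link{write_problem}}. Validation is exhaustive: the error message
#' lists every violation found (missing files, unknown or missing columns,
#' non-numeric values, dangling identifiers), not just the first.
#'
#' @param directory the problem directory.
#' @return A \code{problem_bundle}: file paths plus the parsed
#'   \code{calibration_problem}.
#' @export
read_problem <- function(directory) {
  problems <- character()
  ypath <- file.path(directory, "problem.yaml")
  if (!file.exists(ypath)) {
    stop(sprintf("missing file: %s", ypath), call. = FALSE)
  }
  y <- yaml::read_yaml(ypath)
  paths <- list(
    conditions = file.path(directory, y$problems[[1]]$condition_files[[1]]),
    measurements = file.path(directory,
                             y$problems[[1]]$measurement_files[[1]]),
    observables = file.path(directory,
                            y$problems[[1]]$observable_files[[1]]),
    parameters = file.path(directory, y$parameter_file))
  absent <- !vapply(paths, file.exists, logical(1))
  if (any(absent)) {
    problems <- c(problems, sprintf("missing file: %s",
                                    unlist(paths[absent])))
  }
  stop_invalid(problems, "problem directory")
  tabs <- list()
  for (tb in names(paths)) {
    res <- read_table_checked(paths[[tb]], tb, problems)
    tabs[[tb]] <- res$df
    problems <- res$problems
  }
  stop_invalid(problems, "problem directory")

  res <- parse_numeric_col(tabs$conditions, "s_on", paths$conditions,
                           problems)
  s_on <- res$x
  problems <- res$problems
  for (col in c("lowerBound", "upperBound", "nominalValue", "estimate")) {
    res <- parse_numeric_col(tabs$parameters, col, paths$parameters,
                             problems)
    tabs$parameters[[col]] <- res$x
    problems <- res$problems
  }
  for (col in c("time", "replicateId", "measurement")) {
    res <- parse_numeric_col(tabs$measurements, col, paths$measurements,
                             problems)
    tabs$measurements[[col]] <- res$x
    problems <- res$problems
  }
  # cross references
  dangling_obs <- setdiff(tabs$measurements$observableId,
                          tabs$observables$observableId)
  if (length(dangling_obs)) {
    problems <- c(problems, sprintf(
      "%s: measurement observableId(s) not in observables table: %s",
      paths$measurements, paste(dangling_obs, collapse = ", ")))
  }
  dangling_cond <- setdiff(tabs$measurements$simulationConditionId,
                           tabs$conditions$conditionId)
  if (length(dangling_cond)) {
    problems <- c(problems, sprintf(
      "%s: measurement simulationConditionId(s) not in conditions table: %s",
      paths$measurements, paste(dangling_cond, collapse = ", ")))
  }
  species <- sub("^\\s*\\S+\\s*\\*\\s*", "",
                 tabs$observables$observableFormula)
  bad_sp <- setdiff(species, extended_species)
  if (length(bad_sp)) {
    problems <- c(problems, sprintf(
      "%s: observableFormula references unknown species: %s",
      paths$observables, paste(bad_sp, collapse = ", ")))
  }
  stop_invalid(problems, "problem directory")

  par_tab <- data.frame(parameter_id = tabs$parameters$parameterId,
                        scale = tabs$parameters$parameterScale,
                        lower = tabs$parameters$lowerBound,
                        upper = tabs$parameters$upperBound,
                        nominal = tabs$parameters$nominalValue,
                        estimate = tabs$parameters$estimate == 1)
  alpha_row <- par_tab[par_tab$parameter_id == "alpha_cer", ]
  variant <- if (nrow(alpha_row) == 1 &&
                 (alpha_row$estimate || alpha_row$nominal != 0)) {
    "feedback"
  } else {
    "no_feedback"
  }
  sigma_mode <- if (any(grepl("^sigma_", par_tab$parameter_id)))
    "estimate" else "profile"
  measurements <- data.frame(
    observable_id = tabs$measurements$observableId,
    condition_id = tabs$measurements$simulationConditionId,
    time_dpf = tabs$measurements$time,
    replicate = tabs$measurements$replicateId,
    value = tabs$measurements$measurement)
  problem <- make_problem(
    measurements, variant = variant, sigma_mode = sigma_mode,
    observable_species = stats::setNames(species,
                                         tabs$observables$observableId),
    conditions = data.frame(condition_id = tabs$conditions$conditionId,
                            s_on = s_on),
    parameters = par_tab)
  structure(list(directory = directory,
                 files = c(list(yaml = ypath), paths),
                 problem = problem), class = "problem_bundle")
}

#' @export
print.problem_bundle <- function(x, ...) {
  cat(sprintf("<problem_bundle> %s\n", x$directory))
  print(x$problem)
  invisible(x)
}
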