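# Result serialization: strategy-by-perspective tables as CSV and JSON, a
# run manifest tying every results file to a config hash and master seed, and
# the multi-age base-case driver used by the command-line entry point.
#
# Rounding happens only at write time: dollars to the nearest dollar, QALYs to
# two decimals, ICERs to the nearest $100. In-memory objects stay at full
# precision.

#' Run the base case across start ages
#'
#' Runs both strategies at each start age and collects the
#' strategy-by-perspective table (cost, QALY, ICER).
#'
#' @param params an `osteo_params` parameter set.
#' @param start_ages cohort entry ages.
#' @param n_individuals Monte-Carlo sample size per strategy and age.
#' @param master_seed master seed.
#' @param discount_rate annual discount rate.
#' @return List of class `osteo_base_case`: `table` (rounded, one row per age
#'   x strategy x perspective) and `runs` (the underlying `osteo_cea`
#'   objects, full precision).
#' @export
run_base_case <- function(params = default_parameter_set(),
                          start_ages = c(65, 70, 75, 80),
                          n_individuals = 10000, master_seed = 1L,
                          discount_rate = 0.03) {
  runs <- lapply(start_ages, function(age) {
    run_cea(params, make_scenario(start_age = age,
                                  n_individuals = n_individuals,
                                  master_seed = master_seed,
                                  discount_rate = discount_rate))
  })
  names(runs) <- as.character(start_ages)
  rows <- lapply(seq_along(start_ages), function(i) {
    s <- summary(runs[[i]])
    cbind(start_age = start_ages[i], s)
  })
  out <- list(table = do.call(rbind, rows), runs = runs,
              master_seed = master_seed, n_individuals = n_individuals)
  class(out) <- "osteo_base_case"
  out
}

#' @export
print.osteo_base_case <- function(x, ...) {
  cat(sprintf("Base case (n = %s per strategy per age, seed %d)\n",
              format(x$n_individuals, big.mark = ","), x$master_seed))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Write base-case results as CSV + JSON with a run manifest
#'
#' @param bc an `osteo_base_case` from [run_base_case()].
#' @param dir output directory (created if needed).
#' @param params the parameter set used (hashed into the manifest).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cea_results <- function(bc, dir, params = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, "base_case.csv")
  json_path <- file.path(dir, "base_case.json")
  utils::write.csv(bc$table, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bc$table, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- run_manifest(params, master_seed = bc$master_seed,
                           n_individuals = bc$n_individuals,
                           outputs = c(csv_path, json_path))
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path, manifest = man_path))
}

#' Build a run manifest
#'
#' Records the package version, master seed, problem size, a hash of the
#' parameter configuration, a timestamp and the output paths, so every
#' results file is traceable to the run that produced it.
#'
#' @param params parameter set (hashed via its serialized form); may be NULL.
#' @param master_seed master seed used.
#' @param n_individuals Monte-Carlo sample size.
#' @param outputs character vector of result file paths.
#' @return Named list.
#' @export
run_manifest <- function(params = NULL, master_seed = NA_integer_,
                         n_individuals = NA_integer_, outputs = character()) {
  hash <- NA_character_
  if (!is.null(params)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(c(tmp, file.path(dirname(tmp),
                                    c("mortality.csv", "incidence.csv",
                                      "utilities.csv")))), add = TRUE)
    write_parameter_set(params, tmp, dirname(tmp))
    hash <- unname(tools::md5sum(tmp))
  }
  list(package = "osteosim",
       version = as.character(utils::packageVersion("osteosim")),
       config_md5 = hash,
       master_seed = master_seed,
       n_individuals = n_individuals,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}

#' Dump a single simulated trajectory as CSV (debugging aid)
#'
#' @param trajectory an `osteo_trajectory` from [simulate_individual()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
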