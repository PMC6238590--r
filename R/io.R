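# CSV dialect: comma-separated, UTF-8, header row required, "." decimal.
read_csv_checked <- function(path, required, numeric_cols,
                             nonneg_cols = character(), what = "file") {
  if (!file.exists(path)) stop(what, ": file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop(what, ": no data rows in ", path, call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(ifelse(v %in% c("", "NA"), NA, v)))
      bad <- which(!is.na(v) & !(v %in% c("", "NA")) & is.na(vn))
      if (length(bad)) {
        stop(what, ": non-numeric value '", v[bad[1]], "' in column '", col,
             "', row ", bad[1], call. = FALSE)
      }
      df[[col]] <- vn
    }
  }
  for (col in intersect(nonneg_cols, names(df))) {
    bad <- which(df[[col]] < 0)
    if (length(bad)) {
      stop(what, ": negative value in column '", col, "', row ", bad[1],
           call. = FALSE)
    }
  }
  df
}

#' Read per-well metabolite measurements
#'
#' Long-format CSV with one row per well: columns `genotype`, `treatment`,
#' `well`, `glycerol_release`, `ffa_release`, `lactate_release`, and
#' optionally `glucose_uptake`, `o2_consumption`, `ppr_measured` (all rates
#' nmol h^-1 cm^-2; empty cells or `NA` mark unmeasured values). Rows with
#' negative concentrations or non-numeric cells are rejected with the row
#' and column named.
#'
#' @param path CSV file path.
#' @return Validated `data.frame`.
#' @export
read_measurements <- function(path) {
  rates <- c("glycerol_release", "ffa_release", "lactate_release",
             "glucose_uptake", "o2_consumption", "ppr_measured")
  df <- read_csv_checked(path,
                         required = c("genotype", "treatment", "well",
                                      "glycerol_release", "ffa_release",
                                      "lactate_release"),
                         numeric_cols = rates,
                         nonneg_cols = setdiff(rates, "ppr_measured"),
                         what = "read_measurements")
  df
}

#' Read respirometry traces with their injection sidecar
#'
#' `traces_path`: long CSV with columns `well`, `time_min`, `ocr_pmol_min`,
#' optionally `ppr_pmol_min` and `genotype`. `injections_path`: sidecar CSV
#' with columns `well_group`, `time_min`, `agent`; a trace well belongs to
#' the group whose name prefixes its well id (`<well_group>_...`).
#'
#' @param traces_path CSV of the time series.
#' @param injections_path CSV of the injection events.
#' @return List with elements `traces` and `injections`, the layout consumed
#'   by [assemble_wells()].
#' @export
read_traces <- function(traces_path, injections_path) {
  traces <- read_csv_checked(traces_path,
                             required = c("well", "time_min", "ocr_pmol_min"),
                             numeric_cols = c("time_min", "ocr_pmol_min",
                                              "ppr_pmol_min"),
                             what = "read_traces")
  injections <- read_csv_checked(injections_path,
                                 required = c("well_group", "time_min", "agent"),
                                 numeric_cols = "time_min",
                                 what = "read_traces (injections)")
  bad <- setdiff(unique(injections$agent), respiration_agents())
  if (length(bad)) {
    stop("read_traces: unknown agent(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(traces = traces, injections = injections)
}

#' Read glycogen content time courses
#'
#' CSV with columns `genotype`, `treatment`, `time_h`, `content_ug` and
#' optionally `well`; content is glycogen in ug per cm2.
#'
#' @param path CSV file path.
#' @return Validated `data.frame`.
#' @export
read_glycogen <- function(path) {
  read_csv_checked(path,
                   required = c("genotype", "treatment", "time_h", "content_ug"),
                   numeric_cols = c("time_h", "content_ug"),
                   nonneg_cols = "content_ug",
                   what = "read_glycogen")
}

#' Read a structured run configuration
#'
#' YAML file with the optional top-level sections `constants` (fields of
#' [model_constants()]), `geometry` (fields of [culture_geometry()]),
#' `modes` (`ffa_mode`, `co2_mode`), `seed`, `paths` and `tolerance`.
#' Unknown keys at any of these levels are rejected rather than ignored, so
#' typos cannot silently fall back to defaults. The effective configuration
#' is echoed to the message stream.
#'
#' @param path YAML file path.
#' @return List with `constants`, `geometry`, `modes`, `seed`, `paths`,
#'   `tolerance`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed_top <- c("constants", "geometry", "modes", "seed", "paths", "tolerance")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown)) {
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_sub <- function(x, allowed, section) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop("read_run_config: unknown key(s) in '", section, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    x
  }
  cst_over <- check_sub(cfg$constants, names(formals(model_constants)), "constants")
  geo_over <- check_sub(cfg$geometry, names(formals(culture_geometry)), "geometry")
  modes <- check_sub(cfg$modes, c("ffa_mode", "co2_mode"), "modes")
  out <- list(
    constants = do.call(model_constants, as.list(cst_over)),
    geometry = do.call(culture_geometry, as.list(geo_over)),
    modes = list(ffa_mode = if (is.null(modes$ffa_mode)) "stoichiometric" else modes$ffa_mode,
                 co2_mode = if (is.null(modes$co2_mode)) "rq" else modes$co2_mode),
    seed = cfg$seed,
    paths = cfg$paths,
    tolerance = cfg$tolerance
  )
  message("read_run_config: effective configuration\n",
          yaml::as.yaml(list(constants = unclass(out$constants),
                             geometry = unclass(out$geometry),
                             modes = out$modes, seed = out$seed)))
  out
}

flux_table_for_output <- function(x) {
  tab <- if (inherits(x, "flux_model")) flux_table(x) else as.data.frame(x)
  req <- c("genotype", "treatment", "quantity", "mean", "sd", "n", "below_zero")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("write_flux_table: table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab[order(tab$genotype, treatment_order(tab$treatment),
            match(tab$quantity, unique(tab$quantity))), req, drop = FALSE]
}

#' Write a flux table to TSV or JSON
#'
#' The TSV rendering follows the display convention of the reference
#' dataset: each cell is `mean ± SD` rounded to one decimal, and cells whose
#' mean is below zero are shown as `"<0"` (the numeric value is retained in
#' the `mean` column and in the JSON format). Column and row order are
#' deterministic, so identical tables yield byte-identical files.
#'
#' @param x A [flux_model()] fit or a long flux table
#'   (`genotype`, `treatment`, `quantity`, `mean`, `sd`, `n`, `below_zero`).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the path.
#' @seealso [read_flux_table()]
#' @export
write_flux_table <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- flux_table_for_output(x)
  if (format == "json") {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null", digits = NA)
  } else {
    tab$display <- vapply(seq_len(nrow(tab)), function(i) {
      format_flux_cell(tab$mean[i], tab$sd[i], tab$below_zero[i])
    }, character(1))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read back a JSON flux table
#'
#' Inverse of [write_flux_table()] for the JSON format:
#' `read_flux_table(write_flux_table(x, p, "json"))` recovers the table.
#'
#' @param path JSON file path.
#' @return Long flux table `data.frame`.
#' @export
read_flux_table <- function(path) {
  tab <- jsonlite::fromJSON(path)
  req <- c("genotype", "treatment", "quantity", "mean", "sd", "n", "below_zero")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("read_flux_table: not a flux table (missing ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  }
  for (col in c("mean", "sd")) tab[[col]] <- as.numeric(tab[[col]])
  tab$below_zero <- as.logical(tab$below_zero)
  tab
}

#' Write a simulated experiment to disk
#'
#' Emits the exact CSV dialects the readers consume — `metabolites.csv`,
#' `traces.csv`, `injections.csv`, `glycogen.csv` — plus the ground truth as
#' `truth.json`.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @seealso [read_simulation()]
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "flux_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wcsv(sim$metabolites, "metabolites.csv")
  wcsv(sim$traces, "traces.csv")
  wcsv(sim$injections, "injections.csv")
  wcsv(sim$glycogen, "glycogen.csv")
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(dir)
}

#' Read a simulated experiment back from disk
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list with `metabolites`, `traces`, `injections`, `glycogen`
#'   (and `truth` when present), consumable by [assemble_wells()].
#' @export
read_simulation <- function(dir) {
  out <- list(
    metabolites = read_measurements(file.path(dir, "metabolites.csv")),
    glycogen = read_glycogen(file.path(dir, "glycogen.csv"))
  )
  tr <- read_traces(file.path(dir, "traces.csv"), file.path(dir, "injections.csv"))
  out$traces <- tr$traces
  out$injections <- tr$injections
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    out$truth <- jsonlite::fromJSON(truth_path)
  }
  out
}
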