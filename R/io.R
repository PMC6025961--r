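# File dialects. Lineage tables are TSV, environment trajectories and
# snapshot tables CSV; configs are YAML or JSON. Round trips are
# lossless and unknown columns are preserved.

.snapshot_cols <- c("t_min", "od", "reporter", "value")
.environment_cols <- c("t_min", "biomass", "glucose_mM", "malate_mM",
                       "acetate_mM", "acetoin_mM")

.check_cols <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read / write single-cell and environment tables
#'
#' `read_lineage_table()`/`write_lineage_table()` use the tab-separated
#' lineage dialect (`cell_id`, `parent_id`, `channel_id`, `frame`,
#' `t_min`, `length_um`, `f_sucC`, `f_alsS`, `state_sucC`, `state_alsS`,
#' `fate`); `read_snapshot_table()`/`write_snapshot_table()` the long
#' snapshot CSV (`t_min`, `od`, `reporter`, `value`);
#' `read_environment()`/`write_environment()` the environment CSV
#' (`t_min`, `biomass`, `glucose_mM`, `malate_mM`, `acetate_mM`,
#' `acetoin_mM`). Missing mandatory columns raise an error naming them;
#' extra columns pass through unchanged; CRLF files parse identically to
#' LF.
#'
#' @param path file path.
#' @param table,env data frame to write.
#' @return the tibble read, or (for writers) `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_lineage_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_cols(df, .lineage_cols, "lineage table")
  df
}

#' @rdname table_io
#' @export
write_lineage_table <- function(table, path) {
  .check_cols(table, .lineage_cols, "lineage table")
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_snapshot_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .check_cols(df, .snapshot_cols, "snapshot table")
  df
}

#' @rdname table_io
#' @export
write_snapshot_table <- function(table, path) {
  .check_cols(table, .snapshot_cols, "snapshot table")
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_environment <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .check_cols(df, .environment_cols, "environment trajectory")
  df
}

#' @rdname table_io
#' @export
write_environment <- function(env, path) {
  .check_cols(env, .environment_cols, "environment trajectory")
  readr::write_csv(env, path)
  invisible(path)
}

#' Read a scenario configuration from YAML or JSON
#'
#' The file holds the [scenario_config()] arguments, plus an optional
#' `params` block of [switch_params()] overrides.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `config` (a `scenario_config`) and
#'   `params` (a `switch_params`).
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  par_over <- raw$params %||% list()
  raw$params <- NULL
  cfg <- do.call(scenario_config, raw)
  list(config = cfg, params = do.call(switch_params, par_over))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
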