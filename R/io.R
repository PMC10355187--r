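# Text file formats: IOP profile CSV, self-describing gridded signal CSV,
# and JSON run manifests.

profile_columns <- c("depth_m", "a_m-1", "b_m-1", "xi")

#' Write an IOP profile to CSV
#'
#' Columns `depth_m, a_m-1, b_m-1, xi`; depth is positive-down in meters
#' from the air-water interface.
#'
#' @param iop An [iop_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(iop, path) {
  stopifnot(inherits(iop, "iop_profile"))
  df <- data.frame(iop$depth, iop$a, iop$b, iop$xi, check.names = FALSE)
  names(df) <- profile_columns
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IOP profile from CSV
#'
#' @param path CSV file with columns `depth_m, a_m-1, b_m-1, xi`.
#' @param water A [pure_water_optics()] attached to the profile.
#' @return An [iop_profile()].
#' @export
read_profile <- function(path, water = pure_water_optics()) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(profile_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("profile file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("profile file ", path, " has no data rows")
  bad <- which(!stats::complete.cases(df[profile_columns]) |
                 Reduce(`|`, lapply(df[profile_columns],
                                    function(x) !is.numeric(x))))
  if (length(bad) > 0) {
    stop("malformed profile row(s) ", paste(bad + 1, collapse = ", "),
         " in ", path, " (header is line 1)")
  }
  d <- df[["depth_m"]]
  if (any(diff(d) <= 0)) {
    stop("non-monotone depth at row ",
         which(diff(d) <= 0)[1] + 2, " in ", path)
  }
  iop_profile(d, df[["a_m-1"]], df[["b_m-1"]], df[["xi"]], water = water)
}

#' Write a signal set to a self-describing gridded CSV
#'
#' Attributes (model tag, seed, units, channel FOVs) are stored as
#' `# key: value` header lines, followed by a depth x channel table with the
#' canonical channel order.
#'
#' @param signals A [signal_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  stopifnot(inherits(signals, "signal_set"))
  meta <- signals$meta
  hdr <- c("# oceanhsrl signal set",
           "# units: arbitrary (system-constant) signal units; depth_m: m")
  for (key in c("model", "seed", "n_photons")) {
    if (!is.null(meta[[key]])) {
      hdr <- c(hdr, sprintf("# %s: %s", key, format(meta[[key]])))
    }
  }
  if (!is.null(meta$config_fovs)) {
    hdr <- c(hdr, sprintf("# fovs_rad: %s",
                          paste(meta$config_fovs, collapse = " ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(signals), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a signal set from a gridded CSV
#'
#' Channel columns may appear in any order on disk; they are restored to the
#' canonical order (`mol_narrow`, `mol_mid`, `mol_wide`, `comb_wide`).
#'
#' @param path File written by [write_signals()] (or any CSV with a
#'   `depth_m` column and the four canonical channels).
#' @return A [signal_set()].
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    mm <- regmatches(ln, regexec("^# ([A-Za-z0-9_]+): (.*)$", ln))[[1]]
    if (length(mm) == 3) {
      val <- mm[3]
      num <- suppressWarnings(as.numeric(strsplit(val, " ")[[1]]))
      meta[[mm[2]]] <- if (all(is.finite(num))) num else val
    }
  }
  df <- read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                              collapse = "\n"), check.names = FALSE)
  need <- c("depth_m", hsrl_channels())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("unknown/missing channel columns in ", path, ": expected ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(meta$config_fovs)) names(meta)[names(meta) == "fovs_rad"] <-
    "config_fovs"
  if (!is.null(meta$fovs_rad)) {
    meta$config_fovs <- meta$fovs_rad
    meta$fovs_rad <- NULL
  }
  signal_set(df$depth_m,
             as.matrix(df[, hsrl_channels()[1:3]]),
             df$comb_wide, meta = meta)
}

#' Write a JSON run manifest
#'
#' Every pipeline run emits one manifest capturing enough information
#' (seeds, configuration, stage summaries, file paths) to re-run the
#' deterministic stages bit-identically.
#'
#' @param path Output path.
#' @param stage Stage label (e.g. "simulate", "retrieve").
#' @param config A [lidar_config()] or `NULL`.
#' @param seeds Named list/vector of seeds.
#' @param inputs,outputs Character vectors of file paths.
#' @param summary Named list of stage summary values.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, config = NULL, seeds = NULL,
                           inputs = character(0), outputs = character(0),
                           summary = list()) {
  manifest <- list(
    tool = "oceanhsrl",
    version = as.character(utils::packageVersion("oceanhsrl")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    inputs = inputs,
    outputs = outputs,
    summary = summary)
  if (!is.null(config)) {
    manifest$config <- unclass(config)
    manifest$config$water <- unclass(config$water)
    manifest$config_hash <- config_hash(config)
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Stable short hash of a configuration (sum over serialized bytes; enough to
# detect accidental config drift between stages without extra dependencies).
config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %%
            .Machine$integer.max)
}
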