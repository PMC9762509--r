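# Serialization: delimited tables with '#'-prefixed metadata headers, a
# bit-exact trajectory container, and flat key=value run configs for the CLI.

#' Write/read a result table with a metadata header
#'
#' Tables are tab-separated with a header of `# key: value` lines recording
#' the resolved configuration, so every artifact is self-describing.
#'
#' @param df data frame.
#' @param path output path (written atomically: temp file + rename).
#' @param meta named list of scalar metadata.
#' @return `path`, invisibly (write); the data frame with a `"meta"`
#'   attribute (read).
#' @export
write_result_table <- function(df, path, meta = list()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(if (!is.null(con)) close(con), add = TRUE)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con); con <- NULL
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- read.table(text = lines[setdiff(seq_along(lines), hdr)],
                   header = TRUE, sep = "\t")
  attr(df, "meta") <- meta
  df
}

#' Write/read a trajectory container
#'
#' Serializes the full trajectory object (state arrays plus parameter and
#' protocol snapshots) to RDS; the round trip is bit-exact.
#'
#' @param traj a trajectory.
#' @param path file path.
#' @return `path` invisibly (write); the trajectory (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  tmp <- paste0(path, ".tmp")
  saveRDS(traj, tmp, version = 3)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  stopifnot(inherits(traj, "trajectory"))
  traj
}

#' Read a flat key=value run configuration
#'
#' Lines are `key = value` (or `key: value`); blank lines and `#` comments
#' are ignored.  Values are typed: numbers (including `Inf`) become numeric,
#' `true`/`false` logical, everything else character.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^([^=:]+)[=:](.*)$", l))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", l, call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
  }
  out
}

# split a config into network parameters and numerical settings; unknown keys
# are a config error listing the offenders
config_to_params <- function(cfg) {
  par_keys <- c("n_units", "g_h", "alpha_z", "alpha_r", "beta_h", "beta_z",
                "beta_r", "tau_z", "tau_r", "seed")
  num_keys <- c("t_final", "dt", "record_every", "t_total", "t_transient",
                "reorth_interval", "k", "sigma_h", "n_trials", "out")
  unknown <- setdiff(names(cfg), c(par_keys, num_keys))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  list(params = do.call(network_params, cfg[intersect(names(cfg), par_keys)]),
       settings = cfg[intersect(names(cfg), num_keys)])
}
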