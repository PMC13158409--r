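#' Write a reflectivity curve as commented ASCII
#'
#' Columnar `q R dR [dq]` text with `#`-prefixed header lines carrying the
#' resolution and arbitrary metadata, following the plain-text reflectivity
#' file convention (.ort-style commented header).
#'
#' @param curve A [reflectivity_curve()].
#' @param path Output file path.
#' @param metadata Named list written as `# key: value` header lines.
#' @param dq Optional per-point resolution column (A^-1).
#' @return `path`, invisibly.
#' @export
write_reflectivity <- function(curve, path, metadata = list(), dq = NULL) {
  res <- attr(curve, "resolution")
  hdr <- c(
    sprintf("# resolution: %.6g", if (is.null(res)) 0 else res),
    vapply(names(metadata), function(k)
      sprintf("# %s: %s", k, format(metadata[[k]])), character(1)),
    if (is.null(dq)) "# columns: q R dR" else "# columns: q R dR dq"
  )
  tab <- data.frame(q = curve$q, r = curve$r, dr = curve$dr)
  if (!is.null(dq)) tab$dq <- dq
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 10, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reflectivity curve from commented ASCII
#'
#' Accepts 3- or 4-column (`q R dR [dq]`) whitespace-separated text with
#' `#`-prefixed header lines; a `# resolution:` header sets the curve's
#' resolution unless overridden.
#'
#' @param path Input file path.
#' @param resolution Override for the dq/q resolution (otherwise taken from
#'   the header, defaulting to 0.07).
#' @return A [reflectivity_curve()]; a 4th column is stored as attribute
#'   `dq`.
#' @export
read_reflectivity <- function(path, resolution = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^\\s*#", lines)
  if (is.null(resolution)) {
    m <- regmatches(lines[hdr],
                    regexec("#\\s*resolution:\\s*([0-9.eE+-]+)", lines[hdr]))
    vals <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
                   character(1))
    resolution <- if (any(!is.na(vals))) as.numeric(vals[!is.na(vals)][1]) else 0.07
  }
  body_idx <- which(!hdr & nzchar(trimws(lines)))
  rows <- lapply(body_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 3 || length(vals) > 4 || any(is.na(vals)))
      stop("malformed reflectivity row at line ", i, ": '", lines[i], "'")
    vals
  })
  ncols <- unique(vapply(rows, length, numeric(1)))
  if (length(ncols) != 1)
    stop("inconsistent column count across rows")
  tab <- do.call(rbind, rows)
  if (is.unsorted(tab[, 1], strictly = TRUE)) {
    bad <- which(diff(tab[, 1]) <= 0)[1]
    stop("q not strictly ascending at data row ", bad + 1,
         " (file line ", body_idx[bad + 1], ")")
  }
  cv <- reflectivity_curve(tab[, 1], tab[, 2], tab[, 3],
                           resolution = resolution)
  if (ncols == 4) attr(cv, "dq") <- tab[, 4]
  cv
}

#' Write a fit report as JSON
#'
#' Parameters, reduced chi-squared, settings and provenance (package
#' version, seed, config checksum) as a JSON file.
#'
#' @param fit A [fit_global()] result.
#' @param path Output path.
#' @param posterior Optional [sample_posterior()] result; its medians and 68%
#'   intervals are included.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, posterior = NULL) {
  rep <- list(
    variant = fit$problem$model$variant,
    parameters = as.list(fit$par),
    chi2 = fit$chi2,
    red_chi2 = fit$red_chi2,
    n_points = fit$n_points,
    n_free = fit$n_free,
    seed = fit$seed,
    provenance = run_provenance(list(par = as.list(fit$par), seed = fit$seed))
  )
  if (!is.null(posterior)) {
    rep$posterior <- list(
      median = as.list(posterior$median),
      ci68_low = as.list(posterior$ci68[1, ]),
      ci68_high = as.list(posterior$ci68[2, ]),
      settings = posterior$settings
    )
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Provenance block for run outputs
#'
#' Package version, time-independent config checksum, and the seed if
#' present in the config.
#'
#' @param config List of run settings.
#' @return List with `package`, `version`, `config_checksum`, `seed`.
#' @export
run_provenance <- function(config = list()) {
  payload <- paste(deparse(config), collapse = "")
  checksum <- sprintf("%08x",
                      sum(utf8ToInt(payload) * seq_len(nchar(payload))) %% 0xFFFFFFF)
  list(package = "slbtools",
       version = as.character(utils::packageVersion("slbtools")),
       config_checksum = checksum,
       seed = config$seed)
}

#' Read a membrane model and fit configuration from YAML/JSON
#'
#' The config carries a `model` block (variant and parameter values, passed
#' to [membrane_model()]) and an optional `free` block mapping parameter
#' paths to `[lower, upper]` bounds.
#'
#' @param path YAML (or JSON) file path.
#' @return List with `model` ([membrane_model()]), `free` (named list of
#'   bounds), and the raw `config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must contain a 'model' block")
  model <- do.call(membrane_model, cfg$model)
  free <- NULL
  if (!is.null(cfg$free))
    free <- lapply(cfg$free, function(b) as.numeric(unlist(b)))
  list(model = model, free = free, config = cfg)
}

#' Write a volume-fraction profile as CSV
#'
#' @param profile A [volume_fraction_profile()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
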