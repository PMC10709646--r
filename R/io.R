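## Readers and writers for the package's artifacts: PMF profile text
## files, trajectory/grid CSV, JSON reports, YAML configs and serialized
## surfaces. Write-then-read round-trips reproduce values to full
## precision; malformed files produce line-numbered parse errors.

.check_rect_csv <- function(path) {
  nf <- count.fields(path, sep = ",")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("parse error in %s at line %d: expected %d fields, found %d",
                 path, bad, nf[1], nf[bad]))
  }
  invisible(TRUE)
}

#' Write / read a PMF profile as a plain text file
#'
#' Two/four-column whitespace text with `#` header comments (lambda,
#' G_eV, sigma_eV, n), the field's conventional profile format.
#'
#' @param pmf a `dpt_pmf`
#' @param path output file
#' @export
write_pmf <- function(pmf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gcdpt potential of mean force",
               sprintf("# T_K: %g", attr(pmf, "T") %||% NA),
               sprintf("# total_frames: %s", attr(pmf, "total_frames") %||% NA),
               sprintf("# iterations: %s", attr(pmf, "iterations") %||% NA),
               "# columns: lambda G_eV sigma_eV n"), con)
  write.table(format(as.data.frame(pmf), digits = 17, trim = TRUE,
                     scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @return `read_pmf`: a `dpt_pmf` data.frame
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr]
  parts <- strsplit(trimws(body), "\\s+")
  nfield <- lengths(parts)
  if (any(nfield != 4)) {
    bad <- which(nfield != 4)[1]
    stop(sprintf("parse error in %s at line %d: expected 4 fields, found %d",
                 path, which(!hdr)[bad], nfield[bad]))
  }
  num <- function(p) { p[p %in% c("NA", "NaN")] <- NA; as.numeric(p) }
  m <- do.call(rbind, lapply(parts, num))
  out <- data.frame(lambda = m[, 1], G_eV = m[, 2], sigma_eV = m[, 3],
                    n = m[, 4])
  tval <- sub("^# T_K: ", "", lines[grepl("^# T_K:", lines)])
  structure(out, class = c("dpt_pmf", "data.frame"),
            T = if (length(tval)) num(tval) else NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory as CSV
#'
#' Columns: t_fs, r1_A, r2_A, d1_A..d4_A, lambda, E_eV, s_A. Metadata
#' (settings, window, seed) goes to a YAML sidecar when `sidecar = TRUE`.
#'
#' @param traj a `dpt_trajectory`
#' @param path output CSV
#' @param sidecar also write `<path>.meta.yaml`
#' @export
write_trajectory <- function(traj, path, sidecar = FALSE) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (sidecar) {
    st <- attr(traj, "settings")
    w <- attr(traj, "window")
    meta <- list(scenario = attr(traj, "scenario"),
                 settings = unclass(st),
                 window = if (!is.null(w)) unclass(w),
                 s = attr(traj, "s"), n_reflect = attr(traj, "n_reflect"))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  .check_rect_csv(path)
  df <- read.csv(path)
  need <- c("t_fs", "r1_A", "r2_A", "lambda", "E_eV")
  if (!all(need %in% names(df)))
    stop("trajectory file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  meta_path <- paste0(path, ".meta.yaml")
  out <- structure(df, class = c("dpt_trajectory", "data.frame"))
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(out, "scenario") <- meta$scenario
    if (!is.null(meta$window))
      attr(out, "window") <- structure(meta$window,
                                       class = "dpt_umbrella_window")
    if (!is.null(meta$settings))
      attr(out, "settings") <- structure(meta$settings,
                                         class = "dpt_sim_settings")
  }
  out
}

#' Write / read a surface grid as CSV (long format: r1_A, r2_A, E_eV)
#'
#' @param grid a `dpt_grid`
#' @param path output CSV
#' @export
write_grid <- function(grid, path) {
  long <- data.frame(r1_A = rep(grid$r1, times = length(grid$r2)),
                     r2_A = rep(grid$r2, each = length(grid$r1)),
                     E_eV = as.vector(grid$E))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  .check_rect_csv(path)
  long <- read.csv(path)
  if (!all(c("r1_A", "r2_A", "E_eV") %in% names(long)))
    stop("grid file must have columns r1_A, r2_A, E_eV")
  r1 <- sort(unique(long$r1_A)); r2 <- sort(unique(long$r2_A))
  E <- matrix(NA_real_, length(r1), length(r2))
  E[cbind(match(long$r1_A, r1), match(long$r2_A, r2))] <- long$E_eV
  if (any(is.na(E))) stop("grid file is not a complete rectangular grid")
  structure(list(r1 = r1, r2 = r2, E = E, scenario = "file", s = 0,
                 spacing = diff(r1[1:2]),
                 too_coarse = diff(r1[1:2]) > 0.05 + 1e-9),
            class = "dpt_grid")
}

#' Write / read JSON reports
#'
#' @param x named list (profiles, summaries, decay results, ...)
#' @param path output JSON
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Serialize a surface to / from a YAML parameter file
#'
#' @param params a `dpt_surface`
#' @param path file path
#' @export
write_surface <- function(params, path) {
  x <- list(
    scenario = params$scenario,
    geom = params$geom[c("R_NN", "R_ON", "r_cov", "domain")],
    shape = params$shape,
    wells = as.list(params$wells), ramps = as.list(params$ramps),
    bumps = as.list(params$bumps), sep = as.list(params$sep),
    conf = as.list(params$conf), offset = params$offset)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  x <- yaml::read_yaml(path)
  geom <- geometry_refs(R_NN = x$geom$R_NN, R_ON = x$geom$R_ON,
                        r_cov = x$geom$r_cov,
                        domain = as.numeric(x$geom$domain))
  p <- list(scenario = x$scenario, geom = geom, shape = x$shape,
            wells = as.data.frame(x$wells, stringsAsFactors = FALSE),
            ramps = as.data.frame(x$ramps, stringsAsFactors = FALSE),
            bumps = as.data.frame(x$bumps, stringsAsFactors = FALSE),
            sep = as.data.frame(x$sep, stringsAsFactors = FALSE),
            conf = unlist(x$conf), offset = x$offset, calibration = NULL)
  class(p) <- "dpt_surface"
  p
}

#' Emit a human-readable transition table across scenarios
#'
#' Mirrors the layout of the published statistics tables: one row per
#' (transition, quantity), one column per scenario.
#'
#' @param profiles named list of `dpt_profile` (names = scenarios)
#' @return data.frame
#' @export
profile_table <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  rows <- list()
  for (nm in names(profiles)) {
    tr <- profiles[[nm]]$transitions
    for (i in seq_len(nrow(tr))) for (q in c("dG_rxn_eV", "dG_fwd_eV",
                                             "dG_rev_eV", "K")) {
      rows[[length(rows) + 1]] <- data.frame(
        scenario = nm, transition = tr$transition[i], quantity = q,
        value = tr[[q]][i])
    }
  }
  long <- do.call(rbind, rows)
  wide <- stats::reshape(long, idvar = c("transition", "quantity"),
                         timevar = "scenario", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
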