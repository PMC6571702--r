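#' Read a three-column SAXS .dat file
#'
#' Parses the common ATSAS-style dialect: '#'-prefixed (or blank) header
#' lines followed by a 2- or 3-column numeric body of q (1/A), I and
#' optionally sigma.
#'
#' @param path File path.
#' @return A `"scattering_curve"`; the `sigma` column is present only for
#'   3-column files.
#' @export
#' @examples
#' # a packaged synthetic coil/oligomer mixture curve
#' crv <- read_saxs_dat(system.file("extdata", "synthetic_hst5_mixture.dat",
#'                                  package = "histazinc"))
#' guinier_fit(crv)
read_saxs_dat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body_idx)) {
    stop("no data rows in '", path, "' (comments/blank lines only)",
         call. = FALSE)
  }
  parse_row <- function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals) || !(length(vals) %in% 2:3)) {
      stop("non-numeric or malformed row at line ", i, " of '", path, "'",
           call. = FALSE)
    }
    vals
  }
  rows <- lapply(body_idx, parse_row)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) {
    stop("inconsistent column counts in '", path, "'", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (is.unsorted(m[, 1], strictly = TRUE)) {
    bad <- which(diff(m[, 1]) <= 0)[1]
    stop("q not strictly increasing at line ", body_idx[bad + 1], " of '",
         path, "'", call. = FALSE)
  }
  scattering_curve(m[, 1], m[, 2],
                   sigma = if (ncols == 3) m[, 3] else NULL,
                   label = basename(path))
}

#' Write a scattering curve as a SAXS .dat file
#'
#' Three columns (q, I, sigma) when errors are present, two otherwise,
#' with a '#' comment header.
#'
#' @param curve A `"scattering_curve"`.
#' @param path Output path.
#' @param header Optional extra comment line.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path, header = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  lab <- attr(curve, "label")
  writeLines(paste0("# ", c(
    if (!is.null(lab)) paste("sample:", lab),
    if (is.finite(attr(curve, "concentration") %||% NA))
      paste("concentration (mg/mL):", attr(curve, "concentration")),
    header,
    "q (1/A)  I  [sigma]"
  )), con)
  has_sigma <- "sigma" %in% names(curve)
  body <- if (has_sigma) {
    sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma)
  } else {
    sprintf("%.8e %.8e", curve$q, curve$I)
  }
  writeLines(body, con)
  invisible(path)
}

#' Read a PFG-NMR decay table
#'
#' CSV with columns `gradient` (fraction of maximum), `peak`, `intensity`;
#' pulse parameters are given as arguments or '#'-style header comments of
#' the form `# delta: 0.002`.
#'
#' @param path File path.
#' @param ... Parameter overrides passed to [pfg_dataset()].
#' @return A `"pfg_dataset"`.
#' @export
read_pfg_csv <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  params <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("#\\s*(delta|Delta|gamma|g_max)\\s*:\\s*([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 3) params[[m[2]]] <- as.numeric(m[3])
  }
  tbl <- utils::read.csv(text = paste(lines[!grepl("^\\s*#", lines)],
                                      collapse = "\n"))
  need <- c("gradient", "peak", "intensity")
  if (!all(need %in% names(tbl))) {
    stop("PFG table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  args <- utils::modifyList(params, list(...))
  do.call(pfg_dataset, c(list(gradient = tbl$gradient, peak = tbl$peak,
                              intensity = tbl$intensity), args))
}

#' Write a PFG-NMR decay table
#'
#' @param data A `"pfg_dataset"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfg_csv <- function(data, path) {
  stopifnot(inherits(data, "pfg_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# delta: %g", attr(data, "delta")),
    sprintf("# Delta: %g", attr(data, "Delta")),
    sprintf("# gamma: %g", attr(data, "gamma")),
    sprintf("# g_max: %g", attr(data, "g_max"))
  ), con)
  utils::write.csv(as.data.frame(data[, c("gradient", "peak", "intensity")]),
                   con, row.names = FALSE)
  invisible(path)
}

#' Write sampled frames as an XYZ trajectory
#'
#' One record per frame; atom names encode the chain id (C1, C2, ...).
#'
#' @param frames List of coordinate matrices (N x 3).
#' @param path Output path.
#' @param n_beads Beads per chain.
#' @param comment Extra text appended to each frame's comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, n_beads, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    chain_id <- rep(seq_len(nrow(fr) / n_beads), each = n_beads)
    writeLines(c(
      as.character(nrow(fr)),
      paste(c("frame", k, comment), collapse = " "),
      sprintf("C%d %.4f %.4f %.4f", chain_id, fr[, 1], fr[, 2], fr[, 3])
    ), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
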