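# Plain-text interchange formats: series TSV (one row per snapshot x bp),
# single-structure parameter tables, ensemble-spec JSON, and a pseudo-atom
# PDB writer for duplex models. All files carry units (deg / Angstrom) in
# '#' metadata lines; numbers are rendered with 10 significant digits so
# that write -> read round-trips reproduce values to that precision.

.core_cols <- c("snapshot", "bp", .param_names)

#' Write / read a helical-coordinate series as TSV
#'
#' One row per (snapshot, base pair) with columns `snapshot, bp, x_disp,
#' y_disp, h_rise, incl, tip, h_twist`, then any extra parameters.
#' `snapshot` and `bp` are 0-based labels. `#`-prefixed metadata lines
#' carry units, the spec label and the snapshot spacing. The reader
#' validates the header, rejects ragged snapshot blocks, and preserves
#' extra columns.
#'
#' @param series A [helical_series()].
#' @param path File path.
#' @return `read_series` returns a [helical_series()]; `write_series`
#'   returns `path` invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "helical_series"))
  d <- dim(series$params)
  pn <- dimnames(series$params)[[3]]
  snap <- rep(seq_len(d[1]) - 1L, each = d[2])
  bp <- rep(seq_len(d[2]) - 1L, times = d[1])
  flat <- matrix(aperm(series$params, c(3, 2, 1)), ncol = length(pn),
                 byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# helical-coordinate series (angles deg, lengths A)",
               paste0("# label: ", series$label),
               paste0("# snapshot_spacing: ",
                      format(series$snapshot_spacing, digits = 10))), con)
  writeLines(paste(c("snapshot", "bp", pn), collapse = "\t"), con)
  body <- cbind(format(snap, scientific = FALSE, trim = TRUE),
                format(bp, scientific = FALSE, trim = TRUE),
                matrix(sprintf("%.10g", flat), nrow = length(snap)))
  writeLines(do.call(paste, c(split(body, col(body)), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  label <- ""
  spacing <- 1
  for (ml in lines[meta]) {
    if (grepl("^# label:", ml)) label <- trimws(sub("^# label:", "", ml))
    if (grepl("^# snapshot_spacing:", ml))
      spacing <- as.numeric(sub("^# snapshot_spacing:", "", ml))
  }
  body <- lines[setdiff(seq_along(lines), meta)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("no data rows in ", path, call. = FALSE)
  header_line <- which(!grepl("^#", lines) & nzchar(trimws(lines)))[1]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(.core_cols, header)
  if (length(miss))
    stop("malformed header at line ", header_line,
         ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = header, check.names = FALSE)
  snaps <- unique(dat$snapshot)
  per <- table(dat$snapshot)
  if (length(unique(per)) != 1)
    stop("ragged snapshots: base-pair counts differ between snapshots",
         call. = FALSE)
  n_bp <- unique(per)[[1]]
  ord <- order(match(dat$snapshot, snaps), dat$bp)
  dat <- dat[ord, , drop = FALSE]
  pn <- setdiff(header, c("snapshot", "bp"))
  pn <- c(.param_names, setdiff(pn, .param_names))
  arr <- array(NA_real_, c(length(snaps), n_bp, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (p in pn) arr[, , p] <- t(matrix(dat[[p]], n_bp, length(snaps)))
  helical_series(arr, label = label, snapshot_spacing = spacing)
}

#' Write / read a helical parameter table
#'
#' Single-structure table of base-pair axis parameters, one row per base
#' pair, with the conventional hyphenated column names `x-disp y-disp
#' h-rise incl tip h-twist` and `#` comment lines. The format is a
#' hand-convertible cousin of the parameter tables emitted by standard
#' helical-analysis tools.
#'
#' @param params Data frame with columns `x_disp, y_disp, h_rise, incl,
#'   tip, h_twist`.
#' @param path File path.
#' @return `read_par` returns the data frame; `write_par` returns `path`
#'   invisibly.
#' @export
write_par <- function(params, path) {
  params <- as.data.frame(params)
  miss <- setdiff(.param_names, names(params))
  if (length(miss))
    stop("params missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# helical base-pair axis parameters (angles deg, lengths A)",
               paste(gsub("_", "-", .param_names), collapse = " ")), con)
  writeLines(apply(params[.param_names], 1,
                   function(r) paste(sprintf("%.10g", r), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_par
#' @export
read_par <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("no parameter rows in ", path, call. = FALSE)
  header <- gsub("-", "_", strsplit(trimws(lines[1]), "\\s+")[[1]])
  miss <- setdiff(.param_names, header)
  if (length(miss))
    stop("malformed header: missing column(s) ",
         paste(gsub("_", "-", miss), collapse = ", "), call. = FALSE)
  dat <- utils::read.table(text = lines[-1], col.names = header)
  dat[.param_names]
}

#' Write / read an ensemble spec as JSON
#'
#' Serializes every field of an [ensemble_spec()] (units deg / Angstrom);
#' the reader re-validates through the constructor.
#'
#' @param spec An `ensemble_spec`.
#' @param path File path.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ensemble_spec"))
  obj <- list(label = spec$label, n_bp = spec$n_bp,
              n_snapshots = spec$n_snapshots, seed = spec$seed,
              units = list(angles = "deg", lengths = "Angstrom"),
              means = as.list(spec$means), sds = as.list(spec$sds),
              intra_step_correlation = spec$intra_step_correlation,
              neighbor_twist_correlation = spec$neighbor_twist_correlation,
              neighbor_rise_correlation = spec$neighbor_rise_correlation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ensemble_spec(n_bp = obj$n_bp, n_snapshots = obj$n_snapshots,
                means = unlist(obj$means), sds = unlist(obj$sds),
                intra_step_correlation = obj$intra_step_correlation,
                neighbor_twist_correlation = obj$neighbor_twist_correlation,
                neighbor_rise_correlation = obj$neighbor_rise_correlation,
                seed = obj$seed, label = obj$label)
}

#' Write a duplex model as a pseudo-atom PDB file
#'
#' Emits fixed-column PDB HETATM records: per base pair one origin marker
#' (`ORI`), three axis-tip markers (`AXX`, `AXY`, `AXZ`, 2 Angstrom along
#' the frame axes) in chain H, then the strand backbone proxies (`P1` in
#' chain A, `P2` in chain B) with TER records between chains -- six
#' pseudo-atoms per base pair. Coordinates in Angstrom to 3 decimals.
#'
#' @param model A `duplex_model`.
#' @param path File path.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "duplex_model"))
  n <- nrow(model$origins)
  if (n < 1) stop("empty model", call. = FALSE)
  if (6 * n > 99999) stop("model too large for PDB (> 99999 atoms)",
                          call. = FALSE)
  bp <- backbone_points(model)
  rec <- function(serial, name, chain, resno, xyz)
    sprintf("HETATM%5d %-4s DUP %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, chain, resno, xyz[1], xyz[2], xyz[3])
  lines <- character(0)
  serial <- 0L
  add <- function(name, chain, resno, xyz) {
    serial <<- serial + 1L
    lines[[length(lines) + 1L]] <<- rec(serial, name, chain, resno, xyz)
  }
  for (i in seq_len(n)) {
    O <- model$orientations[, , i]
    add("ORI", "H", i, model$origins[i, ])
    add("AXX", "H", i, model$origins[i, ] + 2 * O[, 1])
    add("AXY", "H", i, model$origins[i, ] + 2 * O[, 2])
    add("AXZ", "H", i, model$origins[i, ] + 2 * O[, 3])
  }
  lines[[length(lines) + 1L]] <- "TER"
  for (i in seq_len(n)) add("P1", "A", i, bp$strand1[i, ])
  lines[[length(lines) + 1L]] <- "TER"
  for (i in seq_len(n)) add("P2", "B", i, bp$strand2[i, ])
  lines[[length(lines) + 1L]] <- "END"
  writeLines(unlist(lines), path)
  invisible(path)
}
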