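## Parameter registries -------------------------------------------------------

# One flat namespace per pipeline stage. `default = NA` with required = TRUE
# means the parameter must come from the config file or the command line.
.param_registry <- list(
  difftocorr = list(
    config      = list(type = "character", default = NA, required = FALSE, help = "path to an INI configuration file"),
    folder      = list(type = "character", default = NA, required = TRUE,  help = "folder containing one diffraction image per file"),
    name_format = list(type = "character", default = NA, required = TRUE,  help = "filename format with a single '#' integer token, e.g. patt_#.npy"),
    n_patterns  = list(type = "integer",   default = NA, required = TRUE,  help = "maximum number of patterns to use"),
    wavelength  = list(type = "numeric",   default = NA, required = TRUE,  help = "wavelength in nm"),
    distance    = list(type = "numeric",   default = NA, required = TRUE,  help = "sample-to-detector distance in m"),
    pixel_size  = list(type = "numeric",   default = NA, required = TRUE,  help = "detector pixel width in m"),
    beam_cx     = list(type = "numeric",   default = NA, required = FALSE, help = "beam centre x in fractional pixels (default: image centre)"),
    beam_cy     = list(type = "numeric",   default = NA, required = FALSE, help = "beam centre y in fractional pixels (default: image centre)"),
    nq          = list(type = "integer",   default = NA, required = FALSE, help = "number of radial (q) samples (default: half the image width)"),
    ntheta      = list(type = "integer",   default = 360L, required = FALSE, help = "number of azimuthal samples on [0, 2pi)"),
    qmax        = list(type = "numeric",   default = NA, required = FALSE, help = "maximum q in 1/nm (default: nearest detector edge)"),
    mode        = list(type = "character", default = "standard", required = FALSE, help = "standard | background | difference"),
    mask        = list(type = "character", default = NA, required = FALSE, help = "path to a binary detector mask image"),
    crop        = list(type = "integer",   default = NA, required = FALSE, help = "square crop width about the beam centre, in pixels"),
    rebin       = list(type = "integer",   default = 1L, required = FALSE, help = "integer rebin factor (mean pooling)"),
    interpolation = list(type = "character", default = "cubic", required = FALSE, help = "polar interpolation: cubic | linear"),
    outpath     = list(type = "character", default = ".", required = FALSE, help = "output folder"),
    tag         = list(type = "character", default = "corr", required = FALSE, help = "output file tag"),
    format      = list(type = "character", default = "npy", required = FALSE, help = "volume output format: npy | raw"),
    seed        = list(type = "integer",   default = 1L, required = FALSE, help = "seed for the background/difference pairing")
  ),
  maskcorr = list(
    config      = list(type = "character", default = NA, required = FALSE, help = "path to an INI configuration file"),
    input       = list(type = "character", default = NA, required = TRUE,  help = "input correlation volume"),
    output      = list(type = "character", default = NA, required = TRUE,  help = "output correlation volume"),
    sintheta    = list(type = "logical",   default = TRUE, required = FALSE, help = "apply the |sin theta|^exponent sampling weight"),
    exponent    = list(type = "numeric",   default = 1, required = FALSE, help = "exponent of the |sin theta| weight"),
    qlow        = list(type = "numeric",   default = NA, required = FALSE, help = "low-pass cut in 1/nm"),
    qhigh       = list(type = "numeric",   default = NA, required = FALSE, help = "high-pass cut in 1/nm"),
    thzero_halfwidth = list(type = "numeric", default = NA, required = FALSE, help = "half-width in degrees of the theta=0 noise mask"),
    format      = list(type = "character", default = "npy", required = FALSE, help = "volume output format: npy | raw")
  ),
  corrtopadf = list(
    config      = list(type = "character", default = NA, required = FALSE, help = "path to an INI configuration file"),
    input       = list(type = "character", default = NA, required = TRUE,  help = "input (conditioned) correlation volume"),
    output      = list(type = "character", default = NA, required = TRUE,  help = "output PADF volume"),
    wavelength  = list(type = "numeric",   default = NA, required = TRUE,  help = "wavelength in nm"),
    lmax        = list(type = "integer",   default = 32L, required = FALSE, help = "maximum (even) spherical harmonic order"),
    nr          = list(type = "integer",   default = NA, required = FALSE, help = "number of radial samples (default 2*rmax*qmax)"),
    rmax        = list(type = "numeric",   default = NA, required = TRUE,  help = "maximum real-space distance in nm"),
    regularization = list(type = "numeric", default = 0.5, required = FALSE, help = "relative SVD cutoff for the Legendre inversion"),
    dtheta      = list(type = "numeric",   default = 1, required = FALSE, help = "angular step of the PADF grid in degrees"),
    save_blqq   = list(type = "character", default = NA, required = FALSE, help = "optional path prefix to save B_l(q,q') matrices"),
    save_blrr   = list(type = "character", default = NA, required = FALSE, help = "optional path prefix to save B_l(r,r') matrices"),
    absolute    = list(type = "logical",   default = FALSE, required = FALSE, help = "apply the absolute-scale constants"),
    rho0        = list(type = "numeric",   default = NA, required = FALSE, help = "mean density in 1/nm^3 (absolute mode)"),
    ni          = list(type = "numeric",   default = NA, required = FALSE, help = "incident quanta per exposure (absolute mode)"),
    format      = list(type = "character", default = "npy", required = FALSE, help = "volume output format: npy | raw")
  ),
  plotfxs3d = list(
    config      = list(type = "character", default = NA, required = FALSE, help = "path to an INI configuration file"),
    input       = list(type = "character", default = NA, required = TRUE,  help = "input volume (correlation or PADF)"),
    slice       = list(type = "character", default = "req", required = FALSE, help = "req | theta | r | line-r | line-theta"),
    at          = list(type = "numeric",   default = NA, required = FALSE, help = "slice coordinate (theta in degrees or r in nm)"),
    at2         = list(type = "numeric",   default = NA, required = FALSE, help = "second coordinate for 1D lines"),
    smooth_r    = list(type = "numeric",   default = 0, required = FALSE, help = "radial Gaussian half-width in nm"),
    smooth_th   = list(type = "numeric",   default = 0, required = FALSE, help = "angular Gaussian half-width in degrees"),
    png         = list(type = "character", default = NA, required = TRUE,  help = "output PNG path")
  ),
  diffract = list(
    config      = list(type = "character", default = NA, required = FALSE, help = "path to an INI configuration file"),
    outpath     = list(type = "character", default = ".", required = FALSE, help = "output folder"),
    prefix      = list(type = "character", default = "pattern", required = FALSE, help = "output filename prefix"),
    n_patterns  = list(type = "integer",   default = NA, required = TRUE,  help = "number of patterns to simulate"),
    npix        = list(type = "integer",   default = 256L, required = FALSE, help = "detector width in pixels"),
    wavelength  = list(type = "numeric",   default = 0.1, required = FALSE, help = "wavelength in nm"),
    distance    = list(type = "numeric",   default = 1, required = FALSE, help = "sample-to-detector distance in m"),
    pixel_size  = list(type = "numeric",   default = NA, required = FALSE, help = "pixel width in m (default from q_edge)"),
    q_edge      = list(type = "numeric",   default = 1.28, required = FALSE, help = "q at the nearest detector edge, 1/nm"),
    hexagon_side = list(type = "numeric",  default = 15, required = FALSE, help = "hexagon nearest-neighbour distance in nm"),
    model       = list(type = "character", default = NA, required = FALSE, help = "atom list file (x y z f0 b per line); default: hexagon"),
    solid_angle = list(type = "logical",   default = FALSE, required = FALSE, help = "apply the cos^3 solid-angle factor"),
    photons     = list(type = "numeric",   default = NA, required = FALSE, help = "Poisson photon count per pattern (default: noise free)"),
    seed        = list(type = "integer",   default = 1L, required = FALSE, help = "random seed")
  )
)

#' Parameter registry for a pipeline stage
#'
#' @param stage one of `"difftocorr"`, `"maskcorr"`, `"corrtopadf"`,
#'   `"plotfxs3d"`, `"diffract"`.
#' @return a named list describing each parameter (type, default, required,
#'   help string).
#' @export
param_registry <- function(stage) {
  if (!stage %in% names(.param_registry))
    stop("unknown stage '", stage, "'; stages: ",
         paste(names(.param_registry), collapse = ", "))
  .param_registry[[stage]]
}

.coerce_param <- function(key, value, type) {
  if (is.na(value) && !is.character(value)) return(value)
  switch(type,
    numeric = {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v) && !is.na(value)) stop("parameter '", key, "' must be a number, got '", value, "'")
      v
    },
    integer = {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v) && !is.na(value)) stop("parameter '", key, "' must be an integer, got '", value, "'")
      as.integer(round(v))
    },
    logical = {
      v <- toupper(as.character(value))
      if (v %in% c("TRUE", "T", "1", "YES", "ON")) TRUE
      else if (v %in% c("FALSE", "F", "0", "NO", "OFF")) FALSE
      else stop("parameter '", key, "' must be a logical, got '", value, "'")
    },
    character = as.character(value),
    stop("unknown parameter type '", type, "'")
  )
}

# Minimal INI reader: "key = value" lines, optional "[section]" headers.
# When sections are present only the section named after the stage is used.
.read_ini <- function(path, stage) {
  lines <- trimws(readLines(path, warn = FALSE))
  # whole-line comments only: '#' may appear inside values (filename token)
  lines <- lines[nzchar(lines) & !grepl("^[;#]", lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- trimws(sub("^\\[(.*)\\]$", "\\1", ln))
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("cannot parse config line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (section == "" || section == stage) out[[key]] <- val
  }
  out
}

#' Load stage parameters from a config file and command-line arguments
#'
#' Merges built-in defaults, an INI-style configuration file and command-line
#' flags. The configuration file is read first and command-line values are
#' read second, so command-line values override the configuration file.
#'
#' @param stage stage name (see [param_registry()]).
#' @param config path to an INI file, or `NULL`. A `--config <path>` flag in
#'   `args` takes the same role.
#' @param args character vector of command-line tokens, as flag/value pairs
#'   (`c("--nq", "128", ...)`).
#' @return an object of class `param_set`: list with elements `stage`,
#'   `values` (named list of typed values) and `provenance` (named character,
#'   one of `"default"`, `"config-file"`, `"command-line"` per entry).
#' @export
load_params <- function(stage, config = NULL, args = character()) {
  reg <- param_registry(stage)
  values <- lapply(reg, function(p) p$default)
  provenance <- stats::setNames(rep("default", length(reg)), names(reg))

  # command line parsed first only to find --config; precedence applied below
  if (length(args)) {
    if (length(args) %% 2 != 0)
      stop("command-line arguments must be --flag value pairs")
    flags <- args[seq(1, length(args), 2)]
    if (!all(startsWith(flags, "--")))
      stop("malformed flags: ", paste(flags[!startsWith(flags, "--")], collapse = ", "))
    keys <- substring(flags, 3)
    vals <- args[seq(2, length(args), 2)]
    unknown <- setdiff(keys, names(reg))
    if (length(unknown))
      stop("unknown flag(s) ", paste0("--", unknown, collapse = ", "),
           "; valid flags: ", paste0("--", names(reg), collapse = ", "))
    ci <- match("config", keys)
    if (!is.na(ci)) config <- vals[ci]
  } else {
    keys <- character(); vals <- character()
  }

  if (!is.null(config) && !is.na(config)) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    cfg <- .read_ini(config, stage)
    unknown <- setdiff(names(cfg), names(reg))
    if (length(unknown))
      stop("unknown parameter(s) in config file: ", paste(unknown, collapse = ", "))
    for (k in names(cfg)) {
      values[[k]] <- .coerce_param(k, cfg[[k]], reg[[k]]$type)
      provenance[k] <- "config-file"
    }
    values[["config"]] <- config
  }

  for (i in seq_along(keys)) {
    k <- keys[i]
    values[[k]] <- .coerce_param(k, vals[i], reg[[k]]$type)
    provenance[k] <- "command-line"
  }

  for (k in names(reg)) {
    if (isTRUE(reg[[k]]$required) &&
        (is.null(values[[k]]) || (length(values[[k]]) == 1 && is.na(values[[k]]))))
      stop("missing required parameter '", k, "' for stage '", stage, "'")
  }

  structure(list(stage = stage, values = values, provenance = provenance),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> stage:", x$stage, "\n")
  for (k in names(x$values)) {
    v <- x$values[[k]]
    cat(sprintf("  %-18s = %-20s [%s]\n", k,
                if (length(v) == 1 && is.na(v)) "<unset>" else format(v),
                x$provenance[k]))
  }
  invisible(x)
}

#' Print the flag help for a stage
#' @param stage stage name.
#' @return invisibly, the registry.
#' @export
param_help <- function(stage) {
  reg <- param_registry(stage)
  cat("Parameters for stage '", stage, "':\n", sep = "")
  for (k in names(reg)) {
    d <- reg[[k]]$default
    cat(sprintf("  --%-18s %s%s\n", k, reg[[k]]$help,
                if (length(d) == 1 && !is.na(d)) paste0(" [default: ", d, "]") else ""))
  }
  invisible(reg)
}

## File lists ------------------------------------------------------------------

#' Build an ordered diffraction-file list
#'
#' Matches files in `folder` against `name_format`, where a single `#` token
#' stands for a non-negative integer index. Files are ordered by that integer
#' (ties broken lexicographically), independent of filesystem enumeration
#' order, and truncated to `n_max` entries.
#'
#' @param folder directory to search.
#' @param name_format filename format containing exactly one `#` token.
#' @param n_max maximum number of files to return.
#' @return character vector of full paths.
#' @export
build_file_list <- function(folder, name_format, n_max = Inf) {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  if (lengths(regmatches(name_format, gregexpr("#", name_format, fixed = TRUE))) != 1)
    stop("name_format must contain exactly one '#' token")
  parts <- strsplit(name_format, "#", fixed = TRUE)[[1]]
  if (length(parts) == 1) parts <- c(parts, "")
  quote_lit <- function(s) if (nzchar(s)) paste0("\\Q", s, "\\E") else ""
  rex <- paste0("^", quote_lit(parts[1]), "([0-9]+)", quote_lit(parts[2]), "$")
  files <- list.files(folder)
  m <- regmatches(files, regexec(rex, files, perl = TRUE))
  hit <- lengths(m) == 2
  if (!any(hit)) stop("no diffraction files found in '", folder,
                      "' matching '", name_format, "'")
  files <- files[hit]
  idx <- as.numeric(vapply(m[hit], `[`, character(1), 2))
  ord <- order(idx, files)
  files <- files[ord]
  if (is.finite(n_max)) files <- utils::head(files, n_max)
  file.path(folder, files)
}

## NPY read/write --------------------------------------------------------------

#' Write a numeric array as an NPY (v1.0) file
#'
#' Arrays are stored as little-endian float64 in Fortran (column-major) order,
#' which is the natural memory order of R arrays.
#'
#' @param x numeric vector, matrix or array.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_npy <- function(x, path) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  shape <- paste0("(", paste0(dims, ",", collapse = " "), ")")
  shape <- sub(", \\)$", ")", sub(",\\)$", ",)", shape))
  header <- paste0("{'descr': '<f8', 'fortran_order': True, 'shape': ",
                   shape, ", }")
  # pad so that total header size (magic 6 + 2 + 2 + header) is a multiple of 64
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  if (pad == 64) pad <- 0
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NPY file into a numeric array
#'
#' Supports v1.0/v2.0 headers with little-endian float/integer scalar types,
#' in either C or Fortran order.
#'
#' @param path NPY file path.
#' @return numeric vector, matrix or array.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  if (length(dims) == 0 || any(is.na(dims))) dims <- integer(0)
  n <- if (length(dims)) prod(dims) else 1L
  type <- substring(descr, 2, 2)
  size <- as.integer(substring(descr, 3))
  if (substring(descr, 1, 1) == ">") stop("big-endian NPY not supported")
  x <- switch(type,
    f = readBin(con, "numeric", n, size = size, endian = "little"),
    i = as.numeric(readBin(con, "integer", n, size = size, endian = "little")),
    u = as.numeric(readBin(con, "integer", n, size = size, signed = FALSE, endian = "little")),
    b = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little")),
    stop("unsupported NPY dtype: ", descr)
  )
  if (length(dims) >= 2) {
    if (fortran) dim(x) <- dims
    else { dim(x) <- rev(dims); x <- aperm(x, rev(seq_along(dims))) }
  }
  x
}

## Volume I/O ------------------------------------------------------------------

.sidecar_path <- function(path) paste0(path, ".meta.txt")

.write_sidecar <- function(path, meta) {
  lines <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    paste0(k, " = ", paste(format(v, digits = 17), collapse = " "))
  }, character(1))
  writeLines(lines, .sidecar_path(path))
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  lines <- readLines(sp, warn = FALSE)
  out <- list()
  for (ln in lines[nzchar(trimws(lines))]) {
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- val
  }
  out
}

.meta_num <- function(meta, key) {
  if (is.null(meta[[key]])) return(NULL)
  as.numeric(strsplit(meta[[key]], "\\s+")[[1]])
}

#' Write a 3D volume (correlation or PADF) to disk
#'
#' `npy` writes an NPY v1.0 array, `raw` writes 64-bit little-endian reals
#' with the angular axis fastest-varying. Both formats carry a plain-text
#' sidecar (`<path>.meta.txt`) with the shape, axis names, axis ranges and the
#' volume metadata, so that a round trip reproduces values bit-exactly and
#' metadata exactly.
#'
#' @param vol a `correlation_volume`, `padf_volume`, or plain 3D array.
#' @param path output path.
#' @param format `"npy"` or `"raw"`.
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path, format = c("npy", "raw")) {
  format <- match.arg(format)
  values <- if (is.list(vol)) vol$values else vol
  meta <- list(format = format, shape = dim(values))
  if (inherits(vol, "correlation_volume")) {
    meta$class <- "correlation_volume"
    meta$axes <- c("q", "q", "theta")
    meta$qmax <- max(vol$q)
    meta$theta_range <- max(vol$theta)
    meta$mode <- vol$mode
    meta$n_patterns <- vol$n_patterns
    meta$split <- vol$split
    meta$mask_corrected <- vol$mask_corrected
    if (length(vol$conditioning))
      meta$conditioning <- paste(names(vol$conditioning),
                                 vapply(vol$conditioning, function(v)
                                   paste(format(v, digits = 17), collapse = ","), ""),
                                 sep = ":", collapse = ";")
  } else if (inherits(vol, "padf_volume")) {
    meta$class <- "padf_volume"
    meta$axes <- c("r", "r", "theta")
    meta$rmax <- max(vol$r)
    meta$theta_range <- max(vol$theta)
    meta$lmax <- vol$lmax
    if (length(vol$scaling))
      meta$scaling <- paste(names(vol$scaling),
                            vapply(vol$scaling, function(v)
                              paste(format(v, digits = 17), collapse = ","), ""),
                            sep = ":", collapse = ";")
  } else {
    meta$class <- "array"
    meta$axes <- c("x", "y", "z")[seq_along(dim(values))]
  }
  if (format == "npy") {
    write_npy(values, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    # theta (third axis) fastest-varying in the file
    writeBin(as.numeric(aperm(values, c(3, 1, 2))), con, size = 8,
             endian = "little")
  }
  .write_sidecar(path, meta)
  invisible(path)
}

.parse_kv_string <- function(s) {
  if (is.null(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    k <- sub(":.*$", "", p)
    v <- sub("^[^:]*:", "", p)
    vn <- suppressWarnings(as.numeric(strsplit(v, ",", fixed = TRUE)[[1]]))
    out[[k]] <- if (any(is.na(vn))) v else vn
  }
  out
}

#' Read a volume written by [write_volume()]
#'
#' @param path volume path (the sidecar `<path>.meta.txt` must exist for
#'   raw-binary files and is used, when present, to restore metadata).
#' @return a `correlation_volume`, `padf_volume` or plain array, as written.
#' @export
read_volume <- function(path) {
  meta <- .read_sidecar(path)
  is_npy <- grepl("\\.npy$", path) ||
    (!is.null(meta$format) && meta$format == "npy")
  if (is_npy) {
    values <- read_npy(path)
  } else {
    if (is.null(meta)) stop("raw-binary volume requires the sidecar file ",
                            .sidecar_path(path))
    dims <- as.integer(.meta_num(meta, "shape"))
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
    values <- aperm(array(x, dims[c(3, 1, 2)]), c(2, 3, 1))
  }
  if (is.null(meta) || is.null(meta$class) || meta$class == "array")
    return(values)
  if (meta$class == "correlation_volume") {
    nq <- dim(values)[1]; nth <- dim(values)[3]
    new_correlation_volume(
      values,
      q = seq(0, .meta_num(meta, "qmax"), length.out = nq),
      theta = seq(0, 2 * pi, length.out = nth + 1)[seq_len(nth)],
      mode = meta$mode %||% "standard",
      n_patterns = as.integer(.meta_num(meta, "n_patterns") %||% NA),
      split = meta$split %||% "all",
      mask_corrected = isTRUE(meta$mask_corrected == "TRUE"),
      conditioning = .parse_kv_string(meta$conditioning)
    )
  } else {
    nr <- dim(values)[1]; nth <- dim(values)[3]
    structure(list(
      values = values,
      r = seq_len(nr) * .meta_num(meta, "rmax") / nr,
      theta = seq(0, .meta_num(meta, "theta_range"), length.out = nth),
      lmax = as.integer(.meta_num(meta, "lmax") %||% NA),
      scaling = .parse_kv_string(meta$scaling)
    ), class = "padf_volume")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 2D image (NPY, TIFF or raw binary with sidecar)
#'
#' @param path image path; the format is chosen by extension (`.npy`,
#'   `.tif`/`.tiff`, otherwise raw float64 with a `<path>.meta.txt` sidecar
#'   giving `shape`).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    img <- read_npy(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
  } else {
    meta <- .read_sidecar(path)
    if (is.null(meta)) stop("raw image requires the sidecar file ", .sidecar_path(path))
    dims <- as.integer(.meta_num(meta, "shape"))
    con <- file(path, "rb")
    on.exit(close(con))
    img <- matrix(readBin(con, "numeric", prod(dims), size = 8,
                          endian = "little"), dims[1], dims[2])
  }
  if (is.null(dim(img)) || length(dim(img)) != 2)
    stop("expected a 2D image in ", path)
  img
}
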