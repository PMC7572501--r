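#' Read an image stack from a multi-page TIFF or a slice-file directory
#'
#' Directory sequences are ordered by the numeric value of the last integer
#' group in each filename (robust to inconsistent zero padding), with a
#' lexicographic fallback; the result is invariant under file-system listing
#' order. All pages must be grayscale, unsigned 8- or 16-bit, and share
#' identical dimensions.
#'
#' @param path path to a multi-page TIFF file or a directory of single-page
#'   TIFF slices.
#' @param pattern optional filename glob (e.g. `"s*.tif"`) applied when
#'   `path` is a directory; default matches `.tif`/`.tiff`.
#' @param voxel_size optional `(z, y, x)` voxel spacing in micrometres,
#'   attached as metadata.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pattern = NULL, voxel_size = NULL) {
  if (!file.exists(path))
    stop(sprintf("input path '%s' does not exist", path))
  if (dir.exists(path)) {
    rx <- if (is.null(pattern)) "\\.tiff?$" else utils::glob2rx(pattern)
    files <- list.files(path, pattern = rx, ignore.case = is.null(pattern),
                        full.names = TRUE)
    if (length(files) == 0L)
      stop(sprintf("no TIFF slices matching pattern in '%s'", path))
    files <- files[order_by_trailing_number(basename(files))]
    pages <- list(); bd <- NULL; ref_dim <- NULL
    for (f in files) {
      pg <- read_tiff_pages(f)
      if (is.null(bd)) {
        bd <- pg$bit_depth; ref_dim <- dim(pg$planes[[1L]])
      } else if (pg$bit_depth != bd) {
        stop(sprintf("'%s': bit depth %d differs from first slice (%d)",
                     f, pg$bit_depth, bd))
      }
      for (p in pg$planes) {
        if (!identical(dim(p), ref_dim))
          stop(sprintf("'%s': dimensions %dx%d differ from first slice %dx%d",
                       f, nrow(p), ncol(p), ref_dim[1L], ref_dim[2L]))
        pages[[length(pages) + 1L]] <- p
      }
    }
  } else {
    pg <- read_tiff_pages(path)
    pages <- pg$planes; bd <- pg$bit_depth
    d1 <- dim(pages[[1L]])
    for (i in seq_along(pages))
      if (!identical(dim(pages[[i]]), d1))
        stop(sprintf("page %d of '%s': mixed dimensions", i, path))
  }
  image_stack(pages, bit_depth = bd, voxel_size = voxel_size,
              name = basename(path))
}

# Sort key: numeric value of the LAST integer group in the filename;
# ties / no digits fall back to lexicographic order.
order_by_trailing_number <- function(names) {
  m <- regmatches(names, gregexpr("[0-9]+", names))
  key <- vapply(m, function(g) {
    if (length(g) == 0L) NA_real_ else as.numeric(g[length(g)])
  }, numeric(1L))
  order(key, names, na.last = TRUE)
}

#' Write an image stack losslessly
#'
#' @param stack an [image_stack()].
#' @param path output file (multi-page TIFF) or directory (slice sequence).
#' @param as_sequence write zero-padded single-page files
#'   `slice_000.tif, slice_001.tif, ...` into directory `path` instead of a
#'   single multi-page file.
#' @param overwrite allow clobbering existing output; off by default.
#' @return invisibly, the character vector of files written.
#' @export
write_stack <- function(stack, path, as_sequence = FALSE, overwrite = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$planes)[1L]
  plane_list <- lapply(seq_len(nz), function(z) stack$planes[z, , ])
  if (as_sequence) {
    files <- file.path(path, sprintf("slice_%03d.tif", seq_len(nz) - 1L))
    if (!overwrite && any(file.exists(files)))
      stop(sprintf("output '%s' already has slice files; set overwrite",
                   path))
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (z in seq_len(nz))
      write_tiff_pages(files[z], plane_list[z], stack$bit_depth)
  } else {
    if (!overwrite && file.exists(path))
      stop(sprintf("output '%s' exists; set overwrite", path))
    parent <- dirname(path)
    if (!dir.exists(parent))
      dir.create(parent, recursive = TRUE)
    write_tiff_pages(path, plane_list, stack$bit_depth)
    files <- path
  }
  invisible(files)
}

# ---------------------------------------------------------------------------
# Pipeline configuration

PIPELINE_STAGES <- c("clahe", "destripe", "unsharp", "segment", "colormap")

stage_defaults <- function(stage) {
  switch(stage,
    clahe = list(tile_rows = 8L, tile_cols = 8L, clip_limit = 0.01,
                 n_bins = NULL),  # NULL -> 2^bit_depth at run time
    destripe = list(alpha = "auto", d1 = 5, d2 = "nyquist", w1 = 3, w2 = 9,
                    edge_sigma = 2, attenuation = 1, rescale_mode = "clip"),
    unsharp = list(sigma = 1.5, amount = 0.5, threshold = 0),
    segment = list(scheme = NULL),
    colormap = list(map = "grayscale", display_range = "auto"),
    stop(sprintf("unknown stage '%s'", stage)))
}

#' Load and validate a pipeline configuration
#'
#' The config is a single YAML document with a `schema_version` key, I/O
#' paths, and an ordered `stages` list. Stage names must come from
#' `clahe, destripe, unsharp, segment, colormap`; each may appear at most
#' once; unknown stage names and unknown parameter keys are rejected;
#' omitted parameters are filled with package defaults.
#'
#' @param path path to the YAML file.
#' @return a `pipeline_config` list with fields `stages` (named list in
#'   config order, each a full parameter list), `input_path`, `output_path`,
#'   `overwrite`, `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' does not exist", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "malformed config '%s': %s", path, conditionMessage(e))))
  if (!is.list(doc)) stop(sprintf("malformed config '%s'", path))
  allowed_top <- c("schema_version", "stages", "input", "output",
                   "overwrite", "log_level")
  bad <- setdiff(names(doc), allowed_top)
  if (length(bad) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  pipeline_config(stages = doc$stages, input_path = doc$input,
                  output_path = doc$output,
                  overwrite = isTRUE(doc$overwrite),
                  log_level = if (is.null(doc$log_level)) "info"
                              else doc$log_level)
}

#' Construct a validated pipeline configuration in code
#'
#' @param stages ordered list; each element either a bare stage name or a
#'   one-element named list `list(clahe = list(clip_limit = 0.02))`.
#' @param input_path,output_path I/O paths (optional for in-memory use).
#' @param overwrite logical.
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(stages, input_path = NULL, output_path = NULL,
                            overwrite = FALSE, log_level = "info") {
  if (is.null(stages) || length(stages) == 0L)
    stop("config must list at least one stage")
  if (!log_level %in% c("debug", "info", "warn", "error"))
    stop(sprintf("unknown log_level '%s'", log_level))
  parsed <- list()
  for (s in stages) {
    if (is.character(s) && length(s) == 1L) {
      nm <- s; params <- list()
    } else if (is.list(s) && length(s) == 1L && !is.null(names(s))) {
      nm <- names(s)
      params <- if (is.null(s[[1L]])) list() else s[[1L]]
    } else {
      stop("each stage entry must be a name or a one-element named mapping")
    }
    if (!nm %in% PIPELINE_STAGES)
      stop(sprintf("unknown stage '%s' (known: %s)", nm,
                   paste(PIPELINE_STAGES, collapse = ", ")))
    if (nm %in% names(parsed))
      stop(sprintf("stage '%s' listed more than once", nm))
    defaults <- stage_defaults(nm)
    bad <- setdiff(names(params), names(defaults))
    if (length(bad) > 0L)
      stop(sprintf("stage '%s': unknown parameter(s) %s", nm,
                   paste(bad, collapse = ", ")))
    parsed[[nm]] <- utils::modifyList(defaults, params)
  }
  # user order must not conflict with the canonical chain
  canon <- match(names(parsed), PIPELINE_STAGES)
  if (is.unsorted(canon))
    stop(sprintf(
      "stage order %s conflicts with the canonical chain %s",
      paste(names(parsed), collapse = " -> "),
      paste(PIPELINE_STAGES, collapse = " -> ")))
  structure(list(stages = parsed, input_path = input_path,
                 output_path = output_path, overwrite = overwrite,
                 log_level = log_level),
            class = "pipeline_config")
}

# ---------------------------------------------------------------------------
# Structured logging: timestamp, level, stage, optional plane, message.

LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

lp_log <- function(level, stage, msg, plane = NA_integer_,
                   min_level = getOption("lumipipe.log_level", "warn")) {
  if (LOG_LEVELS[[level]] < LOG_LEVELS[[min_level]]) return(invisible(NULL))
  line <- sprintf("[%s] %-5s %-9s %s%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), toupper(level),
                  stage,
                  if (is.na(plane)) "" else sprintf("plane %d: ", plane),
                  msg)
  message(line)
  invisible(line)
}
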