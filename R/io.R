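# Delimited-text dialect shared by all output files: '#'-prefixed
# 'key=value' header lines carrying flattened metadata (SI units), then a
# tab-separated table with a column-name row. Numbers are written with 17
# significant digits so doubles round-trip exactly.

flatten_meta <- function(meta, prefix = "") {
  out <- character(0)
  for (nm in names(meta)) {
    v <- meta[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) out <- c(out, flatten_meta(v, key))
    else if (is.null(v) || !length(v)) next
    else if (is.numeric(v))
      out <- c(out, paste0(key, "=", paste(sprintf("%.17g", v), collapse = ",")))
    else out <- c(out, paste0(key, "=", paste(v, collapse = ",")))
  }
  out
}

unflatten_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- substr(ln, 1, eq - 1)
    val <- substr(ln, eq + 1, nchar(ln))
    parts <- strsplit(val, ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(parts))
    v <- if (length(parts) && !anyNA(num)) num else
      if (val %in% c("TRUE", "FALSE")) as.logical(val) else parts
    path <- strsplit(key, ".", fixed = TRUE)[[1L]]
    meta <- assign_nested(meta, path, v)
  }
  meta
}

assign_nested <- function(lst, path, value) {
  if (length(path) == 1L) {
    lst[[path]] <- value
  } else {
    sub <- lst[[path[1L]]]
    if (!is.list(sub)) sub <- list()
    lst[[path[1L]]] <- assign_nested(sub, path[-1L], value)
  }
  lst
}

# short FNV-1a hash of the flattened configuration, embedded in every
# output file so a run can be regenerated exactly
config_hash <- function(meta) {
  s <- paste(sort(flatten_meta(meta)), collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_table_with_meta <- function(df, meta, path, what) {
  meta$config_hash <- NULL
  hash <- config_hash(meta)
  hdr <- c(paste0("# needledma_file=", what),
           paste0("# config_hash=", hash),
           paste0("# ", flatten_meta(meta)))
  num <- vapply(df, is.numeric, TRUE)
  body <- df
  body[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(body), sep = "\t")), con)
  invisible(path)
}

read_table_with_meta <- function(path, what) {
  lines <- readLines(path, n = 400L)
  nhdr <- sum(cumprod(startsWith(lines, "#")))
  hdr <- sub("^# ?", "", lines[seq_len(nhdr)])
  if (!any(startsWith(hdr, "needledma_file=")))
    stop("malformed header in '", path, "': missing file-type marker",
         call. = FALSE)
  ftype <- sub("needledma_file=", "", hdr[startsWith(hdr, "needledma_file=")][1L])
  if (!identical(ftype, what))
    stop("'", path, "' is a ", ftype, " file, expected ", what, call. = FALSE)
  meta <- unflatten_meta(hdr[!startsWith(hdr, "needledma_file=")])
  hash <- meta$config_hash
  meta$config_hash <- NULL
  df <- utils::read.delim(path, skip = nhdr, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  list(meta = meta, data = df, n_header = nhdr, config_hash = hash)
}

#' Write a recording to a delimited-text file
#'
#' @param recording a `recording`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  write_table_with_meta(recording$data, recording$meta, path, "recording")
}

#' Read a recording from a delimited-text file
#'
#' Validates the metadata header (mandatory keys) and the time grid
#' (strictly increasing, uniform). A legacy file lacking the
#' `segment_label` column is accepted when the protocol metadata is
#' present: the labels are reconstructed from the protocol's
#' deterministic segmentation.
#'
#' @param path file written by [write_recording()].
#' @return a `recording`.
#' @export
read_recording <- function(path) {
  parsed <- read_table_with_meta(path, "recording")
  meta <- parsed$meta
  dat <- parsed$data
  for (key in c("seed", "probe", "protocol"))
    if (is.null(meta[[key]]))
      stop("read_recording: mandatory metadata key '", key, "' missing in '",
           path, "'", call. = FALSE)
  need <- c("time", "piezo_position", "deflection", "load")
  if (!all(need %in% names(dat)))
    stop("read_recording: missing data columns in '", path, "'", call. = FALSE)
  dtv <- diff(dat$time)
  bad <- which(dtv <= 0 | abs(dtv - stats::median(dtv)) > 1e-6 * stats::median(dtv))
  if (length(bad))
    stop("read_recording: non-monotonic or non-uniform time grid at line ",
         parsed$n_header + 2L + bad[1L], " of '", path, "'", call. = FALSE)
  meta$seed <- as.integer(meta$seed)
  if (!is.null(meta$contact_index)) meta$contact_index <- as.integer(meta$contact_index)
  if (is.null(dat$segment_label)) {
    proto <- try(do.call(sweep_protocol, meta$protocol), silent = TRUE)
    if (inherits(proto, "try-error"))
      stop("read_recording: no segment labels and no usable protocol metadata in '",
           path, "'", call. = FALSE)
    seg <- protocol_segments(proto)
    if (sum(seg$n) != nrow(dat))
      stop("read_recording: protocol segmentation does not match the number of samples in '",
           path, "'", call. = FALSE)
    dat$segment_label <- rep(seg$label, seg$n)
  }
  structure(list(data = dat, meta = meta), class = "recording")
}

#' Write / read a sweep result table
#'
#' Columns `frequency_hz, F1_N, h1_m, phase_rad, h0_m, G_storage_Pa,
#' G_loss_Pa, qc_flags` with the shared metadata-header dialect.
#'
#' @param result a `sweep_result`.
#' @param path file path.
#' @return the path ([write_sweep_result()]) or a `sweep_result`
#'   ([read_sweep_result()]).
#' @export
write_sweep_result <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  tb <- result$table
  out <- data.frame(frequency_hz = tb$frequency, F1_N = tb$F1, h1_m = tb$h1,
                    phase_rad = tb$phase, h0_m = tb$h0,
                    G_storage_Pa = tb$storage, G_loss_Pa = tb$loss,
                    qc_flags = ifelse(nzchar(tb$qc_flags), tb$qc_flags, "-"),
                    stringsAsFactors = FALSE)
  write_table_with_meta(out, result$meta, path, "sweep_result")
}

#' @rdname write_sweep_result
#' @export
read_sweep_result <- function(path) {
  parsed <- read_table_with_meta(path, "sweep_result")
  d <- parsed$data
  tb <- data.frame(frequency = d$frequency_hz, F1 = d$F1_N, h1 = d$h1_m,
                   phase = d$phase_rad, h0 = d$h0_m,
                   storage = d$G_storage_Pa, loss = d$G_loss_Pa,
                   qc_flags = ifelse(d$qc_flags == "-", "", d$qc_flags),
                   stringsAsFactors = FALSE)
  structure(list(table = tb, meta = parsed$meta), class = "sweep_result")
}

#' Write an aggregate result table
#'
#' @param aggregate an `aggregate_result`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_aggregate_result <- function(aggregate, path) {
  stopifnot(inherits(aggregate, "aggregate_result"))
  write_table_with_meta(aggregate$table,
                        list(n_sweeps = aggregate$n_sweeps), path,
                        "aggregate_result")
}

#' Read a simulation run configuration
#'
#' YAML file with flat sections `probe`, `contact`, `protocol`, `model`,
#' `stick_slip` (optional) plus top-level `seed` and `fidelity`; all
#' values SI. Returns the constructed configuration objects ready for
#' [simulate_measurement()].
#'
#' @param path YAML config file.
#' @return list with elements `model`, `probe`, `contact`, `protocol`,
#'   `stick_slip`, `seed`, `fidelity`, `rigid`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed))
    stop("read_run_config: 'seed' is mandatory for simulation runs",
         call. = FALSE)
  probe <- do.call(probe_config, cfg$probe %||% list())
  contact <- do.call(contact_config,
                     cfg$contact %||% list(bead_radius = probe$bead_radius))
  protocol <- do.call(sweep_protocol, cfg$protocol %||% list())
  rigid <- isTRUE(cfg$model$kind == "rigid")
  model <- if (rigid) NULL else do.call(rheology_model, cfg$model)
  ss <- do.call(stick_slip_config, cfg$stick_slip %||% list())
  list(model = model, probe = probe, contact = contact, protocol = protocol,
       stick_slip = ss, seed = as.integer(cfg$seed),
       fidelity = cfg$fidelity %||% "deflection", rigid = rigid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
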