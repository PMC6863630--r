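#' Assemble a dataset of recorded cells and their sweeps
#'
#' The dataset is the package's container for one experiment: a cell
#' table, a sweep table (with the traces as a list-column), the stimulus
#' protocols the sweeps reference, and free-form provenance metadata
#' (including the random seed when the data are synthetic).
#'
#' @param cells Tibble with at least `cell_id` (unique) and optionally
#'   `projection_class` (`GP_STN`, `GP_CPu`, `GP_Bi`, `MSN`, `STN`,
#'   `putative_cholinergic`, `unknown`), `cortical_source` (`M1`, `M2`),
#'   `series_resistance` (MOhm) and per-marker status columns.
#' @param sweeps Tibble with columns `cell_id`, `sweep_id`,
#'   `protocol_id` and `sweep` (list-column of [opto_sweep()] objects).
#' @param protocols Named list of protocol objects referenced by
#'   `sweeps$protocol_id`.
#' @param metadata Free-form list of provenance fields.
#' @return An `opto_dataset`.
#' @export
opto_dataset <- function(cells = tibble::tibble(cell_id = character()),
                         sweeps = tibble::tibble(cell_id = character(),
                                                 sweep_id = character(),
                                                 protocol_id = character(),
                                                 sweep = list()),
                         protocols = list(),
                         metadata = list()) {
  d <- structure(
    list(cells = tibble::as_tibble(cells),
         sweeps = tibble::as_tibble(sweeps),
         protocols = protocols,
         metadata = metadata),
    class = "opto_dataset"
  )
  validate_dataset(d)
}

projection_classes <- c("GP_STN", "GP_CPu", "GP_Bi", "MSN", "STN",
                        "putative_cholinergic", "unknown")
cortical_sources <- c("M1", "M2", "Cg", "LO")

#' Validate an opto_dataset's invariants
#'
#' Checks unique cell ids, closed vocabularies for projection class and
#' cortical source, finite samples, and that every sweep references an
#' existing cell and protocol.
#'
#' @param d An `opto_dataset`.
#' @return `d`, invisibly-validated (errors on violation).
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "opto_dataset"))
  if (anyDuplicated(d$cells$cell_id)) {
    stop_validation("cell ids must be unique")
  }
  if ("projection_class" %in% names(d$cells) &&
      !all(d$cells$projection_class %in% projection_classes)) {
    stop_validation("unknown projection_class value")
  }
  if ("cortical_source" %in% names(d$cells) &&
      !all(is.na(d$cells$cortical_source) |
           d$cells$cortical_source %in% cortical_sources)) {
    stop_validation("unknown cortical_source value")
  }
  if (nrow(d$sweeps) > 0) {
    if (!all(d$sweeps$cell_id %in% d$cells$cell_id)) {
      stop_validation("sweep references a cell_id absent from the cell table")
    }
    if (!all(d$sweeps$protocol_id %in% c(names(d$protocols), NA_character_))) {
      stop_validation("sweep references an unknown protocol_id")
    }
    ok <- vapply(d$sweeps$sweep, inherits, logical(1), what = "opto_sweep")
    if (!all(ok)) stop_validation("`sweeps$sweep` must hold opto_sweep objects")
  }
  d
}

#' @export
print.opto_dataset <- function(x, ...) {
  cat(sprintf("<opto_dataset> %d cells, %d sweeps, %d protocols\n",
              nrow(x$cells), nrow(x$sweeps), length(x$protocols)))
  if (!is.null(x$metadata$seed)) cat("  synthetic, seed", x$metadata$seed, "\n")
  invisible(x)
}

fmt_full <- function(x) sprintf("%.17g", x)

serialize_protocol <- function(p) {
  c(list(.type = class(p)[1]), unclass(p))
}

deserialize_protocol <- function(l) {
  type <- l$.type
  l$.type <- NULL
  l <- lapply(l, unlist)
  switch(type,
    light_stim_protocol = {
      p <- light_stim_protocol(
        n_pulses = l$n_pulses, train_freq = l$train_freq,
        pulse_duration = l$pulse_duration,
        first_onset = l$pulse_onsets[1],
        n_trains = l$n_trains,
        inter_train_interval = l$inter_train_interval,
        tail = l$sweep_duration - l$pulse_onsets[length(l$pulse_onsets)]
      )
      p$pulse_onsets <- as.numeric(l$pulse_onsets)
      p
    },
    current_step_protocol = current_step_protocol(
      step_amplitudes = l$step_amplitudes, step_duration = l$step_duration,
      pre_baseline = l$pre_baseline, post_baseline = l$post_baseline
    ),
    brief_pulse_protocol = brief_pulse_protocol(
      pulse_duration = l$pulse_duration, amplitudes = l$amplitudes,
      pre_baseline = l$pre_baseline, post_baseline = l$post_baseline
    ),
    stop_format("unknown protocol type in manifest: ", type)
  )
}

#' Save a dataset to disk
#'
#' Two dialects are supported. `"container"` writes a directory holding
#' a JSON manifest (cells, sweep index, protocols, metadata) and one
#' plain-text sample file per sweep, written at full double precision so
#' that the round trip is bit-exact. `"tabular"` writes a single
#' two-column `time_s,value` text file and therefore requires a dataset
#' with exactly one sweep.
#'
#' @param d An `opto_dataset`.
#' @param path Target directory (container) or file (tabular).
#' @param dialect `"container"` or `"tabular"`.
#' @return `path`, invisibly.
#' @seealso [load_dataset()]
#' @export
save_dataset <- function(d, path, dialect = c("container", "tabular")) {
  dialect <- rlang::arg_match(dialect)
  validate_dataset(d)
  if (dialect == "tabular") {
    if (nrow(d$sweeps) != 1) {
      stop_arg("tabular dialect stores exactly one sweep; dataset has ",
               nrow(d$sweeps))
    }
    sw <- d$sweeps$sweep[[1]]
    lines <- c("time_s,value",
               paste(fmt_full(sweep_times(sw)), fmt_full(as.numeric(sw)), sep = ","))
    writeLines(lines, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(path, "sweeps"), showWarnings = FALSE)
  sweep_index <- d$sweeps
  sweep_index$file <- sprintf("sweeps/%03d.txt", seq_len(nrow(sweep_index)))
  for (i in seq_len(nrow(sweep_index))) {
    sw <- sweep_index$sweep[[i]]
    con <- file.path(path, sweep_index$file[i])
    writeLines(
      c(sprintf("# sampling_rate=%s clamp_mode=%s t0=%s holding=%s",
                fmt_full(attr(sw, "sampling_rate")), attr(sw, "clamp_mode"),
                fmt_full(attr(sw, "t0")), fmt_full(attr(sw, "holding"))),
        fmt_full(as.numeric(sw))),
      con
    )
  }
  manifest <- list(
    format = "optopallidum-container",
    version = 1L,
    cells = d$cells,
    sweeps = sweep_index[, setdiff(names(sweep_index), "sweep")],
    protocols = lapply(d$protocols, serialize_protocol),
    metadata = d$metadata
  )
  # I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

parse_sweep_file <- function(file) {
  lines <- readLines(file)
  hdr <- lines[1]
  if (!startsWith(hdr, "# sampling_rate=")) {
    stop_format("sweep file ", file, " is missing its header line")
  }
  kv <- regmatches(hdr, gregexpr("[a-z0-9_]+=[^ ]+", hdr))[[1]]
  fields <- stats::setNames(
    sub("^[a-z0-9_]+=", "", kv),
    sub("=.*$", "", kv)
  )
  samples <- as.numeric(lines[-1])
  opto_sweep(samples,
             sampling_rate = as.numeric(fields[["sampling_rate"]]),
             clamp_mode = fields[["clamp_mode"]],
             t0 = as.numeric(fields[["t0"]]),
             holding = as.numeric(fields[["holding"]]))
}

#' Load a dataset from disk
#'
#' Counterpart of [save_dataset()]. For the tabular dialect the sampling
#' rate is inferred from the (required, uniform) time column; a
#' non-uniform time grid or non-finite sample is a validation error.
#'
#' @param path Directory (container) or file (tabular).
#' @param dialect `"container"` or `"tabular"`.
#' @return An `opto_dataset`.
#' @export
load_dataset <- function(path, dialect = c("container", "tabular")) {
  dialect <- rlang::arg_match(dialect)
  if (!file.exists(path)) stop_format("path does not exist: ", path)
  if (dialect == "tabular") {
    tab <- utils::read.csv(path, colClasses = "numeric")
    if (!identical(names(tab), c("time_s", "value"))) {
      stop_format("tabular dialect requires the header `time_s,value`")
    }
    dt <- diff(tab$time_s)
    if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1e-12))) {
      stop_validation("non-uniform sampling in tabular file")
    }
    sw <- opto_sweep(tab$value, sampling_rate = 1 / dt[1],
                     clamp_mode = "voltage_clamp", t0 = tab$time_s[1])
    return(opto_dataset(
      cells = tibble::tibble(cell_id = "cell_1"),
      sweeps = tibble::tibble(cell_id = "cell_1", sweep_id = "sweep_1",
                              protocol_id = NA_character_, sweep = list(sw))
    ))
  }
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_format("container is missing its manifest.json sidecar")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                                  simplifyMatrix = FALSE)
  if (!identical(manifest$format, "optopallidum-container")) {
    stop_format("not an optopallidum container: ", path)
  }
  sweep_index <- tibble::as_tibble(manifest$sweeps)
  sweeps <- if (nrow(sweep_index) > 0) {
    sweep_index$sweep <- lapply(file.path(path, sweep_index$file), parse_sweep_file)
    sweep_index[, c("cell_id", "sweep_id", "protocol_id", "sweep")]
  } else {
    tibble::tibble(cell_id = character(), sweep_id = character(),
                   protocol_id = character(), sweep = list())
  }
  protocols <- lapply(manifest$protocols, deserialize_protocol)
  cells <- tibble::as_tibble(manifest$cells)
  if (nrow(cells) == 0 && !"cell_id" %in% names(cells)) {
    cells <- tibble::tibble(cell_id = character())
  }
  opto_dataset(
    cells = cells,
    sweeps = sweeps,
    protocols = protocols,
    metadata = manifest$metadata
  )
}

#' Series-resistance check from a brief test pulse
#'
#' Estimates access (series) resistance from the peak capacitive
#' transient evoked by a brief voltage step (-10 mV for 10 ms in the
#' recordings this models): `Rs = |dV| / |I_peak|`. A recording passes
#' the quality gate iff `Rs` is strictly below the threshold.
#'
#' @param sweep Voltage-clamp `opto_sweep` carrying a `test_pulse`
#'   attribute: a list with `onset` (s), `duration` (ms) and `delta_mv`
#'   (step size, mV).
#' @param threshold Pass threshold in MOhm (default 25).
#' @return One-row tibble with `rs_mohm` and `pass`.
#' @export
check_series_resistance <- function(sweep, threshold = 25) {
  stopifnot(inherits(sweep, "opto_sweep"))
  if (attr(sweep, "clamp_mode") != "voltage_clamp") {
    stop_protocol("series-resistance check requires a voltage-clamp sweep")
  }
  tp <- attr(sweep, "test_pulse")
  if (is.null(tp)) {
    stop_protocol("sweep carries no test-pulse annotation")
  }
  if (is.null(tp$delta_mv) || !is.finite(tp$delta_mv) || tp$delta_mv == 0) {
    stop_protocol("test pulse has zero or missing step amplitude")
  }
  fs <- sampling_rate(sweep)
  i_on <- s_to_samples(tp$onset - attr(sweep, "t0"), fs) + 1L
  i_off <- i_on + ms_to_samples(tp$duration, fs) - 1L
  if (i_on < 2 || i_off > length(sweep)) {
    stop_protocol("test pulse window falls outside the sweep")
  }
  baseline <- mean(sweep[seq_len(i_on - 1L)])
  transient <- sweep[i_on:i_off] - baseline
  i_peak <- max(abs(transient))
  if (i_peak == 0) stop_protocol("no transient current in the test-pulse window")
  rs <- abs(tp$delta_mv) / i_peak * 1000 # mV / pA -> GOhm -> MOhm via *1000
  tibble::tibble(rs_mohm = rs, pass = rs < threshold)
}
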