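# Configuration files, CSV/JSON input-output and deterministic fixtures.

run_defaults <- function() {
  list(n_cycles = 110, discard = 20, phases_n = 50,
       phase_lo = 0.02, phase_hi = 0.98, dt = 0.02,
       tol = 0.05, window = 10, seed = 1L)
}

#' Load a network configuration file
#'
#' Reads a YAML or JSON file whose keys mirror the model symbols: `P1i`,
#' `P2i`, `P3i`, `g12`, `g23`, `g32`, an optional `neuron` block
#' (`gCa`, ..., `I0`), an optional `synapse` block (`alpha_on`, `beta_off`,
#' `T_half`, `T_scale`) and an optional `run` block (`n_cycles`, `discard`,
#' `phases_n`, `dt`, `seed`, ...). Missing run settings are filled with
#' defaults; schema violations are reported with the offending keys.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return list with elements `network` (a [network_config()]) and `run`
#'   (completed run settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("P1i", "P2i", "P3i", "g12", "g23", "g32",
             "neuron", "synapse", "run")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  num_keys <- c("P1i", "P2i", "P3i", "g12", "g23", "g32")
  for (k in num_keys)
    if (!is.null(raw[[k]]) && (!is.numeric(raw[[k]]) || length(raw[[k]]) != 1))
      stop("config key must be a numeric scalar: ", k)
  for (k in c("g12", "g23", "g32"))
    if (!is.null(raw[[k]]) && raw[[k]] < 0)
      stop("negative synaptic conductance: ", k)
  for (k in c("P1i", "P2i", "P3i"))
    if (!is.null(raw[[k]]) && raw[[k]] <= 0)
      stop("intrinsic period must be positive: ", k)
  neuron <- do.call(ml_neuron, raw$neuron %||% list())
  synk <- do.call(synapse, c(list(gsyn = 0), raw$synapse %||% list()))
  args <- raw[intersect(num_keys, names(raw))]
  net <- do.call(network_config,
                 c(args, list(neuron = neuron, syn_kinetics = synk)))
  run <- utils::modifyList(run_defaults(), raw$run %||% list())
  if (run$tol <= 0 || run$dt <= 0) stop("run tolerances must be positive")
  list(network = net, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read spike trains as CSV
#'
#' Long format with columns `neuron_id`, `spike_time`.
#'
#' @param trains named list of [spike_train()]s.
#' @param path output file.
#' @export
write_spike_csv <- function(trains, path) {
  df <- do.call(rbind, lapply(names(trains), function(id)
    data.frame(neuron_id = id, spike_time = as.numeric(trains[[id]]))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("neuron_id", "spike_time") %in% names(df)))
  lapply(split(df$spike_time, df$neuron_id), spike_train)
}

#' Write and read a PRC table as CSV
#'
#' Commented header lines carry the intrinsic period and synapse metadata so
#' the file round-trips losslessly through [read_prc_csv()].
#'
#' @param table a [prc_table()].
#' @param path output file.
#' @export
write_prc_csv <- function(table, path) {
  stopifnot(inherits(table, "prc_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Pi: %.15g", attr(table, "Pi")), con)
  if (!is.null(attr(table, "label")))
    writeLines(paste0("# label: ", attr(table, "label")), con)
  writeLines("phi,F", con)
  utils::write.table(data.frame(table), con, sep = ",", col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_prc_csv
#' @export
read_prc_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  pi_line <- grep("^# Pi:", hdr, value = TRUE)
  if (!length(pi_line)) stop("not a PRC csv: missing '# Pi:' header")
  Pi <- as.numeric(sub("^# Pi:\\s*", "", pi_line[1]))
  lab_line <- grep("^# label:", hdr, value = TRUE)
  label <- if (length(lab_line)) sub("^# label:\\s*", "", lab_line[1]) else NULL
  df <- utils::read.csv(path, comment.char = "#")
  prc_table(df$phi, df$F, Pi, label = label)
}

#' Deterministic synthetic fixtures
#'
#' Reproducible synthetic objects for testing and demonstration:
#' \describe{
#'   \item{`"spike_trains"`}{three periodic trains: the slave (`n2`) firing
#'     at `period`, the interneuron (`n3`) offset by `offsets[1]` and the
#'     master (`n1`) by `offsets[2]` after each slave spike.}
#'   \item{`"prc_table"`}{a normal-form PRC sampled on a grid, with optional
#'     additive Gaussian noise of standard deviation `sigma`.}
#'   \item{`"stability_matrix"`}{a list of random 2x2 matrices with entries
#'     uniform on `[-max_entry, max_entry]`.}
#' }
#' The same `(type, parameters, seed)` always yields the identical object;
#' the caller's RNG state is left untouched.
#'
#' @param type fixture kind (see above).
#' @param period,offsets,n_cycles spike-train parameters.
#' @param amplitude,Pi,n_points,sigma PRC-table parameters (normal-form
#'   amplitude, period, grid size, noise sd).
#' @param n_matrices,max_entry stability-matrix parameters.
#' @param seed integer seed.
#' @return the synthetic object.
#' @export
make_fixture <- function(type = c("spike_trains", "prc_table",
                                  "stability_matrix"),
                         period = 60, offsets = c(15, 40), n_cycles = 30,
                         amplitude = -0.1, Pi = 70, n_points = 50, sigma = 0,
                         n_matrices = 1, max_entry = 2, seed = 1L) {
  type <- match.arg(type)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  switch(type,
    spike_trains = {
      stopifnot(offsets[1] < offsets[2], offsets[2] < period)
      base <- period * seq(0, n_cycles)
      list(n1 = spike_train(base[-length(base)] + offsets[2]),
           n2 = spike_train(base),
           n3 = spike_train(base[-length(base)] + offsets[1]))
    },
    prc_table = {
      phi <- seq(0.02, 0.98, length.out = n_points)
      F <- amplitude * (1 - cos(2 * pi * phi)) + stats::rnorm(n_points, 0, sigma)
      prc_table(phi, pmax(F, -0.999), Pi,
                label = sprintf("synthetic normal form c=%g sigma=%g",
                                amplitude, sigma))
    },
    stability_matrix = {
      out <- lapply(seq_len(n_matrices), function(i)
        matrix(stats::runif(4, -max_entry, max_entry), 2, 2))
      if (n_matrices == 1) out[[1]] else out
    })
}

#' Write a JSON report
#'
#' Serializes modes, stability results, measurements or comparison tables
#' with `jsonlite` (auto-unboxed, full precision).
#'
#' @param x object to serialize (lists, data.frames, package S3 objects).
#' @param path output file.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, complex = "list")
  invisible(path)
}

strip_classes <- function(x) {
  if (inherits(x, "stability_result")) {
    x$eigenvalues <- list(mod = Mod(x$eigenvalues), re = Re(x$eigenvalues),
                          im = Im(x$eigenvalues))
    x$A <- as.vector(x$A)
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  if (inherits(x, "spike_train")) return(as.numeric(x))
  x
}
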