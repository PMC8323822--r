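#' Read and write spike trains as CSV
#'
#' On-disk format: header `neuron_id,time_s`, 0-based neuron ids, times in
#' seconds sorted within neuron. Out-of-order rows are auto-sorted with a
#' warning; non-numeric fields are reported with their line numbers.
#'
#' @param trains a [spike_train_set()].
#' @param path file path.
#' @param n_neurons total neuron count (so trailing silent neurons are
#'   kept); default `max(neuron_id) + 1`.
#' @param duration recording duration in seconds; default just past the
#'   last spike.
#' @param one_based treat ids on disk as 1-based.
#' @return `read_spikes` returns a [spike_train_set()].
#' @export
write_spikes <- function(trains, path) {
  stopifnot(inherits(trains, "spike_train_set"))
  df <- data.frame(
    neuron_id = rep(0:(trains$n_neurons - 1L), lengths(trains$spike_times)),
    time_s = unlist(trains$spike_times, use.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, n_neurons = NULL, duration = NULL,
                        one_based = FALSE) {
  df <- read.csv(path, colClasses = "character")
  if (!all(c("neuron_id", "time_s") %in% names(df)))
    stop("missing header: expected columns neuron_id,time_s in ", path)
  ids <- suppressWarnings(as.integer(df$neuron_id))
  ts <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(is.na(ids) | is.na(ts))
  if (length(bad))
    stop("non-numeric fields in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", ")) # +1 for the header line
  if (one_based) ids <- ids - 1L
  if (nrow(df) == 0) {
    return(spike_train_set(rep(list(numeric(0)), n_neurons %||% 0L),
                           duration %||% 1))
  }
  if (is.null(n_neurons)) n_neurons <- max(ids) + 1L
  if (is.null(duration)) duration <- max(ts) * (1 + 1e-9) + 1e-9
  st <- rep(list(numeric(0)), n_neurons)
  sp <- split(ts, factor(ids, levels = 0:(n_neurons - 1L)))
  unsorted <- any(vapply(sp, is.unsorted, logical(1)))
  if (unsorted) {
    warning("spike times not sorted within neuron in ", path,
            "; sorting them")
    sp <- lapply(sp, sort)
  }
  spike_train_set(unname(lapply(sp, unname)), duration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write ground-truth edge lists as CSV
#'
#' Format: header `src,dst,weight,delay_ms`, 0-based ids.
#'
#' @param model a [network_model()].
#' @param path file path.
#' @param n_neurons neuron count; default `max(id) + 1`.
#' @param one_based treat ids on disk as 1-based.
#' @export
write_truth <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  write.csv(model$edges[, c("src", "dst", "weight", "delay_ms")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path, n_neurons = NULL, one_based = FALSE) {
  df <- read.csv(path)
  if (!all(c("src", "dst") %in% names(df)))
    stop("missing header: expected columns src,dst[,weight,delay_ms] in ",
         path)
  if (is.null(df$weight)) df$weight <- 1
  if (is.null(df$delay_ms)) df$delay_ms <- 1
  if (one_based) { df$src <- df$src - 1L; df$dst <- df$dst - 1L }
  if (is.null(n_neurons))
    n_neurons <- if (nrow(df)) max(df$src, df$dst) + 1L else 0L
  network_model(n_neurons, df)
}

#' Read and write connectivity / frequency matrices as CSV
#'
#' Matrices are written with a neuron-id header row and a leading
#' `neuron_id` column; frequencies are written with 9 significant digits so
#' multiples of `1/K` round-trip exactly to reading precision.
#'
#' @param m binary matrix (`write_adjacency`) or [frequency_matrix()]
#'   (`write_frequency`).
#' @param path file path.
#' @export
write_adjacency <- function(m, path) {
  stopifnot(is.matrix(m))
  write_matrix_csv(m, path, function(v) as.integer(v))
}

#' @rdname write_adjacency
#' @export
write_frequency <- function(m, path) {
  if (inherits(m, "frequency_matrix")) {
    K <- m$K
    m <- m$values
  } else K <- NA_integer_
  write_matrix_csv(m, path, function(v) sprintf("%.9g", v), K = K)
}

write_matrix_csv <- function(m, path, fmt, K = NA_integer_) {
  n <- nrow(m)
  ids <- 0:(n - 1)
  cols <- lapply(seq_len(n), function(cc) fmt(m[, cc]))
  df <- data.frame(cols)
  names(df) <- ids
  df <- cbind(neuron_id = ids, df)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(K)) writeLines(sprintf("# K=%d", K), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- read.csv(path, skip = skip, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square: ", nrow(m), " x ", ncol(m))
  dimnames(m) <- NULL
  m
}

#' @rdname write_adjacency
#' @export
read_frequency <- function(path) {
  first <- readLines(path, n = 1)
  K <- if (grepl("^# K=", first))
    as.integer(sub("^# K=", "", first)) else NA_integer_
  m <- read_adjacency(path)
  if (is.na(K)) frequency_matrix(m, K = 1L) else frequency_matrix(m, K = K)
}

#' Write the peak table of a peak graph as CSV
#'
#' Columns: `j,k,tau_ms,amplitude,width_ms,removed,removal_reason`.
#'
#' @param pg a [peak_graph()].
#' @param path file path.
#' @export
write_peaks <- function(pg, path) {
  stopifnot(inherits(pg, "peak_graph"))
  write.csv(pg$peaks, path, row.names = FALSE)
  invisible(path)
}

#' Write a correlation-triangle audit table as CSV
#'
#' Columns `j,k,m,tau_jk,tau_km,tau_mj,closure_ms,flagged,removed_pair`;
#' `removed_pair` names the stored pair of the triangle peak marked removed
#' in `pg` (empty when none is).
#'
#' @param triangles data frame from [enumerate_triangles()] /
#'   [flag_triangles()].
#' @param path file path.
#' @param pg optionally, the pruned [peak_graph()] used to fill
#'   `removed_pair`.
#' @export
write_triangles <- function(triangles, path, pg = NULL) {
  out <- triangles[, c("j", "k", "m", "tau_jk", "tau_km", "tau_mj")]
  out$closure_ms <- triangles$closure
  out$flagged <- triangles$flagged
  out$removed_pair <- ""
  if (!is.null(pg)) {
    rem <- which(pg$peaks$removed)
    pair_of <- function(pid) paste0("(", pg$peaks$j[pid], ",", pg$peaks$k[pid], ")")
    for (col in c("pid_jk", "pid_km", "pid_mj")) {
      hit <- triangles[[col]] %in% rem & out$removed_pair == ""
      out$removed_pair[hit] <- vapply(triangles[[col]][hit], pair_of, "")
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a thresholded digraph as GraphML
#'
#' Nodes carry `in_degree` and `out_degree` attributes.
#'
#' @param m binary connectivity matrix.
#' @param path file path.
#' @export
write_graphml <- function(m, path) {
  stopifnot(is.matrix(m))
  g <- igraph::graph_from_adjacency_matrix(m != 0, mode = "directed")
  igraph::V(g)$name <- as.character(0:(nrow(m) - 1))
  igraph::V(g)$in_degree <- igraph::degree(g, mode = "in")
  igraph::V(g)$out_degree <- igraph::degree(g, mode = "out")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write waveform snippets as CSV (first column `time_s`, then samples)
#' @param waveforms a [waveform_set()].
#' @param path file path.
#' @export
write_waveforms <- function(waveforms, path) {
  stopifnot(inherits(waveforms, "waveform_set"))
  df <- data.frame(time_s = waveforms$event_times, waveforms$snippets)
  names(df) <- c("time_s", paste0("s", seq_len(ncol(waveforms$snippets))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveforms
#' @param sample_interval_ms sampling interval in ms.
#' @export
read_waveforms <- function(path, sample_interval_ms = 0.05) {
  df <- read.csv(path)
  if (names(df)[1] != "time_s")
    stop("missing header: expected first column time_s in ", path)
  waveform_set(as.matrix(df[, -1, drop = FALSE]), df$time_s,
               sample_interval_ms)
}

#' Run configuration
#'
#' Assembles and validates the knobs of a full reconstruction run before
#' any computation starts. Unknown fields are rejected.
#'
#' @param profile `"sim"` or `"mea"` (sets grid defaults).
#' @param dt_ms correlogram bin width.
#' @param mode `"raw"` or `"pearson"`.
#' @param T_values,sigma_values,epsilon grid overrides (ms).
#' @param d discrimination threshold in `[0, 1]`.
#' @param min_prominence_frac,noise_z peak-detection knobs.
#' @param window_ms receiver-probability window.
#' @param seed integer seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(profile = "sim", dt_ms = 0.1, mode = "pearson",
                       T_values = NULL, sigma_values = NULL, epsilon = NULL,
                       d = 1, min_prominence_frac = 0.2, noise_z = 4,
                       window_ms = 15, seed = 1L) {
  profile <- match.arg(profile, c("sim", "mea"))
  mode <- match.arg(mode, c("raw", "pearson"))
  base <- default_grid(profile)
  if (is.null(T_values)) T_values <- unique(base$T)
  if (is.null(sigma_values)) sigma_values <- unique(base$sigma)
  if (is.null(epsilon)) epsilon <- base$epsilon[1]
  stopifnot(dt_ms > 0, d >= 0, d <= 1,
            min_prominence_frac > 0, min_prominence_frac <= 1,
            noise_z >= 0, window_ms > 0,
            all(T_values > 0), all(sigma_values > 0), epsilon > 0)
  structure(list(profile = profile, dt_ms = dt_ms, mode = mode,
                 T_values = T_values, sigma_values = sigma_values,
                 epsilon = epsilon, d = d,
                 min_prominence_frac = min_prominence_frac,
                 noise_z = noise_z, window_ms = window_ms,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
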