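#' Write a network/drive/protocol configuration as flat text
#'
#' Serializes the three configuration objects to a sectioned `key = value`
#' text file (`[neuron]`, `[structure]`, `[weights]`, `[heterogeneity]`,
#' `[drive]`, `[sim]`). [read_spec_config()] round-trips exactly.
#'
#' @param spec A `network_spec`.
#' @param drive A `drive_spec`.
#' @param config A `sim_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spec_config <- function(spec, drive, config, path) {
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  sec <- function(name, values)
    c(sprintf("[%s]", name),
      sprintf("%s = %s", names(values), vapply(values, fmt, "")), "")
  lines <- c(
    sec("neuron", spec$constants[c("tau_m", "V_r", "theta_mean", "tau_ref")]),
    sec("structure", spec$structure[c("N", "gamma", "eps")]),
    sec("weights", spec$weights[c("J_EE", "J_IE", "J_EI", "J_II")]),
    sec("heterogeneity", spec$heterogeneity[c("w_E", "w_I")]),
    sec("drive", unclass(drive)),
    sec("sim", config[c("duration", "dt", "transient", "n_trials",
                        "master_seed")]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_spec_config()]
#'
#' @param path Path to the config file.
#' @return A list with `spec`, `drive`, `config`.
#' @export
read_spec_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NULL
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      out[[section]][[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
    }
  }
  g <- function(s, k) out[[s]][[k]]
  list(
    spec = network_spec(
      constants = neuron_constants(g("neuron", "tau_m"), g("neuron", "V_r"),
                                   g("neuron", "theta_mean"),
                                   g("neuron", "tau_ref")),
      structure = population_structure(g("structure", "N"),
                                       g("structure", "gamma"),
                                       g("structure", "eps")),
      weights = synaptic_weights(g("weights", "J_EE"), g("weights", "J_IE"),
                                 g("weights", "J_EI"), g("weights", "J_II")),
      heterogeneity = heterogeneity_levels(g("heterogeneity", "w_E"),
                                           g("heterogeneity", "w_I"))),
    drive = drive_spec(g("drive", "mu"), g("drive", "mu0"),
                       g("drive", "sigma"), g("drive", "S0"),
                       g("drive", "f_s")),
    config = sim_config(g("sim", "duration"), g("sim", "dt"),
                        g("sim", "transient"), g("sim", "n_trials"),
                        g("sim", "master_seed")))
}

#' Write spikes as plain two-column text
#'
#' Columns `time_ms`, `neuron` after a commented header recording the
#' duration, dt and population sizes; [read_spikes()] round-trips
#' bit-exactly.
#'
#' @param spikes A `spike_data` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spikes <- function(spikes, path) {
  sizes <- attr(spikes, "population_sizes")
  hdr <- c("# spike data: time_ms neuron",
           sprintf("# duration_ms = %.17g", attr(spikes, "duration")),
           sprintf("# dt_ms = %.17g", attr(spikes, "dt")),
           sprintf("# n_E = %d", sizes[["E"]]),
           sprintf("# n_I = %d", sizes[["I"]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(time_ms = sprintf("%.17g", spikes$time),
               neuron = spikes$neuron),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spikes written by [write_spikes()]
#'
#' @param path Path to a spike file.
#' @return A `spike_data` tibble (population labels reconstructed from
#'   the header sizes).
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("# ", key, " ="), hdr, fixed = TRUE)]
    as.numeric(sub(".*= ", "", ln))
  }
  n_e <- as.integer(get("n_E")); n_i <- as.integer(get("n_I"))
  body <- lines[!startsWith(lines, "#")]
  if (length(body)) {
    parts <- strsplit(body, " ", fixed = TRUE)
    time <- as.numeric(vapply(parts, `[[`, "", 1))
    neuron <- as.integer(vapply(parts, `[[`, "", 2))
  } else {
    time <- numeric(0); neuron <- integer(0)
  }
  out <- tibble::tibble(time = time, neuron = neuron,
                        population = ifelse(neuron <= n_e, "E", "I"))
  structure(out, class = c("spike_data", class(out)),
            duration = get("duration_ms"), dt = get("dt_ms"),
            n_neurons = n_e + n_i,
            population_sizes = c(E = n_e, I = n_i))
}

#' Write a network realization as a documented columnar text file
#'
#' Header block (spec parameters + seed), a threshold table
#' (`index label theta_mV`) and an edge list (`post pre weight_mV`).
#' [read_realization()] round-trips bit-exactly.
#'
#' @param realization A `network_realization`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_realization <- function(realization, path) {
  sp <- realization$spec
  con <- file(path, "w")
  on.exit(close(con))
  flat <- c(sp$constants[c("tau_m", "V_r", "theta_mean", "tau_ref")],
            sp$structure[c("N", "gamma", "eps")],
            sp$weights, sp$heterogeneity,
            list(seed = realization$seed_record))
  writeLines(c("# network realization",
               sprintf("# %s = %.17g", names(flat), as.numeric(flat)),
               "# thresholds: index label theta_mV"), con)
  writeLines(sprintf("T %d %s %.17g", seq_along(realization$thresholds),
                     realization$population, realization$thresholds), con)
  m <- methods::as(realization$connectivity, "TsparseMatrix")
  writeLines("# edges: post pre weight_mV", con)
  if (length(m@i))
    writeLines(sprintf("E %d %d %.17g", m@i + 1L, m@j + 1L, m@x), con)
  invisible(path)
}

#' Read a realization written by [write_realization()]
#'
#' @param path Path to a realization file.
#' @return A `network_realization`.
#' @export
read_realization <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("# ", key, " ="), hdr, fixed = TRUE)]
    as.numeric(sub(".*= ", "", ln))
  }
  spec <- network_spec(
    constants = neuron_constants(get("tau_m"), get("V_r"),
                                 get("theta_mean"), get("tau_ref")),
    structure = population_structure(get("N"), get("gamma"), get("eps")),
    weights = synaptic_weights(get("J_EE"), get("J_IE"),
                               get("J_EI"), get("J_II")),
    heterogeneity = heterogeneity_levels(get("w_E"), get("w_I")))
  tl <- lines[startsWith(lines, "T ")]
  tp <- strsplit(tl, " ", fixed = TRUE)
  th <- as.numeric(vapply(tp, `[[`, "", 4))
  pop <- vapply(tp, `[[`, "", 3)
  el <- lines[startsWith(lines, "E ")]
  n <- length(th)
  if (length(el)) {
    ep <- strsplit(el, " ", fixed = TRUE)
    conn <- Matrix::sparseMatrix(
      i = as.integer(vapply(ep, `[[`, "", 2)),
      j = as.integer(vapply(ep, `[[`, "", 3)),
      x = as.numeric(vapply(ep, `[[`, "", 4)), dims = c(n, n))
  } else {
    conn <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(n, n))
  }
  structure(list(thresholds = th, population = pop, connectivity = conn,
                 spec = spec, seed_record = as.integer(get("seed"))),
            class = "network_realization")
}
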