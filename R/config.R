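#' Read a plain-text experiment configuration
#'
#' Configs are INI-style: `[section-type name]` headers followed by
#' `key = value` lines; values are numeric scalars, comma-separated numeric
#' vectors, or strings. Recognized section types: `simulation`, `population`,
#' `synapses`, `fiber`, `uniform_light`, `opsin`, `probe`. Lines starting
#' with `#` are comments.
#'
#' @param path Config file path.
#' @return Nested list: one entry per section with fields `type`, `name`, and
#'   the parsed keys.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sections <- list()
  current <- NULL
  parse_value <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) return(nums)
    if (length(parts) == 1) parts else parts
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      hdr <- strsplit(gsub("\\[|\\]", "", ln), "\\s+")[[1]]
      current <- length(sections) + 1
      sections[[current]] <- list(type = hdr[1],
                                  name = if (length(hdr) > 1) hdr[2]
                                         else hdr[1])
    } else if (grepl("=", ln)) {
      if (is.null(current)) stop("key before any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      sections[[current]][[key]] <- parse_value(paste(kv[-1],
                                                      collapse = "="))
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  sections
}

#' Build a simulation from a parsed configuration
#'
#' @param cfg Output of [read_config()].
#' @return List with `sim` (a [simulation()] with populations, synapses, and
#'   devices injected) and `duration_ms`.
#' @export
build_simulation <- function(cfg) {
  get1 <- function(type) Filter(function(s) s$type == type, cfg)
  simsec <- get1("simulation")
  if (length(simsec) != 1) stop("config needs exactly one [simulation]")
  simsec <- simsec[[1]]
  sim <- simulation(dt = simsec$dt %||% 0.1, seed = simsec$seed)
  for (s in get1("population")) {
    n <- s$n
    geom <- s$geometry %||% "box"
    coords <- if (geom == "box") {
      box <- s$box %||% c(150, 150, 100)
      cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
    } else if (geom == "disc") {
      r <- (s$diameter %||% 2000) / 2 * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), 0)
    } else stop("unknown geometry '", geom, "'")
    pop <- neuron_population(coords,
                             cell_type = s$cell_type %||% "excitatory",
                             model = s$model %||% "lif",
                             tau_m = s$tau_m %||% 20,
                             v_rest = s$v_rest %||% -70,
                             v_thresh = s$v_thresh %||% -50,
                             v_reset = s$v_reset %||% -70,
                             R = s$R %||% 1,
                             refractory_ms = s$refractory %||% 2,
                             bias = s$bias %||% 0,
                             noise_sd = s$noise_sd %||% 0,
                             name = s$name)
    add_population(sim, pop)
  }
  for (s in get1("synapses")) {
    ns <- length(sim$populations[[s$source]]$ids)
    nt <- length(sim$populations[[s$target]]$ids)
    m <- matrix(runif(ns * nt) < (s$p %||% 0.1), ns, nt)
    if (s$source == s$target) diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    add_synapses(sim, synapse_group(s$source, s$target, idx[, 1], idx[, 2],
                                    weight = s$weight %||% 1,
                                    delay_ms = s$delay %||% 0,
                                    receptor = s$receptor %||% "AMPA",
                                    tau_syn_ms = s$tau_syn %||% 5))
  }
  inject_all <- function(dev, targets) {
    for (pn in targets) inject(sim, dev, pn)
  }
  for (s in get1("fiber")) {
    fib <- optic_fiber(tip = s$tip %||% c(0, 0, 0),
                       direction = s$direction %||% c(0, 0, 1),
                       radius = s$radius %||% 100,
                       NA_ = s$`NA` %||% 0.37,
                       wavelength_nm = s$wavelength %||% 473)
    inject_all(light_device(fib, label = s$name, value = s$irr0 %||% 0),
               s$targets)
  }
  for (s in get1("uniform_light")) {
    inject_all(light_device(uniform_light(s$wavelength %||% 473),
                            label = s$name, value = s$irr0 %||% 0),
               s$targets)
  }
  for (s in get1("opsin")) {
    model <- if ((s$model %||% "simple") == "simple") {
      simple_opsin(s$k %||% 1)
    } else {
      opsin_markov_params(s$opsin %||% "ChR2")
    }
    spectrum <- if (!is.null(s$opsin)) action_spectrum(s$opsin) else NULL
    inject_all(opsin_device(model, spectrum,
                            expression_model(s$p_expr %||% 1),
                            label = s$name),
               s$targets)
  }
  for (s in get1("probe")) {
    arr <- if ((s$type %||% "linear") == "linear") {
      linear_probe(start = s$start %||% c(0, 0, 0),
                   direction = s$direction %||% c(0, 0, 1),
                   n_contacts = s$n_contacts %||% 32,
                   pitch_um = s$pitch %||% 25)
    } else {
      mea_grid(pitch_um = s$pitch %||% 200)
    }
    inject_all(spike_probe(arr, mode = s$mode %||% "mua", label = s$name),
               s$targets)
  }
  list(sim = sim, duration_ms = simsec$duration %||% 100)
}

#' Run a configured experiment and export outputs
#'
#' Builds the simulation from a config file, runs it, and writes per
#' population ground-truth spike CSVs (`time_ms, channel_or_unit,
#' population`) and per-probe detected-spike CSVs into `out_dir`.
#'
#' @param config_path Path to a config file (see [read_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Paths of the written files, invisibly.
#' @export
run_config <- function(config_path, out_dir = ".") {
  built <- build_simulation(read_config(config_path))
  run(built$sim, built$duration_ms)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (pn in names(built$sim$populations)) {
    sp <- get_spikes(built$sim, pn)
    p <- file.path(out_dir, paste0("spikes_", pn, ".csv"))
    utils::write.csv(data.frame(time_ms = sp$time_ms,
                                channel_or_unit = sp$neuron,
                                population = rep(pn, nrow(sp))),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (lab in names(built$sim$devices)) {
    if (!inherits(built$sim$devices[[lab]]$device, "spike_probe")) next
    p <- file.path(out_dir, paste0("probe_", lab, ".csv"))
    write_spikes_csv(device_output(built$sim, lab), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
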