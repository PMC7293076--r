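# Flat-text serializers: INI-style configs, genome checkpoints, history and
# trajectory tables, JSON run manifests. Everything round-trips at full
# double precision so checkpointed populations replay bit-identically.

CONFIG_KEYS <- list(
  world = c("arena_width", "arena_height", "n_boars", "n_stags",
            "trial_steps", "capture_steps", "robot_radius", "prey_radius",
            "wheel_speed_max", "axle_length", "prox_range"),
  payoffs = c("boar_coop", "stag_coop", "solo"),
  evolution = c("population_size", "n_elites", "n_partners",
                "trials_per_pair", "scheme"),
  mutation = c("per_gene_prob", "sd", "duplication_prob", "deletion_prob",
               "duplication_enabled"),
  protocol = c("preset", "scale", "n_replicates", "base_seed",
               "pre_generations", "post_generations", "generations"))

parseIni <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ";")]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(CONFIG_KEYS))
        stop("unknown config section [", section, "]", call. = FALSE)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section))
        stop("config key outside any [section]: ", ln, call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% CONFIG_KEYS[[section]])
        stop("unknown config key '", key, "' in section [", section, "]",
             call. = FALSE)
      out[[section]][[key]] <- val
    } else stop("malformed config line: ", ln, call. = FALSE)
  }
  out
}

coerceLike <- function(value, template) {
  if (is.logical(template)) as.logical(value)
  else if (is.integer(template)) as.integer(value)
  else if (is.numeric(template)) as.numeric(value)
  else as.character(value)
}

#' Load and resolve a run configuration
#'
#' Reads a flat INI-style configuration (sections `[world]`, `[payoffs]`,
#' `[evolution]`, `[mutation]`, `[protocol]`) on top of a named preset; any
#' key not present in the file keeps the preset/default value. Unknown
#' sections or keys, and out-of-range values, raise an error naming the
#' offender.
#'
#' @param path Path to a config file, or `NULL` to use the preset alone.
#' @param preset Preset name (see [protocolPreset()]); default `"simple"`.
#' @param scale Problem scale, `"desk"` or `"paper"`.
#' @return An object of class `RunConfig`: `world`, `payoffs`, `evolution`,
#'   and `protocol` (preset name, scale, replicate count, base seed, phase
#'   generations).
#' @examples
#' ini <- system.file("extdata", "example-config.ini", package = "staghunt")
#' rc <- loadConfig(ini)
#' rc$world
#' @export
loadConfig <- function(path = NULL, preset = c("simple", "complex",
                                               "complex-asym", "wright-fisher"),
                       scale = c("desk", "paper")) {
  raw <- if (is.null(path)) list() else parseIni(path)
  if (!is.null(raw$protocol$preset)) preset <- raw$protocol$preset
  if (!is.null(raw$protocol$scale)) scale <- raw$protocol$scale
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  proto <- protocolPreset(preset, scale = scale)
  ph1 <- proto$phases[[1]]
  world <- ph1$world
  payoffs <- payoffScheme()
  evo <- ph1$evolution
  mut <- evo$mutation
  override <- function(obj, section) {
    for (key in names(raw[[section]])) {
      obj[[key]] <- coerceLike(raw[[section]][[key]], obj[[key]])
    }
    obj
  }
  world <- validateWorldConfig(override(world, "world"))
  payoffs <- do.call(payoffScheme, unclass(override(payoffs, "payoffs")))
  mut_l <- unclass(override(mut, "mutation"))
  mut <- do.call(mutationConfig, mut_l)
  evo_l <- unclass(override(evo, "evolution"))
  evo_l$mutation <- mut
  evo_l$eval_seed <- NULL
  evo <- do.call(evolutionConfig, evo_l)
  gens <- vapply(proto$phases, `[[`, 1L, "generations")
  pr <- list(preset = preset, scale = scale,
             n_replicates = proto$n_replicates, base_seed = proto$base_seed,
             pre_generations = if (length(gens) == 2) gens[1] else 0L,
             post_generations = gens[length(gens)])
  for (key in setdiff(names(raw$protocol), c("preset", "scale")))
    pr[[key]] <- coerceLike(raw$protocol[[key]], pr[[key]])
  structure(list(world = world, payoffs = payoffs, evolution = evo,
                 protocol = pr), class = "RunConfig")
}

#' @rdname loadConfig
#' @param config A `RunConfig`.
#' @export
configProtocol <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  pr <- config$protocol
  pre_pay <- payoffScheme(boar_coop = config$payoffs$boar_coop, stag_coop = 0,
                          solo = config$payoffs$solo)
  phases <- list()
  if (pr$pre_generations > 0)
    phases <- c(phases, list(phase(pr$pre_generations, config$world, pre_pay,
                                   config$evolution)))
  phases <- c(phases, list(phase(pr$post_generations, config$world,
                                 config$payoffs, config$evolution)))
  protocol(phases, n_replicates = pr$n_replicates, base_seed = pr$base_seed)
}

#' @rdname loadConfig
#' @export
dumpConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 17)
  }
  lines <- character(0)
  secs <- list(world = unclass(config$world), payoffs = unclass(config$payoffs),
               evolution = unclass(config$evolution)[CONFIG_KEYS$evolution],
               mutation = unclass(config$evolution$mutation),
               protocol = config$protocol)
  for (s in names(secs)) {
    lines <- c(lines, paste0("[", s, "]"))
    vals <- secs[[s]]
    for (k in names(vals)) lines <- c(lines, paste0(k, " = ", fmt(vals[[k]])))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

FORMAT_TAG <- "staghunt-genomes v1"

#' Serialize genomes as structured text
#'
#' One record per genome: lineage id and network count on a header line,
#' then one line of 410 genes per network at full double precision (17
#' significant digits), so that restored populations replay bit-identically.
#'
#' @param genomes A list of [genome()]s (or a single genome).
#' @param path Output file.
#' @param generation,seed Optional checkpoint metadata stored in the header.
#' @return `path`, invisibly.
#' @export
writeGenomes <- function(genomes, path, generation = NA, seed = NA) {
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", FORMAT_TAG),
               paste("meta", "generation", generation),
               paste("meta", "seed", seed),
               paste("n_genomes", length(genomes))), con)
  for (g in genomes) {
    writeLines(paste("genome", g$lineage_id, length(g$networks)), con)
    for (net in g$networks)
      writeLines(paste(sprintf("%.17g", net), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname writeGenomes
#' @return `readGenomes()`: the list of genomes, with attributes
#'   `generation` and `seed` when present.
#' @export
readGenomes <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], paste0("# ", FORMAT_TAG)))
    stop("not a ", FORMAT_TAG, " file: ", path, call. = FALSE)
  meta <- list()
  i <- 2L
  while (startsWith(lines[i], "meta ")) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    meta[[parts[2]]] <- parts[3]
    i <- i + 1L
  }
  n <- as.integer(strsplit(lines[i], " ")[[1]][2])
  i <- i + 1L
  genomes <- vector("list", n)
  for (k in seq_len(n)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (hdr[1] != "genome") stop("corrupt genome record at line ", i, call. = FALSE)
    nn <- as.integer(hdr[3])
    nets <- lapply(seq_len(nn), function(j)
      as.numeric(strsplit(lines[i + j], " ", fixed = TRUE)[[1]]))
    genomes[[k]] <- genome(nets, lineage_id = hdr[2])
    i <- i + 1L + nn
  }
  gen <- suppressWarnings(as.integer(meta$generation))
  sd <- suppressWarnings(as.integer(meta$seed))
  attr(genomes, "generation") <- gen
  attr(genomes, "seed") <- sd
  genomes
}

#' Write / read a per-generation history table
#'
#' Tab-delimited with a header row; one row per generation (see
#' [runReplicate()] for the columns).
#'
#' @param history A `ReplicateHistory` (or its `records` data frame).
#' @param path File path.
#' @export
writeHistory <- function(history, path) {
  rec <- if (inherits(history, "ReplicateHistory")) history$records else history
  write.table(rec, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHistory
#' @export
readHistory <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Write trial logs as flat delimited tables
#'
#' `writeTrajectory()` writes per-step robot poses (requires a trial run
#' with `recordTrajectory = TRUE`); `writeEvents()` writes the capture-event
#' log.
#'
#' @param trial A `TrialResult`.
#' @param path File path.
#' @export
writeTrajectory <- function(trial, path) {
  if (is.null(trial$trajectory))
    stop("trial was run without recordTrajectory = TRUE", call. = FALSE)
  tr <- as.data.frame(trial$trajectory)
  names(tr) <- c("xA", "yA", "headingA", "xB", "yB", "headingB")
  tr <- cbind(step = seq_len(nrow(tr)), tr)
  write.table(tr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
writeEvents <- function(trial, path) {
  write.table(trial$events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for provenance
#'
#' Captures everything needed to reproduce a study bit-identically: package
#' version, base seed, per-replicate derived seeds, and the full protocol
#' description (phase generations, world, payoff, evolution and mutation
#' parameters).
#'
#' @param protocol A [protocol()].
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list, invisibly when written.
#' @export
runManifest <- function(protocol, path = NULL) {
  stopifnot(inherits(protocol, "Protocol"))
  man <- list(
    package = "staghunt",
    version = as.character(packageVersion("staghunt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = protocol$base_seed,
    n_replicates = protocol$n_replicates,
    replicate_seeds = vapply(seq_len(protocol$n_replicates), function(i)
      bitwXor(protocol$base_seed, i), 1L),
    seeded_population = !is.null(protocol$initial_population),
    phases = lapply(protocol$phases, function(ph) list(
      generations = ph$generations,
      world = unclass(ph$world),
      payoffs = unclass(ph$payoffs),
      evolution = c(unclass(ph$evolution)[c("population_size", "n_elites",
                                            "n_partners", "trials_per_pair",
                                            "scheme")],
                    list(mutation = unclass(ph$evolution$mutation))))))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
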