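fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

meta_header <- function(meta) {
  keys <- names(meta)
  vapply(keys, function(k) sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")),
         character(1))
}

parse_header <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}

#' Write / read peak-intensity tables
#'
#' Plain-text exchange format for decay series: `#` header lines carrying
#' the sample label, metadata and the delay schedule (seconds), then one
#' row per residue (residue index followed by one intensity per delay).
#' Numbers are written at full double precision so that write/read round
#' trips are exact to numerical tolerance.
#'
#' @param series_list list of [peak_series()] (one sample).
#' @param path output file.
#' @return `write_intensity_table` returns `path` invisibly;
#'   `read_intensity_table` (see [read_intensity_table()]) reads the
#'   format back.
#' @export
write_intensity_table <- function(series_list, path) {
  stopifnot(length(series_list) >= 1L)
  s1 <- series_list[[1L]]
  meta <- s1$sample
  hdr <- c(sprintf("# sample: %s", s1$sample_label),
           meta_header(meta),
           sprintf("# delays: %s", paste(fmt_num(s1$delays), collapse = " ")))
  rows <- vapply(series_list, function(s) {
    paste(c(s$residue_index, fmt_num(s$intensities)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

read_meta_sample <- function(h) {
  keys <- c("visible_species", "invisible_species", "label_site", "ratio", "arm")
  meta <- list()
  for (k in keys) if (!is.null(h[[k]])) {
    v <- h[[k]]
    meta[[k]] <- if (k %in% c("label_site")) as.integer(v)
                 else if (k == "ratio") as.numeric(v) else v
  }
  meta
}

#' Read an intensity table written by [write_intensity_table()]
#'
#' Thin wrapper around [read_intensity_table()] that also restores the
#' structured sample metadata from the header.
#'
#' @param path file path.
#' @return list of [peak_series()].
#' @export
read_intensity_table_meta <- function(path) {
  h <- parse_header(readLines(path, warn = FALSE))
  read_intensity_table(path, sample = read_meta_sample(h))
}

#' Write / read per-residue relaxation tables
#'
#' @param profile a `relaxation_profile` from [fit_profile()].
#' @param path output file.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(inherits(profile, "relaxation_profile"))
  meta <- attr(profile, "sample") %||% list()
  hdr <- c(meta_header(meta),
           sprintf("# noise: %s", fmt_num(attr(profile, "noise"))),
           paste("residue", "r2", "r2_error", "amplitude", "fit_quality",
                 sep = "\t"))
  rows <- vapply(seq_len(nrow(profile)), function(i) {
    paste(c(profile$residue[i], fmt_num(c(profile$r2[i], profile$r2_error[i],
                                          profile$amplitude[i],
                                          profile$fit_quality[i]))),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_profile_table
#' @export
read_profile_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- parse_header(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  out <- tibble::as_tibble(tab)
  attr(out, "noise") <- as.numeric(h$noise %||% NA)
  attr(out, "sample") <- read_meta_sample(h)
  attr(out, "failures") <- tibble::tibble(residue = integer(),
                                          reason = character())
  class(out) <- c("relaxation_profile", class(out))
  out
}

#' Write / read PRE profile tables
#'
#' @param profile a `pre_profile` from [compute_pre()].
#' @param path output file.
#' @export
write_pre_table <- function(profile, path) {
  stopifnot(inherits(profile, "pre_profile"))
  meta <- attr(profile, "sample") %||% list()
  hdr <- c(meta_header(meta),
           paste("residue", "gamma2", "gamma2_error", "significant",
                 sep = "\t"))
  rows <- vapply(seq_len(nrow(profile)), function(i) {
    paste(c(profile$residue[i],
            fmt_num(c(profile$gamma2[i], profile$gamma2_error[i])),
            as.integer(profile$significant[i])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_pre_table
#' @export
read_pre_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- parse_header(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  out <- tibble::tibble(residue = as.integer(tab$residue),
                        gamma2 = tab$gamma2,
                        gamma2_error = tab$gamma2_error,
                        significant = as.logical(tab$significant))
  attr(out, "sample") <- read_meta_sample(h)
  class(out) <- c("pre_profile", class(out))
  out
}

#' Load and validate a run configuration
#'
#' A run configuration (YAML or JSON) carries the experimental constants
#' (species, sequences, spin-label sites, delay schedules, concentrations,
#' ratios), the analysis thresholds (8 s^-1 significance floor, 2x mean
#' factor, 15 s^-1 selection threshold and its point ordinal, the
#' model-selection margin), the seed, and an index of peak-table files
#' keyed by kind (`map` or `titration`), spin-label site, arm and ratio.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`), or a list
#'   already in memory.
#' @param base_dir directory table paths are relative to (default: the
#'   configuration file's directory).
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(path, base_dir = NULL) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.character(path)) base_dir <- base_dir %||% dirname(path)
  base_dir <- base_dir %||% "."
  cfg$base_dir <- base_dir
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    floor = th$floor %||% 8, mean_factor = th$mean_factor %||% 2,
    select_threshold = th$select_threshold %||% 15,
    select_point = th$select_point,
    margin = th$margin %||% 2)
  if (any(unlist(cfg$thresholds[c("floor", "mean_factor",
                                  "select_threshold", "margin")]) <= 0))
    abort2("thresholds must be positive", "prekd_config")
  if (!is.null(cfg$ratios) && is.unsorted(cfg$ratios))
    abort2("ratios must be sorted increasing", "prekd_config")
  if (!is.null(cfg$tables)) {
    cfg$tables <- as.data.frame(cfg$tables)
    for (p in cfg$tables$path)
      if (!file.exists(file.path(base_dir, p)))
        abort2(paste0("referenced table does not exist: ", p), "prekd_config")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[prekd:%s] %s", stage, sprintf(...)))
}

#' Simulate a scenario and write a fixture tree
#'
#' Writes, under `out_dir`: the scenario configuration (`config.yaml`),
#' the generating truth (`truth.tsv`) and baseline rates
#' (`baseline.tsv`), contact-map peak tables for every spin-label site at
#' 1:1 mixing (`tables/map/`), and titration peak tables for the probe
#' site at every ratio (`tables/titration/`). Deterministic for a fixed
#' seed: the same call writes byte-identical tables.
#'
#' @param scenario_name `"homo"`, `"hetero"` or `"beta-beta"`.
#' @param seed integer seed.
#' @param out_dir output directory (created).
#' @param titration_site probe site of the titration arm.
#' @return the written configuration, invisibly.
#' @export
run_simulate <- function(scenario_name, seed = 1L, out_dir,
                         titration_site = 44L) {
  cfg <- scenario(scenario_name, seed = seed)
  dir.create(file.path(out_dir, "tables", "map"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables", "titration"), recursive = TRUE,
             showWarnings = FALSE)
  index <- list()
  for (site in cfg$spin_label_sites) {
    for (arm in c("para", "dia")) {
      p <- file.path("tables", "map",
                     sprintf("site%03d_%s_ratio1.tsv", site, arm))
      series <- simulate_peak_tables(cfg, 1, arm, site = site)
      write_intensity_table(series, file.path(out_dir, p))
      index[[length(index) + 1L]] <- data.frame(
        path = p, kind = "map", site = site, arm = arm, ratio = 1)
    }
  }
  for (k in seq_along(cfg$ratios)) {
    rt <- cfg$ratios[k]
    for (arm in c("para", "dia")) {
      p <- file.path("tables", "titration",
                     sprintf("site%03d_%s_ratio%04.0f.tsv", titration_site,
                             arm, rt * 1000))
      series <- simulate_peak_tables(
        cfg, rt, arm, site = titration_site, delays = cfg$titration_delays,
        seed = derive_seed(derive_seed(cfg$seed, titration_site, "titration"),
                           k, arm))
      write_intensity_table(series, file.path(out_dir, p))
      index[[length(index) + 1L]] <- data.frame(
        path = p, kind = "titration", site = titration_site, arm = arm,
        ratio = rt)
    }
  }
  readr::write_tsv(cfg$truth, file.path(out_dir, "truth.tsv"))
  readr::write_tsv(cfg$baseline, file.path(out_dir, "baseline.tsv"))
  conf <- list(
    scenario = cfg$name, seed = cfg$seed,
    visible_species = cfg$visible_species,
    invisible_species = cfg$invisible_species,
    visible_sequence = cfg$visible_sequence,
    invisible_sequence = cfg$invisible_sequence,
    spin_label_sites = cfg$spin_label_sites,
    visible_concentration = cfg$visible_concentration,
    ratios = cfg$ratios, noise = cfg$noise,
    occupancy_model = cfg$occupancy_model,
    delays = cfg$delays, titration_delays = cfg$titration_delays,
    thresholds = list(floor = 8, mean_factor = 2, select_threshold = 15,
                      margin = 2),
    tables = do.call(rbind, index))
  yaml::write_yaml(conf, file.path(out_dir, "config.yaml"))
  stage_log("simulate", "scenario '%s' seed %d -> %s (%d tables)",
            cfg$name, cfg$seed, out_dir, length(index))
  invisible(run_config(file.path(out_dir, "config.yaml")))
}

load_series_file <- function(cfg, path) {
  full <- file.path(cfg$base_dir, path)
  if (!file.exists(full))
    abort2(paste0("missing table: ", path), "prekd_io")
  read_intensity_table_meta(full)
}

#' Fit relaxation profiles for every table of a run
#'
#' Reads each peak table referenced by the configuration, fits the
#' per-residue decay rates, writes one relaxation table per sample under
#' `out_dir/r2/` and logs fitted/failed counts.
#'
#' @param cfg a [run_config()] (or path to one).
#' @param out_dir output directory.
#' @return tibble index of written files, invisibly.
#' @export
run_fit_r2 <- function(cfg, out_dir) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(cfg$tables) || !nrow(cfg$tables))
    abort2("run configuration lists no tables", "prekd_config")
  dir.create(file.path(out_dir, "r2"), recursive = TRUE, showWarnings = FALSE)
  idx <- cfg$tables
  idx$r2_path <- NA_character_
  for (i in seq_len(nrow(idx))) {
    series <- load_series_file(cfg, idx$path[i])
    prof <- fit_profile(series)
    p <- file.path("r2", paste0(sub("\\.tsv$", "", basename(idx$path[i])),
                                "_r2.tsv"))
    write_profile_table(prof, file.path(out_dir, p))
    idx$r2_path[i] <- p
    stage_log("fit-r2", "%s: %d fitted, %d failed", basename(idx$path[i]),
              nrow(prof), nrow(attr(prof, "failures")))
  }
  invisible(tibble::as_tibble(idx))
}

#' Compute PRE profiles from fitted relaxation tables
#'
#' Pairs the paramagnetic and diamagnetic relaxation tables of each
#' (kind, site, ratio) combination, computes \eqn{\Gamma_2} profiles with
#' the configured significance thresholds, and writes one PRE table per
#' pair under `out_dir/pre/`.
#'
#' @param cfg a [run_config()].
#' @param r2_index index returned by [run_fit_r2()].
#' @param out_dir output directory (also the base of `r2_index` paths).
#' @return tibble index of PRE tables, invisibly.
#' @export
run_compute_pre <- function(cfg, r2_index, out_dir) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(file.path(out_dir, "pre"), recursive = TRUE, showWarnings = FALSE)
  key <- unique(r2_index[, c("kind", "site", "ratio")])
  out <- list()
  for (i in seq_len(nrow(key))) {
    sel <- r2_index[r2_index$kind == key$kind[i] &
                    r2_index$site == key$site[i] &
                    r2_index$ratio == key$ratio[i], ]
    pp <- sel$r2_path[sel$arm == "para"]
    dp <- sel$r2_path[sel$arm == "dia"]
    if (length(pp) != 1L || length(dp) != 1L)
      abort2(sprintf("missing %s arm for kind=%s site=%d ratio=%g",
                     if (!length(pp)) "paramagnetic" else "diamagnetic",
                     key$kind[i], key$site[i], key$ratio[i]), "prekd_io")
    para <- read_profile_table(file.path(out_dir, pp))
    dia <- read_profile_table(file.path(out_dir, dp))
    prof <- compute_pre(para, dia, floor = cfg$thresholds$floor,
                        mean_factor = cfg$thresholds$mean_factor)
    p <- file.path("pre", sprintf("%s_site%03d_ratio%04.0f_pre.tsv",
                                  key$kind[i], key$site[i],
                                  key$ratio[i] * 1000))
    write_pre_table(prof, file.path(out_dir, p))
    out[[i]] <- data.frame(kind = key$kind[i], site = key$site[i],
                           ratio = key$ratio[i], pre_path = p)
    stage_log("compute-pre", "%s: %d residues, %d significant", p,
              nrow(prof), sum(prof$significant))
  }
  invisible(tibble::as_tibble(do.call(rbind, out)))
}

#' Build and export the contact map of a run
#'
#' @param cfg a [run_config()].
#' @param pre_index index returned by [run_compute_pre()].
#' @param out_dir output directory.
#' @param ratio mixing ratio of the map experiment.
#' @return the [build_contact_map()] object, invisibly. Writes the
#'   long-format table (`contact_map.tsv`) and a rendered heat map
#'   (`contact_map.png`).
#' @export
run_contact_map <- function(cfg, pre_index, out_dir, ratio = 1) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  sel <- pre_index[pre_index$kind == "map" & pre_index$ratio == ratio, ]
  if (!nrow(sel)) abort2("no map-kind PRE tables at this ratio", "prekd_io")
  profiles <- lapply(sel$pre_path, function(p)
    read_pre_table(file.path(out_dir, p)))
  rmap <- region_map(cfg$visible_sequence,
                     mtsl_sites = unlist(cfg$spin_label_sites))
  cmap <- build_contact_map(profiles, rmap)
  readr::write_tsv(cmap$table, file.path(out_dir, "contact_map.tsv"))
  gg <- plot(cmap)
  ggplot2::ggsave(file.path(out_dir, "contact_map.png"), gg,
                  width = 8, height = 3, dpi = 150)
  summ <- region_summary(cmap)
  stage_log("contact-map", "%d strips; topology: %s", length(cmap$strips),
            if (length(summ$topology)) paste(summ$topology, collapse = " + ")
            else "none")
  invisible(cmap)
}

#' Fit residue-specific dissociation constants for a run
#'
#' Assembles the titration set from the run's titration-kind PRE tables,
#' applies the selection rule, fits and classifies every selected
#' residue, and writes the long-format report (`kd_report.tsv`).
#'
#' @param cfg a [run_config()].
#' @param pre_index index returned by [run_compute_pre()].
#' @param out_dir output directory.
#' @return the `binding_fit` tibble, invisibly.
#' @export
run_fit_kd <- function(cfg, pre_index, out_dir) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  sel <- pre_index[pre_index$kind == "titration", ]
  if (!nrow(sel)) abort2("no titration-kind PRE tables", "prekd_io")
  want <- sort(unlist(cfg$ratios))
  missing <- setdiff(want, sel$ratio)
  if (length(missing))
    abort2(paste0("missing titration PRE tables for ratio(s): ",
                  paste(missing, collapse = ", ")), "prekd_io")
  sel <- sel[order(sel$ratio), ]
  profiles <- lapply(sel$pre_path, function(p)
    read_pre_table(file.path(out_dir, p)))
  set <- titration_set(profiles, cfg$visible_concentration,
                       ratios = sel$ratio)
  fits <- fit_titration_set(
    set, threshold = cfg$thresholds$select_threshold,
    point_index = cfg$thresholds$select_point,
    margin = cfg$thresholds$margin)
  readr::write_tsv(tibble::as_tibble(fits), file.path(out_dir, "kd_report.tsv"))
  stage_log("fit-kd", "%d residues: %d specific, %d nonspecific, %d noninteracting",
            nrow(fits), sum(fits$classification == "specific"),
            sum(fits$classification == "nonspecific"),
            sum(fits$classification == "noninteracting"))
  invisible(fits)
}
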