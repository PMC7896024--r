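# Minimal TOML-subset reader: [table] headers and scalar key = value pairs
# (integers, floats, booleans, quoted strings). Sufficient for run
# configuration; arrays and nested tables are deliberately out of scope.
parse_toml_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  tab <- NULL
  for (ln in seq_along(lines)) {
    s <- sub("#.*$", "", lines[ln])
    s <- trimws(s)
    if (s == "") next
    if (grepl("^\\[[A-Za-z0-9_.]+\\]$", s)) {
      tab <- gsub("\\[|\\]", "", s)
      if (is.null(out[[tab]])) out[[tab]] <- list()
      next
    }
    m <- regmatches(s, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", s))[[1]]
    if (length(m) != 3)
      stop(sprintf("config parse error at line %d: '%s'", ln, lines[ln]))
    key <- m[2]
    raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw)) {
      gsub('^"|"$', "", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else if (grepl("^[+-]?[0-9]+$", raw)) {
      as.integer(raw)
    } else if (grepl("^[+-]?([0-9]*\\.[0-9]+|[0-9]+\\.?)([eE][+-]?[0-9]+)?$", raw)) {
      as.numeric(raw)
    } else {
      stop(sprintf("config parse error at line %d: unsupported value '%s'", ln, raw))
    }
    if (is.null(tab)) out[[key]] <- val else out[[tab]][[key]] <- val
  }
  out
}

config_defaults <- function() {
  list(
    fiber = list(L = 20L, L_NCP = 147L, n_nucleosomes = 12L, circular = FALSE,
                 family_hint = "auto"),
    energy = list(stacking_depth = 18, stacking_distance = 7.0,
                  stacking_width = 0.5, core_radius = 5.5,
                  core_half_height = 2.75, dna_radius = 1.0,
                  stacking = TRUE, excluded_volume = TRUE,
                  stack_min_sep = 2L, adjacent_center_floor = 6.5,
                  bend_stiffness = 0.043, twist_stiffness = 0.06,
                  displacement_stiffness = 50),
    mc = list(temperature = 1, n_steps = 200000L, move_size_angles = 3,
              move_size_disp = 0.03, seed = 1L, record_every = 500L,
              burnin_fraction = 0.2),
    observables = list(lambda_nm = 4.0, fld_min = 250L, fld_max = 400L,
                       contact_cutoff = 11, min_prominence = 0.05,
                       s_mono = 11.1, R_eff = 5.5),
    output = list(dir = ".", formats = "tsv")
  )
}

#' Load a run configuration
#'
#' Reads a TOML configuration with tables `[fiber]`, `[energy]`, `[mc]`,
#' `[observables]` and `[output]` (a restricted TOML subset: scalar
#' `key = value` entries only). Missing keys take package defaults; unknown
#' tables or keys are rejected; the fiber invariant `NRL = L_NCP + L` is
#' enforced when `NRL` is given explicitly.
#'
#' @param path file path; an empty or absent-table file yields all defaults.
#' @return An object of class `run_config`: validated `fiber` spec fields,
#'   an [energy_params()] object, an [mc_params()] object, observable
#'   settings, and output settings, plus `defaults_used` naming every key
#'   that fell back to its default (materialized into provenance sidecars).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- parse_toml_subset(path)
  defs <- config_defaults()
  bad_tab <- setdiff(names(raw), names(defs))
  if (length(bad_tab) > 0)
    stop(sprintf("unknown config table(s): %s", paste(bad_tab, collapse = ", ")))
  defaults_used <- character(0)
  merged <- defs
  for (tab in names(defs)) {
    given <- raw[[tab]] %||% list()
    extra <- setdiff(names(given), c(names(defs[[tab]]),
                                     if (tab == "fiber") "NRL"))
    if (length(extra) > 0)
      stop(sprintf("unknown key(s) in [%s]: %s", tab, paste(extra, collapse = ", ")))
    if (tab == "fiber" && !is.null(given$NRL)) {
      L <- given$L %||% defs$fiber$L
      L_NCP <- given$L_NCP %||% defs$fiber$L_NCP
      if (given$NRL != L + L_NCP)
        stop(sprintf("inconsistent NRL: %d != L + L_NCP = %d", given$NRL, L + L_NCP))
      given$NRL <- NULL
    }
    merged[[tab]] <- modifyList(defs[[tab]], given)
    defaults_used <- c(defaults_used,
                       paste(tab, setdiff(names(defs[[tab]]), names(given)), sep = "."))
  }
  f <- merged$fiber
  spec <- fiber_spec(f$L, f$L_NCP, f$n_nucleosomes, f$circular, f$family_hint)
  e <- merged$energy
  epar <- energy_params(
    step_stiffness = diag(c(e$bend_stiffness, e$bend_stiffness, e$twist_stiffness,
                            rep(e$displacement_stiffness, 3))),
    stacking_depth = e$stacking_depth, stacking_distance = e$stacking_distance,
    stacking_width = e$stacking_width, core_radius = e$core_radius,
    core_half_height = e$core_half_height, dna_radius = e$dna_radius,
    stacking = e$stacking, excluded_volume = e$excluded_volume,
    stack_min_sep = e$stack_min_sep,
    adjacent_center_floor = e$adjacent_center_floor)
  m <- merged$mc
  mpar <- mc_params(m$temperature, m$n_steps, m$move_size_angles,
                    m$move_size_disp, m$seed, m$record_every, m$burnin_fraction)
  structure(list(fiber = spec, energy = epar, mc = mpar,
                 observables = merged$observables, output = merged$output,
                 defaults_used = defaults_used),
            class = "run_config")
}

#' Write a conformation as TSV
#'
#' Tab-delimited, '.' decimal, one row per bp with a unit-annotated header:
#' bp index, origin coordinates (nm), region label (core or linker index),
#' and the nine frame-axis components so topology can be recomputed from
#' the file.
#'
#' @param fiber a `fiber_conformation`.
#' @param path output file.
#' @export
write_conformation_tsv <- function(fiber, path) {
  d <- data.frame(
    bp_index = seq_len(nrow(fiber$origins)) - 1L,
    x_nm = fiber$origins[, 1], y_nm = fiber$origins[, 2], z_nm = fiber$origins[, 3],
    region = ifelse(fiber$is_core, sprintf("core_%d", fiber$region),
                    sprintf("linker_%d", fiber$region)))
  ax <- fiber$axes
  colnames(ax) <- paste0("a", rep(1:3, each = 3), rep(1:3, 3))
  d <- cbind(d, ax)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a conformation TSV
#'
#' @param path file written by [write_conformation_tsv()].
#' @return A list (`framed_chain`) with `origins`, `axes`, `region`,
#'   `is_core`, `n_nucleosomes`.
#' @export
read_conformation_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("bp_index", "x_nm", "y_nm", "z_nm", "region")
  if (!all(need %in% names(d)))
    stop("malformed conformation TSV: missing required columns")
  axcols <- paste0("a", rep(1:3, each = 3), rep(1:3, 3))
  axes <- if (all(axcols %in% names(d))) as.matrix(d[, axcols]) else NULL
  is_core <- grepl("^core_", d$region)
  region <- as.integer(sub("^(core|linker)_", "", d$region))
  structure(list(origins = as.matrix(d[, c("x_nm", "y_nm", "z_nm")]),
                 axes = axes, region = region, is_core = is_core,
                 n_nucleosomes = length(unique(region[is_core]))),
            class = "framed_chain")
}

#' Write a conformation as a pseudo-atom PDB
#'
#' One pseudo-atom (CA) per bp origin, coordinates in Angstrom, a chain per
#' nucleosome-plus-linker unit, and the nucleosome index in the B-factor
#' column.
#'
#' @param fiber a `fiber_conformation`.
#' @param path output file.
#' @export
write_conformation_pdb <- function(fiber, path) {
  n <- nrow(fiber$origins)
  chains <- rep(LETTERS, length.out = max(fiber$region) + 1L)[fiber$region + 1L]
  xyz <- as.numeric(t(fiber$origins * 10))  # nm -> Angstrom
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(n), resid = rep("DNA", n),
                   elety = rep("CA", n), chain = chains,
                   b = fiber$region)
  invisible(path)
}

#' Read a pseudo-atom conformation PDB
#'
#' @param path file written by [write_conformation_pdb()].
#' @return A list (`framed_chain`, without axes) with `origins` (nm),
#'   `region` (from the B-factor column), `n_nucleosomes`.
#' @export
read_conformation_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("malformed PDB: ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) stop("malformed PDB: no atoms")
  origins <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10
  region <- as.integer(round(pdb$atom$b))
  structure(list(origins = origins, axes = NULL, region = region,
                 is_core = rep(NA, nrow(origins)),
                 n_nucleosomes = length(unique(region))),
            class = "framed_chain")
}

#' Write a JSON provenance sidecar
#'
#' Every CLI run records the seed, full parameter set (defaults
#' materialized), package and R versions, and a timestamp, so the run is
#' reproducible from the sidecar alone.
#'
#' @param path output file (".json").
#' @param seed integer seed used.
#' @param params named list of parameters to record.
#' @export
write_provenance <- function(path, seed, params = list()) {
  payload <- list(
    package = "fibertopo",
    version = as.character(utils::packageVersion("fibertopo")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
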