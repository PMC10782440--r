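#' Read and write EVB topologies as JSON
#'
#' The on-disk document has sections `atoms`, `state1`, `state2`, `coupling`
#' (plus optional `restraint` and `posres`), with field names exactly as in
#' [evb_topology()]. Exclusion tables are derived, not stored, so a
#' round trip through disk reproduces the object exactly.
#'
#' @param topo An [evb_topology()].
#' @param path File path.
#' @return `read_topology_json` returns an `evb_topology`.
#' @export
write_topology_json <- function(topo, path) {
  stopifnot(inherits(topo, "evb_topology"))
  strip <- function(s) s[c("bonds", "angles", "torsions", "impropers",
                           "charge", "sigma", "epsilon")]
  doc <- list(atoms = topo$atoms,
              state1 = strip(topo$state1), state2 = strip(topo$state2),
              coupling = unclass(topo$coupling),
              restraint = topo$restraint, posres = topo$posres)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  if (!file.exists(path)) stop_data("topology file not found: %s", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x) if (is.null(x) || !length(x)) NULL else as.data.frame(x)
  state <- function(s) list(bonds = as_df(s$bonds), angles = as_df(s$angles),
                            torsions = as_df(s$torsions),
                            impropers = as_df(s$impropers),
                            charge = s$charge, sigma = s$sigma,
                            epsilon = s$epsilon)
  evb_topology(as.data.frame(js$atoms), state(js$state1), state(js$state2),
               coupling = evb_coupling(js$coupling$delta_alpha,
                                       js$coupling$H12),
               restraint = js$restraint,
               posres = as_df(js$posres))
}

#' Read and write full systems (topology or oracle plus metadata)
#'
#' A 3D `evb_system` document embeds the topology JSON plus coordinates and a
#' label; a 1D `oracle_1d` document stores the diabats, coupling, domain and
#' mass. `read_system_json` detects the kind from the fields.
#'
#' @param system An `evb_system` or `oracle_1d`.
#' @param path File path.
#' @export
write_system_json <- function(system, path) {
  if (inherits(system, "oracle_1d")) {
    code_diabat <- function(d) {
      if (d[1] == 0) list(form = "harmonic", k = d[2], x0 = d[3], offset = d[4])
      else list(form = "morse", D = d[2], a = d[3], x0 = d[4], offset = d[5])
    }
    doc <- list(kind = "oracle_1d", label = system$label, mass = system$mass,
                domain = system$domain, diabat1 = code_diabat(system$d1),
                diabat2 = code_diabat(system$d2),
                coupling = unclass(system$coupling), targets = system$targets)
  } else {
    stopifnot(inherits(system, "evb_system"))
    strip <- function(s) s[c("bonds", "angles", "torsions", "impropers",
                             "charge", "sigma", "epsilon")]
    doc <- list(kind = "evb_system", label = system$label,
                atoms = system$topology$atoms,
                state1 = strip(system$topology$state1),
                state2 = strip(system$topology$state2),
                coupling = unclass(system$topology$coupling),
                restraint = system$topology$restraint,
                posres = system$topology$posres,
                coords = system$coords)
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_system_json
#' @export
read_system_json <- function(path) {
  if (!file.exists(path)) stop_data("system file not found: %s", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(js$diabat1) || identical(js$kind, "oracle_1d")) {
    from_js <- function(d) do.call(diabat_1d, as.list(d))
    sys <- structure(list(d1 = from_js(js$diabat1), d2 = from_js(js$diabat2),
                          coupling = evb_coupling(js$coupling$delta_alpha,
                                                  js$coupling$H12),
                          domain = as.numeric(js$domain), mass = js$mass,
                          label = js$label, targets = js$targets),
                     class = "oracle_1d")
    check_oracle_shape(sys)
    return(sys)
  }
  as_df <- function(x) if (is.null(x) || !length(x)) NULL else as.data.frame(x)
  state <- function(s) list(bonds = as_df(s$bonds), angles = as_df(s$angles),
                            torsions = as_df(s$torsions),
                            impropers = as_df(s$impropers),
                            charge = s$charge, sigma = s$sigma,
                            epsilon = s$epsilon)
  topo <- evb_topology(as.data.frame(js$atoms), state(js$state1),
                       state(js$state2),
                       coupling = evb_coupling(js$coupling$delta_alpha,
                                               js$coupling$H12),
                       restraint = js$restraint, posres = as_df(js$posres))
  structure(list(topology = topo, coords = matrix(unlist(js$coords),
                                                  ncol = 3),
                 label = js$label, spec = NULL), class = "evb_system")
}

#' Write and read per-window energy logs
#'
#' One CSV per (temperature, replicate) with columns step, lambda, T,
#' replicate, eps1, eps2s, Eg, eps_m, bond1..vdw1, bond2..vdw2 (per-term
#' totals of each diabat, when breakdowns were recorded), kinT. Re-reading
#' reconstructs windows suitable for FEP/umbrella re-analysis.
#'
#' @param windows List of `evb_window` objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_energy_logs <- function(windows, dir, prefix = "energy") {
  windows <- as_window_list(windows)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  terms <- c("bond", "angle", "torsion", "improper", "elec", "vdw")
  key <- vapply(windows, function(w)
    sprintf("%s_T%g_rep%d", prefix, w$temperature, w$replicate), character(1))
  paths <- character(0)
  for (k in unique(key)) {
    ws <- windows[key == k]
    tabs <- lapply(ws, function(w) {
      tab <- data.frame(step = w$frames$step, lambda = w$lambda,
                        T = w$temperature, replicate = w$replicate,
                        eps1 = w$frames$eps1, eps2s = w$frames$eps2s,
                        Eg = w$frames$Eg, eps_m = w$frames$eps_m)
      for (s in 1:2) {
        bk <- w[[paste0("breakdown", s)]]
        for (tm in terms) {
          tab[[paste0(tm, s)]] <- if (is.null(bk)) NA_real_ else
            rowSums(bk[, paste(c("rr", "rs", "ss"), tm, sep = "_"),
                       drop = FALSE])
        }
      }
      tab$kinT <- w$frames$kinT
      tab
    })
    path <- file.path(dir, paste0(k, ".csv"))
    utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_energy_logs
#' @param files CSV paths written by `write_energy_logs`.
#' @export
read_energy_logs <- function(files) {
  miss <- files[!file.exists(files)]
  if (length(miss)) stop_data("energy log not found: %s", miss[1])
  out <- list()
  for (f in files) {
    tab <- utils::read.csv(f)
    for (key in split(seq_len(nrow(tab)),
                      interaction(tab$lambda, tab$replicate, drop = TRUE))) {
      sub <- tab[key, ]
      out[[length(out) + 1L]] <- window_obj(
        lambda = sub$lambda[1], temperature = sub$T[1],
        replicate = sub$replicate[1],
        frames = data.frame(step = sub$step, eps1 = sub$eps1,
                            eps2s = sub$eps2s, Eg = sub$Eg,
                            eps_m = sub$eps_m, kinT = sub$kinT))
    }
  }
  out
}

#' Write a free-energy profile as TSV
#'
#' Columns de_center, dg, n_frames, replicate, T.
#'
#' @param profiles An `evb_profile` or list of them.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "evb_profile")) profiles <- list(profiles)
  tabs <- lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    data.frame(de_center = p$de_center, dg = p$dg, n_frames = p$n_frames,
               replicate = attr(p, "replicate") %||% k,
               T = attr(p, "temperature"))
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# JSON report with a provenance block; no timestamps so identical runs are
# byte-identical
write_json_report <- function(x, path, seed = NULL, config = NULL) {
  x$provenance <- list(
    package = "evbthermo",
    version = as.character(utils::packageVersion("evbthermo")),
    seed = seed,
    config = config)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a flat key = value run configuration
#'
#' Minimal TOML-style configuration: one `key = value` per line, `#`
#' comments, quoted strings, booleans `true`/`false`, numbers, and arrays
#' `[a, b, c]`. Section headers are ignored.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_data("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[.*\\]$", v)) {
      parts <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
      return(unlist(lapply(parts, parse_val)))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_data("malformed config line: %s", ln)
    out[[trimws(kv[1])]] <- parse_val(paste(kv[-1], collapse = "="))
  }
  out
}

#' Read coordinates from a minimal PDB file
#'
#' Parses ATOM/HETATM records for coordinates only (interpreted as
#' Angstrom); no connectivity is inferred. Used to seed toy fragment
#' geometries from external structures.
#'
#' @param path PDB file.
#' @return n x 3 coordinate matrix.
#' @export
read_coords_pdb <- function(path) {
  if (!file.exists(path)) stop_data("PDB file not found: %s", path)
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path)
    return(matrix(pdb$xyz, ncol = 3, byrow = TRUE))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(rec)) stop_data("no ATOM records in %s", path)
  t(vapply(rec, function(l)
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))),
    numeric(3), USE.NAMES = FALSE))
}
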