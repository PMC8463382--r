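# Orchestration: plain-text key=value configuration with explicit schema,
# the end-to-end redox-comparison run, scenario simulation, and report
# assembly. The summary only aggregates per-stage outputs; it never
# computes anything itself.

.CONFIG_SCHEMA <- list(
  out_dir = list(default = ".", type = "character"),
  seed = list(default = 1, type = "numeric"),
  stages = list(default = "auto", type = "character"),
  # charges stage
  cube_red = list(default = NA, type = "file"),
  cube_ox = list(default = NA, type = "file"),
  partition_scheme = list(default = "nearest-atom", type = "character",
                          allowed = c("nearest-atom", "spheres")),
  sphere_radius = list(default = NA, type = "numeric", min = 0),
  # geometry / models stage
  structure_pdb = list(default = NA, type = "file"),
  model_level = list(default = 3, type = "numeric", min = 1, max = 3),
  model_radius_A = list(default = 4.0, type = "numeric", min = 0),
  # bonded parameters stage
  fchk = list(default = NA, type = "file"),
  bond_atoms = list(default = NA, type = "character"),
  esp_dat = list(default = NA, type = "file"),
  net_charge = list(default = -3, type = "numeric"),
  resp_a = list(default = 0.0005, type = "numeric", min = 0),
  # coevolution stage
  msa = list(default = NA, type = "file"),
  coevo_score_min = list(default = 0.7, type = "numeric", min = 0, max = 1),
  coevo_top_fraction = list(default = 0.30, type = "numeric",
                            min = 1e-9, max = 1),
  coevo_min_seq_sep = list(default = 5, type = "numeric", min = 0),
  coevo_min_distance_A = list(default = 5.0, type = "numeric", min = 0),
  # clustering stage
  traj_pdb = list(default = NA, type = "file"),
  cluster_cutoff_nm = list(default = 0.11, type = "numeric", min = 1e-9),
  # kinetics stage
  traces_csv = list(default = NA, type = "file")
)

#' Validate a pipeline configuration file
#'
#' Reads a plain-text `key = value` configuration (`#` comments allowed),
#' rejects unknown keys (typo protection) and out-of-range values, fills
#' every default, checks that referenced input files exist, and returns
#' the fully resolved configuration. Every default filled in is echoed as
#' a message so no setting is hidden.
#'
#' @param path Configuration file path, or a named list of settings.
#' @param quiet Suppress the default-echo messages.
#' @return A `run_config` (named list) with attribute `resolved_from`.
#' @export
validate_config <- function(path, quiet = FALSE) {
  if (is.character(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- lengths(kv) != 2
    if (any(bad)) stop("malformed config line(s): ",
                       paste(lines[bad], collapse = "; "))
    cfg <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
    src <- path
  } else {
    cfg <- as.list(path)
    src <- "<list>"
  }
  unknown <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out <- list()
  missing_files <- character(0)
  for (key in names(.CONFIG_SCHEMA)) {
    sch <- .CONFIG_SCHEMA[[key]]
    if (key %in% names(cfg)) {
      v <- cfg[[key]]
      if (sch$type == "numeric") {
        v <- suppressWarnings(as.numeric(v))
        if (is.na(v)) stop("config key '", key, "' must be numeric")
        if (!is.null(sch$min) && v < sch$min) {
          stop(sprintf("config key '%s' = %g below minimum %g",
                       key, v, sch$min))
        }
        if (!is.null(sch$max) && v > sch$max) {
          stop(sprintf("config key '%s' = %g above maximum %g",
                       key, v, sch$max))
        }
      } else {
        v <- as.character(v)
        if (!is.null(sch$allowed) && !(v %in% sch$allowed)) {
          stop(sprintf("config key '%s' must be one of: %s", key,
                       paste(sch$allowed, collapse = ", ")))
        }
        if (sch$type == "file" && !file.exists(v)) {
          missing_files <- c(missing_files, sprintf("%s = %s", key, v))
        }
      }
      out[[key]] <- v
    } else {
      out[[key]] <- sch$default
      if (!quiet && !identical(sch$default, NA)) {
        message(sprintf("config default: %s = %s", key, sch$default))
      }
    }
  }
  if (length(missing_files)) {
    stop("config refers to missing input file(s): ",
         paste(missing_files, collapse = "; "))
  }
  structure(out, resolved_from = src, class = c("run_config", "list"))
}

#' Write a resolved configuration back to disk
#'
#' The emitted file re-validates to an identical configuration
#' (round-trip idempotence).
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v) {
    if (length(v) == 0 || (length(v) == 1 && is.na(v))) NA_character_
    else format(v, scientific = FALSE)
  }, character(1))
  writeLines(sprintf("%s = %s", keys[!is.na(vals)], vals[!is.na(vals)]),
             path)
  invisible(path)
}

stage_try <- function(status, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr, error = NULL),
                  error = function(e) list(ok = FALSE, value = NULL,
                                           error = conditionMessage(e)))
  status[[name]] <- res
  status
}

#' Run the configured analysis stages
#'
#' Executes every stage whose inputs are configured (or the explicit
#' `stages` list), in dependency order: structure geometry, difference
#' charges, bonded parameters, coevolution screen, conformational
#' clustering, lability kinetics. Each stage writes its table under
#' `out_dir`; a failing stage is recorded and skipped without stopping
#' independent stages. A `summary.txt` aggregating every stage output and
#' every threshold closes the run.
#'
#' @param config A `run_config` from [validate_config()].
#' @return A `pipeline_report`: list with `status` (per-stage ok/error),
#'   `outputs` (file paths) and `n_failed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  want <- if (identical(config$stages, "auto")) NULL
          else strsplit(config$stages, ",")[[1]]
  enabled <- function(stage, inputs) {
    if (!is.null(want)) return(stage %in% want)
    all(!vapply(config[inputs], function(v) length(v) == 1 && is.na(v),
                logical(1)))
  }
  status <- list()
  outputs <- character(0)
  opath <- function(f) file.path(config$out_dir, f)

  if (enabled("geometry", "structure_pdb")) {
    status <- stage_try(status, "geometry", {
      sites <- detect_cluster_sites(config$structure_pdb)
      if (length(sites) == 0) stop("no [2Fe-2S] site detected")
      geo <- bond_geometry(sites[[1]])
      utils::write.csv(as.data.frame(geo), opath("geometry.csv"),
                       row.names = FALSE)
      model <- build_model(sites[[1]], config$structure_pdb,
                           level = config$model_level,
                           radius = config$model_radius_A)
      write_model_pdb(model, opath(sprintf("model%d.pdb",
                                           as.integer(config$model_level))))
      outputs <- c(outputs, opath("geometry.csv"))
      list(n_sites = length(sites), class = sites[[1]]$class,
           model_atoms = nrow(model$atoms))
    })
  }
  if (enabled("charges", c("cube_red", "cube_ox"))) {
    status <- stage_try(status, "charges", {
      red <- read_cube(config$cube_red)
      ox <- read_cube(config$cube_ox)
      delta <- subtract_density(red, ox)
      ct <- if (config$partition_scheme == "spheres") {
        partition_charges(delta, "spheres",
                          selection = seq_len(nrow(delta$atoms)),
                          radius = config$sphere_radius)
      } else partition_charges(delta, "nearest-atom")
      df <- as.data.frame(ct)
      utils::write.csv(df, opath("dq.csv"), row.names = FALSE)
      outputs <- c(outputs, opath("dq.csv"))
      list(total_e = attr(ct, "total"), scheme = attr(ct, "scheme"))
    })
  }
  if (enabled("params", c("fchk", "bond_atoms"))) {
    status <- stage_try(status, "params", {
      hess <- hessian_from_fchk(config$fchk)
      pairs <- strsplit(strsplit(config$bond_atoms, ";")[[1]], ",")
      rows <- lapply(pairs, function(p) {
        bp <- seminario_bond_constant(hess, as.integer(p[1]),
                                      as.integer(p[2]))
        data.frame(i = bp$atoms[1], j = bp$atoms[2],
                   R_min_nm = bp$R_min_nm, K_r = bp$K_r,
                   k_ij = bp$k_ij, k_ji = bp$k_ji,
                   convention = bp$convention)
      })
      df <- do.call(rbind, rows)
      utils::write.csv(df, opath("bond_params.csv"), row.names = FALSE)
      outputs <- c(outputs, opath("bond_params.csv"))
      df
    })
  }
  if (enabled("coevolution", c("msa", "structure_pdb"))) {
    status <- stage_try(status, "coevolution", {
      aln <- read_alignment(config$msa)
      w <- sequence_weights(aln)
      m <- normalize_matrix(chi2_matrix(aln, w))
      rep <- strong_pairs(m, config$structure_pdb,
                          score_min = config$coevo_score_min,
                          top_fraction = config$coevo_top_fraction,
                          min_seq_sep = config$coevo_min_seq_sep,
                          min_distance = config$coevo_min_distance_A)
      utils::write.table(as.data.frame(rep), opath("strong_pairs.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, opath("strong_pairs.tsv"))
      list(n_pairs = nrow(rep))
    })
  }
  if (enabled("clustering", "traj_pdb")) {
    status <- stage_try(status, "clustering", {
      set <- read_conformers(config$traj_pdb, select = "calpha")
      res <- gromos_cluster(pairwise_rmsd(set),
                            cutoff = config$cluster_cutoff_nm)
      reps <- representatives(res, set)
      assign <- integer(dim(set$xyz)[1])
      for (ci in seq_along(res$clusters)) assign[res$clusters[[ci]]] <- ci
      utils::write.table(
        data.frame(frame = seq_along(assign), cluster = assign,
                   is_representative =
                     seq_along(assign) %in% res$representatives),
        opath("clusters.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, opath("clusters.tsv"))
      list(n_clusters = length(res$clusters),
           occupancy = reps$occupancy)
    })
  }
  if (enabled("kinetics", "traces_csv")) {
    status <- stage_try(status, "kinetics", {
      traces <- read_decay_traces(config$traces_csv)
      panel <- temperature_panel(traces)
      utils::write.table(as.data.frame(panel), opath("lability.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, opath("lability.tsv"))
      list(n_traces = length(traces),
           monotone_k = attr(panel, "monotone_k"))
    })
  }

  lines <- c("neetkit pipeline summary", strrep("=", 24), "",
             "resolved configuration:",
             sprintf("  %s = %s", names(config),
                     vapply(config, function(v) paste(format(v),
                                                      collapse = ","),
                            character(1))),
             "", "stage results:")
  for (nm in names(status)) {
    s <- status[[nm]]
    lines <- c(lines, if (s$ok) {
      sprintf("  %-12s OK  -> %s", nm,
              paste(names(unlist(s$value)), unlist(s$value),
                    sep = "=", collapse = ", "))
    } else sprintf("  %-12s FAILED: %s", nm, s$error))
  }
  lines <- c(lines, "", sprintf("output files: %s",
                                paste(basename(outputs), collapse = ", ")))
  writeLines(lines, opath("summary.txt"))

  structure(list(status = status, outputs = outputs,
                 n_failed = sum(!vapply(status, `[[`, TRUE, "ok")),
                 summary = opath("summary.txt")),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d stage(s), %d failed\n",
              length(x$status), x$n_failed))
  invisible(x)
}

#' Simulate a full synthetic input bundle
#'
#' Writes every input class the pipeline consumes into `dir` — cube pair,
#' synthetic structure PDB, harmonic-model fchk, planted-covariation MSA,
#' conformer trajectory, decay-trace CSV — each with a JSON ground-truth
#' sidecar, and a ready-to-run pipeline configuration.
#'
#' @param dir Output directory.
#' @param seed Integer seed driving every generator.
#' @return Path of the written configuration file, invisibly; the bundle
#'   file list is attached as attribute `files`.
#' @export
simulate_scenario <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  truth_out <- function(truth, f) {
    jsonlite::write_json(truth, p(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  rp <- gen_redox_pair()
  write_cube(rp$ox, p("ox.cube"))
  write_cube(rp$red, p("red.cube"))
  truth_out(rp$truth, "cubes.truth.json")

  mock <- gen_mock_neet_structure(seed)
  writeLines(mock$text, p("structure.pdb"))
  truth_out(mock$truth, "structure.truth.json")

  coords <- matrix(c(0, 0, 0, 2.3, 0, 0, 3.4, 1.9, 0), 3, 3, byrow = TRUE)
  bonds <- data.frame(i = c(1, 2), j = c(2, 3),
                      k = c(25000, 18000),
                      r0 = c(2.3, 2.2) * .BOHR_A / 10)
  hess <- gen_harmonic_hessian(coords, c("Fe", "S", "C"), bonds)
  write_fchk(hess, p("model.fchk"))
  truth_out(list(bonds = bonds), "fchk.truth.json")

  # 14 columns = the 14 protein residues of the synthetic structure, so
  # alignment columns map one-to-one onto residues; the planted pair links
  # a cluster-region column to the distal loop
  msa <- gen_msa(120, 14,
                 planted_pairs = data.frame(i = 2, j = 10, coupling = 1),
                 seed = seed)
  con <- file(p("aln.fasta"), "w")
  for (s in seq_along(msa$aln$id)) {
    writeLines(c(paste0(">", msa$aln$id[s]),
                 paste(msa$aln$ali[s, ], collapse = "")), con)
  }
  close(con)
  truth_out(msa$truth["planted_pairs"], "msa.truth.json")

  base <- matrix(0, 30, 3)                    # zigzag 30-atom chain, nm
  base[, 1] <- seq(0, 2.9, length.out = 30)
  base[, 2] <- rep(c(0, 0.15), 15)
  basins <- list(list(shift = c(0, 0, 0), spread = 0.01),
                 list(shift = c(0, 1.2, 0), spread = 0.01),
                 list(shift = c(0, -0.6, 1.2), spread = 0.01))
  gc <- gen_conformers(base, basins, frames_per_basin = 4, seed = seed)
  write_conformers(gc$set, p("traj.pdb"))
  truth_out(list(basin = gc$truth), "traj.truth.json")

  panel <- data.frame(temperature_K = c(310, 313, 315, 318),
                      k = 0.002 * exp(0.25 * (c(310, 313, 315, 318) - 310)),
                      plateau = 0.1, label = "WT-oxidized")
  gd <- gen_decay_traces(panel, seed = seed)
  df <- do.call(rbind, lapply(gd$traces, function(tr) {
    data.frame(time_min = tr$time_min, A458 = tr$a458,
               temperature_K = tr$temperature_K, label = tr$label)
  }))
  utils::write.csv(df, p("traces.csv"), row.names = FALSE)
  truth_out(gd$truth, "traces.truth.json")

  cfg_path <- p("config.txt")
  writeLines(c(
    sprintf("out_dir = %s", p("out")),
    sprintf("seed = %d", seed),
    sprintf("cube_red = %s", p("red.cube")),
    sprintf("cube_ox = %s", p("ox.cube")),
    sprintf("structure_pdb = %s", p("structure.pdb")),
    sprintf("fchk = %s", p("model.fchk")),
    "bond_atoms = 1,2;2,3",
    sprintf("msa = %s", p("aln.fasta")),
    sprintf("traj_pdb = %s", p("traj.pdb")),
    sprintf("traces_csv = %s", p("traces.csv"))), cfg_path)
  invisible(structure(cfg_path, files = list.files(dir)))
}
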