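#' Read a protein structure from a PDB file
#'
#' Minimal fixed-column PDB reader for ATOM/HETATM records: 1-based residue
#' numbering preserved, coordinates in Angstrom, alternate location 'A' (or
#' blank) kept, waters dropped by default. Elements are taken from columns
#' 77-78 when present, otherwise derived from the atom name.
#'
#' @param path PDB file path.
#' @param keep_waters keep HOH/WAT residues (default FALSE).
#' @return data.frame of class `tl_structure` with columns `serial`,
#'   `name`, `resname`, `chain`, `resid`, `x`, `y`, `z`, `element`.
#' @export
read_pdb <- function(path, keep_waters = FALSE) {
  tl_assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  tl_assert(length(sel) > 0, "no ATOM/HETATM records in %s", path)
  f <- function(ln, a, b) substr(ln, a, b)
  rows <- vector("list", length(sel))
  for (kk in seq_along(sel)) {
    ii <- sel[kk]; ln <- lines[ii]
    if (nchar(ln) < 54)
      tl_stop("malformed ATOM/HETATM record at line %d (too short)", ii)
    altloc <- f(ln, 17, 17)
    if (!altloc %in% c(" ", "", "A")) { rows[[kk]] <- NULL; next }
    xyz <- suppressWarnings(as.numeric(c(f(ln, 31, 38), f(ln, 39, 46),
                                         f(ln, 47, 54))))
    resid <- suppressWarnings(as.integer(f(ln, 23, 26)))
    serial <- suppressWarnings(as.integer(f(ln, 7, 11)))
    if (any(!is.finite(xyz)) || is.na(resid))
      tl_stop("malformed ATOM/HETATM record at line %d", ii)
    name <- trimws(f(ln, 13, 16))
    elem <- trimws(f(ln, 77, 78))
    if (!nchar(elem)) {
      elem <- gsub("[^A-Za-z].*$", "", name)
      elem <- if (substr(elem, 1, 1) %in% c("H", "D")) "H"
              else substr(elem, 1, 1)
    }
    rows[[kk]] <- data.frame(serial = serial, name = name,
                             resname = trimws(f(ln, 18, 20)),
                             chain = f(ln, 22, 22), resid = resid,
                             x = xyz[1], y = xyz[2], z = xyz[3],
                             element = toupper(elem))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!keep_waters && !is.null(out))
    out <- out[!out$resname %in% c("HOH", "WAT"), , drop = FALSE]
  tl_assert(!is.null(out) && nrow(out) > 0,
            "structure is empty after filtering (only waters/altlocs?)")
  rownames(out) <- NULL
  class(out) <- c("tl_structure", "data.frame")
  out
}

#' Serialize a constraint network to CSV
#'
#' Writes one row per bar group (`i`, `j`, `type`, `mult`, `e_hb`) plus a
#' commented header carrying the body count.
#'
#' @param network a [constraint_network()].
#' @param path output path.
#' @export
write_network_csv <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# constraint_network n_bodies=%d", network$n_bodies), con)
  write.csv(network$bars, con, row.names = FALSE)
}

#' Read a constraint network written by [write_network_csv()]
#' @param path input path.
#' @return A [constraint_network()].
#' @export
read_network_csv <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("n_bodies=(\\d+)", first))[[1]]
  tl_assert(length(m) == 2, "missing n_bodies header in %s", path)
  bars <- read.csv(path, comment.char = "#")
  constraint_network(as.integer(m[2]), bars)
}

#' Pipeline configuration
#'
#' Gathers the constants used across stages: the dilution schedule
#' (-0.1 to -6.0 kcal/mol, step 0.1), the assay constants of the
#' specific-activity formula (extinction coefficient 4147 /M/cm for
#' 4-nitrophenol at 348 nm, 0.4 cm path, 0.0002 L reaction volume), the
#' variability bin edges (28 and 31 degC), the no-growth OD threshold
#' (0.15) and the Td cutoff of the transition-selection rule (50 degC).
#'
#' @param seed integer seed propagated to the generators.
#' @param ... overrides for any field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 0, ...) {
  cfg <- list(seed = as.integer(seed),
              schedule = c(start = -0.1, stop = -6.0, step = 0.1),
              epsilon = 4147, path_length = 0.4, volume = 0.0002,
              protein_mass = 0.001,
              bins = c(28, 31), od_threshold = 0.15, td_rule = 50,
              n_sites = 14, toy_bodies = 24)
  cfg <- modifyList(cfg, list(...))
  tl_assert(cfg$schedule[["start"]] > cfg$schedule[["stop"]],
            "dilution schedule must be decreasing")
  tl_assert(cfg$epsilon > 0 && cfg$od_threshold > 0 && cfg$td_rule > 0,
            "thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

schedule_vector <- function(cfg) {
  round(seq(cfg$schedule[["start"]], cfg$schedule[["stop"]],
            by = -abs(cfg$schedule[["step"]])), 10)
}

#' Run the full synthetic pipeline
#'
#' Simulates a site dataset, then runs every stage: kinetics plates to
#' Topt, melting curves to Td, planted toy networks through dilution to
#' Tp, and the statistical layer (Topt/Td/Tp against MAT, with an AIC
#' ladder over MAT/pH/salinity). Deterministic given the seed; the report
#' carries the seed and a configuration hash.
#'
#' @param config a [pipeline_config()].
#' @param out optional output directory for tidy CSVs.
#' @param quick smaller assay traces (for tests; default FALSE uses the
#'   full 180-min/30-s design).
#' @return A `pipeline_report`: list with `sites` (per-site true and
#'   recovered phenotypes), `regressions`, `ladder`, `seed`,
#'   `config_hash`, `timing`.
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL,
                         quick = FALSE) {
  t0 <- Sys.time()
  gcfg <- gen_config(seed = config$seed, n_sites = config$n_sites)
  if (quick) { gcfg$assay_duration_min <- 30; gcfg$assay_dt_min <- 1 }
  sites <- gen_site_dataset(gcfg)
  sched <- schedule_vector(config)
  res <- lapply(seq_len(nrow(sites)), function(k) {
    site <- sites[k, ]
    plate <- gen_assay_plate(site, cfg = gcfg)
    rates <- plate_rates(plate, epsilon = config$epsilon,
                         path_length = config$path_length,
                         volume = config$volume,
                         protein_mass = config$protein_mass)
    prof <- build_profile(rates)
    topt <- find_topt(prof)
    mc <- gen_melting_curve(site$td_true, gcfg)
    sfit <- fit_sigmoid5(mc)
    # planted transition: nearest schedule step to a Tp proportional to Td
    tp_true_K <- 330 + 2 * round((site$td_true + 273.15 + 40 - 330) / 2)
    tp_true_K <- min(max(tp_true_K, 304), 418)
    ecut <- round((300 - tp_true_K) / 20, 1)
    net <- gen_toy_network(config$toy_bodies, ecut, gcfg)
    traj <- dilute(net, sched)
    tp <- compute_tp(traj, td = if (sfit$converged) sfit$td else NULL)
    data.frame(site_id = site$site_id, MAT = site$MAT,
               pH = site$pH, salinity = site$salinity,
               topt_true = site$topt_true, topt_hat = topt$topt,
               td_true = site$td_true,
               td_hat = if (sfit$converged) sfit$td else NA_real_,
               tp_true_K = tp_true_K, tp_hat_K = tp$tp_K,
               tp_rule = tp$rule_applied)
  })
  tab <- do.call(rbind, res)
  regs <- list(topt = ols_regress(tab$MAT, tab$topt_hat),
               td = ols_regress(tab$MAT, tab$td_hat),
               tp = ols_regress(tab$MAT, tab$tp_hat_K))
  ladder <- compare_models(data.frame(topt = tab$topt_hat, MAT = tab$MAT,
                                      pH = tab$pH, salinity = tab$salinity),
                           "topt")
  report <- structure(list(sites = tab, regressions = regs, ladder = ladder,
                           seed = config$seed,
                           config_hash = config_hash(unclass(config)),
                           timing = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs"))),
                      class = "pipeline_report")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    .write_stamped(tab, file.path(out, "sites.csv"), report$config_hash)
    .write_stamped(ladder, file.path(out, "ladder.csv"), report$config_hash)
    jsonlite::write_json(
      list(seed = report$seed, config_hash = report$config_hash,
           regressions = lapply(regs, function(r)
             list(slope = r$slope, r2 = r$r2, p = r$p, aic = r$aic))),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

.write_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thermolegacy config_hash=%s", hash), con)
  write.csv(df, con, row.names = FALSE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (seed %d, hash %s, %.1f s)\n",
              x$seed, x$config_hash, x$timing))
  cat(sprintf("  %d sites | Topt~MAT slope %.3f (R2 %.2f) | Td~MAT slope %.3f | Tp~MAT slope %.3f\n",
              nrow(x$sites), x$regressions$topt$slope, x$regressions$topt$r2,
              x$regressions$td$slope, x$regressions$tp$slope))
  invisible(x)
}
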