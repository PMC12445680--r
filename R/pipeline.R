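#' Assemble a pipeline run configuration
#'
#' A single document (JSON on disk) driving an end-to-end run:
#' fixture generation, PB energetics, Monte Carlo titration, Em profile with
#' decomposition, field map, and hole-hopping kinetics.  Every stochastic
#' stage must carry an explicit seed; validation happens before any compute.
#'
#' @param fixture list(kind = one of "born_ion", "layered_protein",
#'   "site_cluster", "coupled_redox_proton", plus generator arguments)
#' @param conditions list(pH, T, ionic_strength)
#' @param pb list(levels, eps_in, eps_out, stern)
#' @param seeds list: \code{fixture} and, when the titrate stage runs,
#'   \code{mc}
#' @param stages character vector of stages to execute, in dependency order
#' @param titrate list(sweeps, burn) MC protocol
#' @param field list(edge, n) field-box geometry (NULL skips the stage)
#' @param chain list(ids, Em_mV, R_edge, lambda_range) (NULL skips hops)
#' @return object of class \code{run_config}
#' @export
run_config <- function(fixture = list(kind = "born_ion", q = 1, a = 2),
                       conditions = list(pH = 7, T = 300,
                                         ionic_strength = 0.1),
                       pb = list(levels = c(2.5, 1.0, 0.3), eps_in = 4,
                                 eps_out = 80, stern = 2),
                       seeds = list(fixture = 1, mc = 1),
                       stages = c("synth", "energetics", "titrate", "em",
                                  "field", "hops"),
                       titrate = list(sweeps = 2e4, burn = 1e3),
                       field = NULL, chain = NULL) {
  cfg <- structure(list(fixture = fixture, conditions = conditions, pb = pb,
                        seeds = seeds, stages = stages, titrate = titrate,
                        field = field, chain = chain),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$fixture$kind)) stop("config: fixture$kind missing")
  if (is.null(cfg$seeds$fixture)) stop("config: fixture seed missing")
  if ("titrate" %in% cfg$stages && is.null(cfg$seeds$mc))
    stop("config: MC titration stage requires seeds$mc")
  invisible(cfg)
}

#' Write / read a run configuration (lossless JSON round-trip)
#' @param cfg a \code{run_config}
#' @param path file path
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Execute a pipeline run
#'
#' Runs the configured stages in dependency order, writing per-stage CSV
#' outputs and a plain-text key-value manifest (seeds, parameters, wall
#' times, stage status) under \code{out_dir}.  With \code{resume = TRUE},
#' stages whose outputs already exist are skipped, so a partial failure can
#' be resumed.
#'
#' @param cfg a \code{run_config}
#' @param out_dir output directory (created)
#' @param resume skip stages with existing outputs
#' @return invisibly, a list of stage results; the manifest is at
#'   \code{file.path(out_dir, "manifest.txt")}
#' @export
run_pipeline <- function(cfg, out_dir, resume = FALSE) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "manifest.txt")
  if (!resume || !file.exists(manifest)) {
    writeLines(c(sprintf("package_version = %s",
                         as.character(utils::packageVersion("redoxpb"))),
                 sprintf("fixture = %s", cfg$fixture$kind),
                 sprintf("seed_fixture = %s", cfg$seeds$fixture),
                 sprintf("seed_mc = %s", cfg$seeds$mc %||% "NA"),
                 sprintf("pH = %s, T = %s, I = %s", cfg$conditions$pH,
                         cfg$conditions$T, cfg$conditions$ionic_strength),
                 sprintf("levels = %s", paste(cfg$pb$levels, collapse = " "))),
               manifest)
  }
  note <- function(...) cat(sprintf(...), "\n", sep = "", file = manifest,
                            append = TRUE)
  res <- list()
  cond <- titration_conditions(pH = cfg$conditions$pH, T = cfg$conditions$T,
                               ionic_strength = cfg$conditions$ionic_strength)
  pbo <- list(levels = cfg$pb$levels, eps_in = cfg$pb$eps_in,
              eps_out = cfg$pb$eps_out, stern = cfg$pb$stern,
              ionic_strength = cfg$conditions$ionic_strength,
              T = cfg$conditions$T)
  stage <- function(name, outputs, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    paths <- file.path(out_dir, outputs)
    if (resume && all(file.exists(paths))) {
      note("stage %s = skipped (resume)", name)
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) { note("stage %s = FAILED (%s)", name,
                                              conditionMessage(e)); e })
    if (!isTRUE(ok)) stop("pipeline stage '", name, "' failed: ",
                          conditionMessage(ok))
    note("stage %s = ok (%.1f s)", name, proc.time()[3] - t0)
  }

  fx <- NULL
  stage("synth", "structure.pqr", function() {
    fx <<- make_fixture(cfg$fixture, cfg$seeds$fixture)
    write_pqr(fx$structure, file.path(out_dir, "structure.pqr"))
  })
  if (is.null(fx)) fx <- make_fixture(cfg$fixture, cfg$seeds$fixture)

  en <- NULL
  stage("energetics", "energetics.csv", function() {
    if (cfg$fixture$kind == "born_ion") {
      a <- fx$structure$atoms
      rf <- reaction_field_at(fx$structure,
                              list(x = a$x, y = a$y, z = a$z, q = a$charge),
                              center = c(a$x, a$y, a$z), radius = a$radius + 4,
                              eval_points = c(a$x, a$y, a$z),
                              levels = cfg$pb$levels, eps_in = 1,
                              eps_out = cfg$pb$eps_out, ionic_strength = 0)
      df <- data.frame(quantity = c("reaction_field_kcal", "born_analytic_kcal"),
                       value = c(0.5 * a$charge * rf,
                                 born_energy(a$charge, a$radius, 1,
                                             cfg$pb$eps_out)))
    } else if (!is.null(fx$energetics)) {
      en <<- fx$energetics
      df <- energetics_table(en)
    } else {
      en <<- do.call(intrinsic_values,
                     c(list(fx$structure, fx$sites), pbo))
      df <- energetics_table(en)
    }
    write.csv(df, file.path(out_dir, "energetics.csv"), row.names = FALSE)
  })
  get_en <- function() {
    if (is.null(en)) {
      en <<- if (!is.null(fx$energetics)) fx$energetics
             else do.call(intrinsic_values, c(list(fx$structure, fx$sites), pbo))
    }
    en
  }

  stage("titrate", "occupancy.csv", function() {
    if (is.null(fx$sites)) { note("stage titrate = no sites"); return() }
    pop <- mc_titrate(get_en(), cond, sweeps = cfg$titrate$sweeps,
                      burn = cfg$titrate$burn, seed = cfg$seeds$mc)
    ex <- enumerate_exact(get_en(), cond)
    df <- do.call(rbind, lapply(names(pop$occupancy), function(id)
      data.frame(site = id, state = names(pop$occupancy[[id]]),
                 occupancy_mc = unname(pop$occupancy[[id]]),
                 se_mc = unname(pop$se[[id]]),
                 occupancy_exact = unname(ex$occupancy[[id]]))))
    write.csv(df, file.path(out_dir, "occupancy.csv"), row.names = FALSE)
  })

  stage("em", "em_profile.csv", function() {
    if (is.null(fx$sites)) return()
    has_redox <- any(vapply(fx$sites, function(s) s$kind == "redox",
                            logical(1)))
    if (!has_redox) return()
    prof <- em_profile(fx$structure, get_en(), cond)
    write.csv(prof, file.path(out_dir, "em_profile.csv"), row.names = FALSE)
  })

  stage("field", "field_slice.csv", function() {
    fb <- field_box(cfg$field$edge %||% 120, cfg$field$n %||% 76)
    rho <- smear_charges(fx$structure, fb)
    fld <- solve_field(rho, fb, fx$structure,
                       membrane_z = fx$structure$z_interfaces,
                       eps_in = cfg$pb$eps_in, eps_out = cfg$pb$eps_out)
    write.csv(field_slice(fld, "x", 0), file.path(out_dir, "field_slice.csv"),
              row.names = FALSE)
    write_dx(fld$potential, file.path(out_dir, "field.dx"), unit = "mV")
  })

  stage("hops", "hops.csv", function() {
    ch <- cfg$chain
    sw <- lambda_sweep(ch$ids, ch$Em_mV, ch$R_edge,
                       lambda_range = ch$lambda_range %||% c(0.6, 0.8))
    write.csv(sw$sweep, file.path(out_dir, "hops.csv"), row.names = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_fixture <- function(fixture, seed) {
  switch(fixture$kind,
    born_ion = list(structure = make_born_ion(fixture$q %||% 1,
                                              fixture$a %||% 2),
                    sites = NULL),
    layered_protein = make_layered_protein(
      seed = seed,
      slab_charges = fixture$slab_charges %||% c(-4, -3, 0, 0, 0, 0, 3, 4),
      probe_z = fixture$probe_z %||% c(-10, 0, 10)),
    site_cluster = make_site_cluster(fixture$n %||% 8,
                                     fixture$coupling %||% 1, seed = seed),
    coupled_redox_proton = make_coupled_redox_proton(seed = seed),
    stop("unknown fixture kind: ", fixture$kind))
}

energetics_table <- function(en) {
  do.call(rbind, lapply(seq_along(en$sites), function(i) {
    v <- en$intrinsic[[i]]
    data.frame(site = en$site_ids[i], kind = en$sites[[i]]$kind,
               intrinsic = paste(signif(unlist(v), 6), collapse = " / "))
  }))
}
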