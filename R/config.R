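# Configuration files and run orchestration. A run is described by one flat
# YAML file with sections model / conditions / method / mc / output whose
# keys mirror the constructor arguments; unknown keys are rejected before
# any computation.

known_keys <- list(
  model = c("n_sites", "spacing", "bond_length", "bond_angle",
            "rotatable_index", "pK", "sigma", "psi", "omega",
            "u_t", "u_g", "u", "p_sigma", "eps_t", "eps_g", "epsilon"),
  conditions = c("pH", "pH_from", "pH_to", "pH_by", "ionic_strength",
                 "bjerrum_length", "lr_enabled"),
  method = c("name", "correct_sigma", "correct_eps",
             "conditional_distance"),
  mc = c("steps_equilibration", "steps_production", "p_bond_move",
         "n_replicas", "seed", "sampling_stride", "check_every"),
  output = c("results", "log", "xyz")
)

check_section <- function(cfg, section, required = FALSE) {
  sec <- cfg[[section]]
  if (is.null(sec)) {
    if (required) stop(sprintf("configuration section `%s` is required",
                               section), call. = FALSE)
    return(list())
  }
  unknown <- setdiff(names(sec), known_keys[[section]])
  if (length(unknown))
    stop(sprintf("unknown key(s) in section `%s`: %s", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  sec
}

#' Read and validate a run configuration file
#'
#' Parses the YAML run description (sections `model`, `conditions`,
#' `method`, `mc`, `output`) into a validated `run_config` object, building
#' the [chain_spec()], [energy_params()], pH/ionic-strength grids and
#' [mc_config()] it describes. Unknown keys anywhere are an error. The pH
#' grid is given either as an explicit `pH` list or as `pH_from` /
#' `pH_to` / `pH_by`.
#'
#' @param path path to a YAML configuration file (or a pre-parsed list).
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), names(known_keys))
  if (length(unknown))
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  model <- check_section(cfg, "model", required = TRUE)
  conds <- check_section(cfg, "conditions", required = TRUE)
  method <- check_section(cfg, "method", required = TRUE)
  mc <- check_section(cfg, "mc")
  output <- check_section(cfg, "output")

  chain_args <- model[intersect(names(model),
                                c("n_sites", "spacing", "bond_length",
                                  "bond_angle", "rotatable_index"))]
  chain <- do.call(chain_spec, chain_args)
  par_args <- model[intersect(names(model),
                              setdiff(known_keys$model,
                                      names(chain_args)))]
  params <- do.call(energy_params, par_args)

  if (!is.null(conds$pH)) {
    pH <- as.numeric(unlist(conds$pH))
  } else if (!is.null(conds$pH_from)) {
    pH <- seq(conds$pH_from, conds$pH_to,
              by = if (conds$pH_to >= conds$pH_from) abs(conds$pH_by)
              else -abs(conds$pH_by))
  } else stop("conditions must give `pH` or `pH_from`/`pH_to`/`pH_by`",
              call. = FALSE)
  I <- as.numeric(unlist(conds$ionic_strength))
  if (!length(I)) stop("conditions$ionic_strength is required",
                       call. = FALSE)
  method_name <- match.arg(method$name,
                           c("leip-flexible", "leip-rigid", "mc", "compare"))
  mc_args <- mc[intersect(names(mc), known_keys$mc)]
  structure(list(
    chain = chain, params = params, pH = pH, ionic_strength = I,
    bjerrum_length = if (is.null(conds$bjerrum_length)) 0.7
    else conds$bjerrum_length,
    lr_enabled = if (is.null(conds$lr_enabled)) TRUE
    else isTRUE(conds$lr_enabled),
    method = method_name,
    correct_sigma = if (is.null(method$correct_sigma)) TRUE
    else isTRUE(method$correct_sigma),
    correct_eps = isTRUE(method$correct_eps),
    conditional_distance = isTRUE(method$conditional_distance),
    mc = do.call(mc_config, mc_args),
    output = output
  ), class = "run_config")
}

#' Execute a configured run
#'
#' Runs the method requested by a [read_run_config()] object over its
#' (pH x ionic strength) grid: `leip-flexible` / `leip-rigid` call
#' [titrate()], `mc` calls [mc_titration()], and `compare` runs both and
#' joins them, reporting the largest absolute differences in theta and the
#' gauche probability. Results are written as full-precision CSV plus a
#' plain-text run log (configuration echo, seeds, convergence
#' diagnostics).
#'
#' @param config a `run_config` or a path to a YAML file.
#' @param quiet suppress progress messages.
#' @return The result data frame, invisibly. For `compare`, the joined
#'   table with attributes `max_dtheta` and `max_dp_gauche`.
#' @export
run_leip <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config
  else read_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  ctrl <- leip_control(conditional_distance = cfg$conditional_distance)
  t0 <- Sys.time()
  res <- switch(cfg$method,
    "leip-flexible" = titrate(cfg$chain, cfg$params, cfg$pH,
                              cfg$ionic_strength, mode = "flexible",
                              correct_sigma = cfg$correct_sigma,
                              bjerrum_length = cfg$bjerrum_length,
                              lr_enabled = cfg$lr_enabled, control = ctrl),
    "leip-rigid" = titrate(cfg$chain, cfg$params, cfg$pH,
                           cfg$ionic_strength, mode = "rigid",
                           correct_eps = cfg$correct_eps,
                           bjerrum_length = cfg$bjerrum_length,
                           lr_enabled = cfg$lr_enabled, control = ctrl),
    "mc" = mc_titration(cfg$chain, cfg$params, cfg$pH, cfg$ionic_strength,
                        mc = cfg$mc, bjerrum_length = cfg$bjerrum_length,
                        lr_enabled = cfg$lr_enabled),
    "compare" = {
      le <- titrate(cfg$chain, cfg$params, cfg$pH, cfg$ionic_strength,
                    mode = "flexible", correct_sigma = cfg$correct_sigma,
                    bjerrum_length = cfg$bjerrum_length,
                    lr_enabled = cfg$lr_enabled, control = ctrl)
      mcres <- mc_titration(cfg$chain, cfg$params, cfg$pH,
                            cfg$ionic_strength, mc = cfg$mc,
                            bjerrum_length = cfg$bjerrum_length,
                            lr_enabled = cfg$lr_enabled)
      j <- merge(as.data.frame(le), as.data.frame(mcres),
                 by = c("pH", "ionic_strength"),
                 suffixes = c("_leip", "_mc"))
      j$dtheta <- j$theta_leip - j$theta_mc
      j$dp_gauche <- j$p_gauche_leip - j$p_gauche_mc
      attr(j, "max_dtheta") <- max(abs(j$dtheta))
      attr(j, "max_dp_gauche") <- max(abs(j$dp_gauche))
      say("compare: max |dtheta| = %.5f, max |dp_gauche| = %.5f",
          attr(j, "max_dtheta"), attr(j, "max_dp_gauche"))
      j
    })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(cfg$output$results)) {
    utils::write.csv(as.data.frame(res), cfg$output$results,
                     row.names = FALSE)
    say("results written to %s", cfg$output$results)
  }
  if (!is.null(cfg$output$log)) {
    lg <- file(cfg$output$log, "w")
    writeLines(c(
      sprintf("leip run log - %s", format(Sys.time())),
      sprintf("package version: %s",
              as.character(utils::packageVersion("leip"))),
      sprintf("method: %s", cfg$method),
      sprintf("chain: %d sites, spacing %d, bond %g nm, angle %g deg",
              cfg$chain$n_sites, cfg$chain$spacing,
              cfg$chain$bond_length, cfg$chain$bond_angle),
      sprintf("params: pK=%g sigma=%g psi=%g omega=%g u_t=%g u_g=%g u=%g",
              cfg$params$pK, cfg$params$sigma, cfg$params$psi,
              cfg$params$omega, cfg$params$u_t, cfg$params$u_g,
              cfg$params$u),
      sprintf("pH grid: %s", paste(signif(cfg$pH, 6), collapse = " ")),
      sprintf("ionic strengths: %s",
              paste(cfg$ionic_strength, collapse = " ")),
      sprintf("lB = %g nm, lr_enabled = %s", cfg$bjerrum_length,
              cfg$lr_enabled),
      if (cfg$method %in% c("mc", "compare")) sprintf(
        "mc: eq=%g prod=%g p_bond=%g replicas=%d stride=%d seeds=%s",
        cfg$mc$steps_equilibration, cfg$mc$steps_production,
        cfg$mc$p_bond_move, cfg$mc$n_replicas, cfg$mc$sampling_stride,
        paste(cfg$mc$seed + seq_len(cfg$mc$n_replicas) - 1L,
              collapse = " ")) else NULL,
      if (!is.null(res$converged)) sprintf(
        "solver: %d/%d points converged",
        sum(res$converged), nrow(res)) else NULL,
      sprintf("elapsed: %.2f s", elapsed)), lg)
    close(lg)
  }
  if (!is.null(res$converged) && !all(res$converged)) {
    bad <- as.data.frame(res)[!res$converged, c("pH", "ionic_strength")]
    stop("solver did not converge at: ",
         paste(sprintf("(pH %.3g, I %.3g)", bad$pH, bad$ionic_strength),
               collapse = " "), call. = FALSE)
  }
  invisible(res)
}

#' Oracle-equivalence self test
#'
#' Checks the transfer-matrix engine and the Monte Carlo energy route
#' against brute-force enumeration on small randomized systems; returns
#' `TRUE` when every check passes (tolerance 1e-10 relative; the machinery
#' behind the `selftest` command-line subcommand).
#'
#' @param n_draws randomized parameter draws.
#' @param seed RNG seed.
#' @param quiet suppress the per-check messages.
#' @return `TRUE`/`FALSE`, invisibly.
#' @export
leip_selftest <- function(n_draws = 20L, seed = 1L, quiet = FALSE) {
  set.seed(seed)
  ok <- TRUE
  say <- function(...) if (!quiet) message(sprintf(...))
  for (k in seq_len(n_draws)) {
    n <- sample(2:4, 1L)
    chain <- chain_spec(n, spacing = sample(2:3, 1L))
    params <- energy_params(pK = runif(1, 4, 10),
                            sigma = runif(1, 0, 4),
                            psi = runif(1, 0.2, 2), omega = runif(1, 0.2, 2),
                            u_t = runif(1, 0, 1.5), u_g = runif(1, 0, 1.5))
    pH <- runif(1, 2, 12)
    cond <- solution_conditions(pH, runif(1, 0.001, 1),
                                lr_enabled = FALSE)
    en <- enumerate_sbris(chain, params, cond, include_lr = FALSE)
    lp <- sbris_partition(chain, params, pH)
    ob <- sbris_observables(chain, params, pH)
    rel <- function(a, b) abs(a - b) / pmax(1e-12, abs(b))
    pass <- rel(lp, en$log_partition) < 1e-10 &&
      all(rel(ob$theta, en$theta) < 1e-10) &&
      all(rel(ob$p_gauche, en$p_gauche) < 1e-10)
    st <- roto_microstate(sample(0:1, n, TRUE),
                          sample(1:3, chain$n_rotatable, TRUE), chain)
    condLR <- solution_conditions(pH, cond$ionic_strength)
    e1 <- reduced_free_energy(st, chain, params, condLR)
    e2 <- mc_state_energy(st, chain, params, condLR)
    pass <- pass && (!is.finite(e1) && !is.finite(e2) ||
                       abs(e1 - e2) < 1e-9)
    if (!pass) { ok <- FALSE; say("draw %d FAILED", k) }
  }
  say("selftest: %s (%d randomized draws)",
      if (ok) "PASS" else "FAIL", n_draws)
  invisible(ok)
}
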