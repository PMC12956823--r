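#' Configuration for an end-to-end pipeline run
#'
#' The regression menu mirrors the six confounder structures used for the
#' headline figure: (a) none, (b) phylogenetic, (c) spatial, (d) phylo +
#' spatial, (e) atoll covariate, (f) atoll + phylo + spatial.
#'
#' @param out_dir Output directory (created if needed).
#' @param responses Ordinal responses to model.
#' @param reg_menu Subset of `c("none", "phylo", "spatial", "phylo+spatial",
#'   "atoll", "atoll+phylo+spatial")`.
#' @param rho Spatial decay length used by spatial structures.
#' @param rho_grid Optional grid for the sensitivity table (`NULL` skips).
#' @param signal_traits Traits for bivariate signal fits (empty skips).
#' @param coev_traits Traits for coevolution fits (empty skips).
#' @param coev_models Subset of `c("model0", "model1")`: without / with
#'   spatial control.
#' @param root_prior Root-state prior for coevolution fits.
#' @param n_trees Trees used by tree-sample stages.
#' @param atoll_mode Atoll binarization mode.
#' @param sampler Named list of sampler settings shared by all stages
#'   (`warmup`, `iter`, `chains`, `leapfrog`).
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir,
                       responses = c("political_complexity",
                                     "social_stratification"),
                       reg_menu = c("none", "phylo", "spatial",
                                    "phylo+spatial", "atoll",
                                    "atoll+phylo+spatial"),
                       rho = 0.02, rho_grid = NULL,
                       signal_traits = "political_complexity",
                       coev_traits = "political_complexity",
                       coev_models = "model0",
                       root_prior = "informed",
                       n_trees = 1, atoll_mode = "half_as_atoll",
                       sampler = list(warmup = 200L, iter = 200L,
                                      chains = 1L, leapfrog = 12L),
                       seed = 1) {
  known <- c("none", "phylo", "spatial", "phylo+spatial", "atoll",
             "atoll+phylo+spatial")
  bad <- setdiff(reg_menu, known)
  if (length(bad) > 0L) {
    ct_config_error(paste0("unknown regression menu entr(ies): ",
                           paste(bad, collapse = ", ")))
  }
  bad_m <- setdiff(coev_models, c("model0", "model1"))
  if (length(bad_m) > 0L) {
    ct_config_error(paste0("unknown coevolution model(s): ",
                           paste(bad_m, collapse = ", ")))
  }
  structure(list(out_dir = out_dir, responses = responses,
                 reg_menu = reg_menu, rho = rho, rho_grid = rho_grid,
                 signal_traits = signal_traits, coev_traits = coev_traits,
                 coev_models = coev_models, root_prior = root_prior,
                 n_trees = n_trees, atoll_mode = atoll_mode,
                 sampler = sampler, seed = seed),
            class = "run_config")
}

menu_structures <- function(entry) {
  switch(entry,
    "none" = list(structures = character(0), atoll = FALSE),
    "phylo" = list(structures = "phylogenetic", atoll = FALSE),
    "spatial" = list(structures = "spatial", atoll = FALSE),
    "phylo+spatial" = list(structures = c("phylogenetic", "spatial"),
                           atoll = FALSE),
    "atoll" = list(structures = character(0), atoll = TRUE),
    "atoll+phylo+spatial" = list(structures = c("phylogenetic", "spatial"),
                                 atoll = TRUE))
}

log_line <- function(con, stage, status, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, status = status), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes the configured regression menu, the rho-sensitivity grid, the
#' bivariate signal fits and the coevolution fits, writing one summary CSV
#' per stage plus a machine-readable manifest (with md5 checksums, seeds
#' and package version) and a JSON-lines log. Re-running with the same
#' configuration and seed reproduces the summaries exactly. A stage failure
#' is recorded in the manifest and does not abort later stages.
#'
#' @param data A dataset list as produced by [simulate_dataset()] (elements
#'   `table`, `pruned`), or a list with `table_csv`, `trees_file`,
#'   `map_csv` paths.
#' @param cfg A [run_config].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(data, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(data$table_csv)) {
    table <- read_society_table(data$table_csv)
    trees <- read_trees(data$trees_file)
    map <- read_taxon_map(data$map_csv)
    pruned <- prune_and_match(trees, map)
  } else {
    table <- data$table
    pruned <- data$pruned
  }
  table <- binarize_atolls(table, cfg$atoll_mode)
  logf <- file(file.path(cfg$out_dir, "run_log.jsonl"), open = "wt")
  on.exit(close(logf), add = TRUE)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("coevotrait")),
                   config = unclass(cfg), stages = list(), files = list())
  outputs <- character(0)
  failures <- list()
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      log_line(logf, name, "failed", error = conditionMessage(res),
               seconds = round(dt, 2))
      failures[[name]] <<- conditionMessage(res)
      NULL
    } else {
      log_line(logf, name, "ok", seconds = round(dt, 2))
      res
    }
  }

  phylo_cov <- phylo_correlation(pruned$trees[[1]])
  spat_cov <- spatial_covariance(table, kernel_config(rho = cfg$rho))

  # regression menu
  reg_rows <- list()
  contrast_rows <- list()
  mi <- 0L
  for (resp in cfg$responses) {
    for (entry in cfg$reg_menu) {
      mi <- mi + 1L
      label <- paste0(resp, " [", entry, "]")
      st <- menu_structures(entry)
      fit <- run_stage(paste0("regression:", label), function() {
        spec <- regression_spec(
          response = resp,
          predictors = c("kava", if (st$atoll) "atoll"),
          random_structures = st$structures,
          kernel_cfg = kernel_config(rho = cfg$rho),
          sampler_cfg = cfg$sampler)
        suppressMessages(fit_structured_regression(
          table, spec,
          cov = list(phylogenetic = phylo_cov, spatial = spat_cov),
          seed = cfg$seed + mi))
      })
      if (!is.null(fit)) {
        reg_rows[[label]] <- summary_with_model(fit$summary, label)
        con <- predicted_contrast(fit, "kava")
        contrast_rows[[label]] <- summary_with_model(con$summary, label)
      }
    }
  }
  if (length(reg_rows) > 0) {
    p1 <- file.path(cfg$out_dir, "regression_summary.csv")
    write_summary_csv(do.call(rbind, reg_rows), p1)
    p2 <- file.path(cfg$out_dir, "contrast_summary.csv")
    write_summary_csv(do.call(rbind, contrast_rows), p2)
    outputs <- c(outputs, p1, p2)
  }

  # rho sensitivity
  if (!is.null(cfg$rho_grid)) {
    res <- run_stage("rho_sensitivity", function() {
      spec <- regression_spec(cfg$responses[1], predictors = "kava",
                              random_structures = "spatial",
                              sampler_cfg = cfg$sampler)
      suppressMessages(
        rho_sensitivity(table, spec, cfg$rho_grid, seed = cfg$seed + 100))
    })
    if (!is.null(res)) {
      p <- file.path(cfg$out_dir, "rho_sensitivity.csv")
      write_summary_csv(res$table, p)
      outputs <- c(outputs, p)
    }
  }

  # phylogenetic signal
  sig_rows <- list()
  for (tr in cfg$signal_traits) {
    res <- run_stage(paste0("signal:", tr), function() {
      fit_bivariate_latent(table, tr, pruned, sampler_cfg = cfg$sampler,
                           n_trees = cfg$n_trees, seed = cfg$seed + 200)
    })
    if (!is.null(res)) sig_rows[[tr]] <- summary_with_model(res$summary, tr)
  }
  if (length(sig_rows) > 0) {
    p <- file.path(cfg$out_dir, "signal_summary.csv")
    write_summary_csv(do.call(rbind, sig_rows), p)
    outputs <- c(outputs, p)
  }

  # coevolution
  coev_rows <- list()
  for (tr in cfg$coev_traits) {
    for (model in cfg$coev_models) {
      label <- paste0(tr, ":", model)
      res <- run_stage(paste0("coevolution:", label), function() {
        spec <- coevolution_spec(
          trait = tr, spatial_control = identical(model, "model1"),
          rho = cfg$rho, root_prior = cfg$root_prior)
        fit <- fit_coevolution(table, pruned, spec,
                               sampler_cfg = cfg$sampler,
                               n_trees = cfg$n_trees,
                               seed = cfg$seed + 300)
        d12 <- delta_theta(fit, from = 1, to = 2)
        d21 <- delta_theta(fit, from = 2, to = 1)
        rbind(summary_with_model(d12$summary, label),
              summary_with_model(d21$summary, label),
              summary_with_model(
                fit$summary[fit$summary$parameter %in%
                              c("A12", "A21", "sigma1", "sigma2", "r"), ],
                label))
      })
      if (!is.null(res)) coev_rows[[label]] <- res
    }
  }
  if (length(coev_rows) > 0) {
    p <- file.path(cfg$out_dir, "coevolution_summary.csv")
    write_summary_csv(do.call(rbind, coev_rows), p)
    outputs <- c(outputs, p)
  }

  manifest$failures <- failures
  manifest$files <- lapply(outputs, function(p) {
    list(path = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
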