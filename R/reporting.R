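#' Read or write a model configuration as YAML
#'
#' A configuration file may specify any subset of the fields of
#' [default_config()]; missing fields fall back to the packaged defaults.
#'
#' @param path YAML file path.
#' @return `read_config` returns a `psm_config` list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], upd[[nm]])
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(default_config(), user)
  class(cfg) <- "psm_config"
  cfg
}

#' @rdname read_config
#' @param config A `psm_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the base-case analysis
#'
#' Resolves the configured survival inputs, builds the traces, accrues the
#' economics and returns (optionally writes) a base-results table in the
#' conventional two-strategy layout (cost, LYs, QALYs, incrementals, both
#' ICERs), plus the per-cycle traces.
#'
#' @param config A [default_config()]-shaped list.
#' @param out_dir Optional output directory; when given,
#'   `base_case.csv` and one `trace_<strategy>.csv` per strategy are
#'   written.
#' @param verbose Log resolved parameters to the console.
#' @return List with `result` (a `ce_result`), `table` (data frame),
#'   `traces`, `model`.
#' @examples
#' \donttest{
#' bc <- run_base_case(default_config())
#' bc$table
#' }
#' @export
run_base_case <- function(config = default_config(), out_dir = NULL,
                          verbose = FALSE) {
  model <- build_model(config)
  if (verbose) {
    message(sprintf(
      "base case: %d cycles x %g days, discount %g, WTP %.2f",
      model$plan$n_cycles, model$plan$cycle_length_days,
      model$plan$annual_discount, config$wtp))
  }
  res <- evaluate_model(model)
  st <- res$strategies
  # comparator first, reference second (published-table convention)
  ord <- match(c(config$comparator, config$reference), st$name)
  tab <- data.frame(
    quantity = c("cost_usd", "ly", "qaly", "incr_cost_usd", "incr_ly",
                 "incr_qaly", "icer_per_ly", "icer_per_qaly"),
    value_comparator = c(st$cost[ord[1]], st$ly[ord[1]], st$qaly[ord[1]],
                         NA, NA, NA, NA, NA),
    value_reference = c(st$cost[ord[2]], st$ly[ord[2]], st$qaly[ord[2]],
                        res$inc_cost, res$inc_ly, res$inc_qaly,
                        res$icer_per_ly, res$icer_per_qaly))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "base_case.csv"),
                     row.names = FALSE)
    for (s in model$strategies) {
      write_trace_csv(model$traces[[s]],
                      file.path(out_dir, paste0("trace_", s, ".csv")))
    }
  }
  list(result = res, table = tab, traces = model$traces, model = model)
}

#' Run the full analysis bundle
#'
#' Base case, one-way sensitivity analysis (tornado), probabilistic
#' sensitivity analysis with CEAC and cost-effectiveness-plane exports, and
#' the scenario table, all from one configuration and one seed. A manifest
#' (JSON) lists the artifacts, the seed and package version, making any run
#' re-executable.
#'
#' @param config A [default_config()]-shaped list.
#' @param out_dir Output directory for the CSV artifacts and manifest.
#' @param seed Integer seed for the PSA.
#' @param n_psa PSA iterations (default 1000); `0` disables the PSA (and
#'   its CEAC / CE-plane artifacts).
#' @param wtp_grid WTP grid for the CEAC.
#' @param scenarios Scenario list (default [default_scenarios()]).
#' @return List with `base`, `tornado`, `psa`, `ceac`, `ce_plane`,
#'   `scenario_table`, `manifest` (PSA members `NULL` when disabled).
#' @export
run_full <- function(config = default_config(), out_dir = NULL, seed = 1L,
                     n_psa = 1000, wtp_grid = seq(0, 150000, by = 5000),
                     scenarios = default_scenarios()) {
  model <- build_model(config)
  base <- run_base_case(config)
  specs <- default_param_specs(config)
  tornado <- one_way_dsa(model, specs)
  psa <- NULL; ceac_tab <- NULL; plane <- NULL
  if (n_psa > 0) {
    psa <- run_psa(model, specs, n_iter = n_psa, seed = seed)
    ceac_tab <- ceac(psa, wtp_grid)
    plane <- ce_plane(psa)
  }
  scen <- run_scenarios(config, scenarios, model = model)

  artifacts <- c("base_case.csv", "tornado.csv",
                 if (n_psa > 0) c("psa_draws.csv", "ceac.csv",
                                  "ce_plane.csv"),
                 "scenarios.csv")
  manifest <- list(artifacts = as.list(artifacts), seed = as.integer(seed),
                   n_psa = n_psa,
                   package_version =
                     as.character(utils::packageVersion("psmcea")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(base$table, file.path(out_dir, "base_case.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(tornado),
                     file.path(out_dir, "tornado.csv"), row.names = FALSE)
    if (n_psa > 0) {
      utils::write.csv(as.data.frame(psa),
                       file.path(out_dir, "psa_draws.csv"),
                       row.names = FALSE)
      utils::write.csv(ceac_tab, file.path(out_dir, "ceac.csv"),
                       row.names = FALSE)
      utils::write.csv(plane, file.path(out_dir, "ce_plane.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(scen, file.path(out_dir, "scenarios.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(base = base, tornado = tornado, psa = psa, ceac = ceac_tab,
       ce_plane = plane, scenario_table = scen, manifest = manifest)
}
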