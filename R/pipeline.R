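# End-to-end pipeline: augment -> solve -> evaluate -> report.

#' Write a flux solution (or FVA ranges) as TSV
#'
#' Numeric columns are written at full precision together with a rounded
#' display column; rounding never feeds back into computation.
#'
#' @param x a `flux_solution` or an FVA data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(x, path) {
  if (inherits(x, "flux_solution")) {
    df <- data.frame(reaction = names(x$fluxes),
                     flux = sprintf("%.12g", x$fluxes),
                     flux_display = sprintf("%.6g", x$fluxes))
  } else {
    df <- data.frame(reaction = x$reaction,
                     min = sprintf("%.12g", x$min),
                     max = sprintf("%.12g", x$max))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the configured analysis pipeline
#'
#' Stages (each optional, driven by the config): load or generate the model,
#' apply a cofactor requirement table, growth FBA with parsimonious
#' selection, FVA, essentiality evaluation against a reference list,
#' turnover accounting, and a run log with solver status, tolerances,
#' precision-guard outcome, config hash and package version.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `model` (SBML path) or `fixture_seed`; optional `cofactor_table` (TSV
#'   path), `essentiality_reference` (TSV path), `fva` (logical),
#'   `fraction_of_optimum`, `threshold`, `out_dir` (required).
#' @return the report directory, invisibly; stops on any stage failure.
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  cat("", file = logf)
  ver <- as.character(utils::packageVersion("cofactorflux"))
  logline("cofactorflux version: ", ver)
  if (!is.null(cfg_path))
    logline("config md5: ", unname(tools::md5sum(cfg_path)))

  if (!is.null(config$model)) {
    if (!file.exists(config$model)) stop("model file not found: ", config$model)
    model <- read_sbml(config$model)
    logline("model: ", config$model)
  } else if (!is.null(config$fixture_seed)) {
    fx <- generate_fixture(fixture_config(seed = as.integer(config$fixture_seed)))
    model <- fx$model
    logline("model: generated fixture, seed ", config$fixture_seed)
  } else stop("config must name a model path or a fixture_seed")

  if (!is.null(config$cofactor_table)) {
    tab <- read_cofactor_table(config$cofactor_table)
    model <- augment_model(model, tab)
    logline("augmented with ", nrow(tab), " cofactor requirements")
  }
  guard <- precision_guard(model)
  logline("precision guard: ", guard$message)

  sol <- optimize_growth(model, selection_rule = "min_total_flux")
  logline("FBA status: ", sol$status, "; growth: ",
          sprintf("%.12g", sol$objective_value))
  if (sol$status != "optimal") stop("FBA stage failed: status ", sol$status)
  write_flux_tsv(sol, file.path(config$out_dir, "fluxes.tsv"))
  report <- list(version = ver, growth = sol$objective_value,
                 precision_guard = guard$pass)

  if (isTRUE(config$fva)) {
    fr <- if (is.null(config$fraction_of_optimum)) 1.0
          else config$fraction_of_optimum
    fva <- flux_variability(model, fraction_of_optimum = fr)
    write_flux_tsv(fva, file.path(config$out_dir, "fva.tsv"))
    logline("FVA at fraction ", fr, " written")
  }
  if (!is.null(config$essentiality_reference)) {
    ref <- read_essentiality_reference(config$essentiality_reference)
    ev <- evaluate_essentiality(model, ref,
                                threshold = if (is.null(config$threshold)) 0.01
                                            else config$threshold)
    utils::write.table(ev$calls, file.path(config$out_dir, "essentiality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    met <- confusion_metrics(ev$confusion)
    report$confusion <- unclass(ev$confusion)
    report$metrics <- as.list(met)
    report$metrics_raw <- as.list(attr(met, "raw"))
    logline("essentiality: ", nrow(ev$calls), " genes evaluated")
  }
  if (nrow(model$cofactor_table) > 0) {
    tv <- total_turnover(model, sol)
    report$turnover <- list(total = tv$total, minimum = tv$minimum,
                            maximum = tv$maximum,
                            spent_pool_influx = tv$spent_pool_influx)
    per <- data.frame(requirement = names(tv$per_reaction),
                      contribution = sprintf("%.12g", tv$per_reaction))
    utils::write.table(per, file.path(config$out_dir, "turnover.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logline("turnover total: ", sprintf("%.12g", tv$total))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done")
  invisible(config$out_dir)
}
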