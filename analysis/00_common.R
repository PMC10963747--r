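# Shared plumbing for the numbered analysis drivers: option parsing and the
# results-directory layout. Every driver is a thin narrative over functions
# from the fieldET package; run them in order from the repository root:
#
#   Rscript analysis/01_simulate.R            [--seed 1] [--results results]
#   Rscript analysis/02_train_counterfactual.R ...
#   ...
#   Rscript analysis/06_efficiency.R

suppressPackageStartupMessages({
  library(fieldET)
  library(data.table)
  library(optparse)
})

analysis_options <- function() {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--seed", type = "integer", default = 1L,
                help = "run seed [default %default]"),
    make_option("--results", type = "character", default = "results",
                help = "results directory [default %default]"),
    make_option("--config", type = "character", default = NULL,
                help = "optional YAML config merged over the defaults")
  )))
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else
    default_config(opts$seed)
  cfg$seed <- opts$seed
  dir.create(opts$results, recursive = TRUE, showWarnings = FALSE)
  list(cfg = cfg, results = opts$results)
}

res_path <- function(ctx, ...) {
  p <- file.path(ctx$results, ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

# Deterministic re-simulation: drivers downstream of 01 rebuild the
# landscape from the config rather than parsing rasters back, so every stage
# sees bit-identical inputs. 01 writes the GeoTIFF/GeoJSON/CSV artifacts and
# checks the raster round trip.
simulate_world <- function(cfg) {
  landscape <- generate_landscape(cfg)
  series <- generate_et_series(landscape)
  pm <- pixel_month_table(landscape, series)
  pm <- merge(pm, landscape$fields[, .(field_id, orchard_years_bearing,
                                       last_year_flag)],
              by = "field_id", sort = FALSE)
  list(landscape = landscape, series = series, pm = pm)
}

say <- function(...) cat(sprintf(...), "\n")
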