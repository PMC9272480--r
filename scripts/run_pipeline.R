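#!/usr/bin/env Rscript
# Thin command-line wrapper over varscape::run_pipeline().
#
#   Rscript scripts/run_pipeline.R --config run.yml [--render]
#   Rscript scripts/run_pipeline.R --mode synthetic --outdir out --seed 3 \
#       [--n-variants 5000] [--render]

suppressPackageStartupMessages({
  library(optparse)
  library(varscape)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (see ?read_run_config)"),
  make_option("--mode", type = "character", default = "synthetic"),
  make_option("--vep", type = "character", default = NULL,
              help = "VEP-dialect table (real mode)"),
  make_option("--outdir", type = "character", default = "varscape_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-variants", type = "integer", default = 5000L,
              dest = "n_variants"),
  make_option("--render", action = "store_true", default = FALSE,
              help = "also write figure PNGs")
)))

cfg <- if (!is.null(opts$config)) {
  read_run_config(opts$config)
} else {
  run_config(mode = opts$mode, vep_path = opts$vep, outdir = opts$outdir,
             seed = opts$seed,
             mm = if (opts$mode == "synthetic")
               mutation_model(n_variants = opts$n_variants, seed = opts$seed))
}
bundle <- run_pipeline(cfg)
print(bundle)
if (opts$render) {
  outdir <- if (is.null(cfg$outdir)) opts$outdir else cfg$outdir
  render_figures(bundle, file.path(outdir, "figures"))
}
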