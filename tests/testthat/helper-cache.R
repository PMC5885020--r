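# One default-design pipeline run shared by the acceptance and pipeline
# tests (computed on first use; ~21 genomes of 50 kb, all stages).
.run_cache <- new.env(parent = emptyenv())

get_default_run <- function() {
  if (is.null(.run_cache$report)) {
    outdir <- file.path(tempdir(), "phagani_default_run")
    cfg <- pipeline_config(outdir = outdir, seed = 7)
    t0 <- Sys.time()
    .run_cache$report <- run_pipeline(cfg)
    .run_cache$elapsed_min <-
      as.numeric(difftime(Sys.time(), t0, units = "mins"))
    .run_cache$outdir <- outdir
  }
  .run_cache
}
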