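# One default synthetic experiment, built once per test session and shared by
# the recovery / invariant tests. The configuration is the package default
# (the study-emulating conditions) at seed 1.

.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!exists("fx", envir = .fixture_env)) {
    cfg <- sim_config(seed = 1)
    refs <- sim_references(cfg)
    libs <- sim_libraries(cfg, refs)
    pc <- pipeline_config(
      reads = libs$reads, design = cfg$library_design,
      mitochondria = refs$mitochondria, chloroplast = refs$chloroplast,
      ncrna = refs$ncrna, mature = refs$mature, hairpin = refs$hairpin,
      transcriptome = refs$transcriptome, adapter = cfg$adapter
    )
    res <- suppressMessages(run_pipeline(pc))
    assign("fx", list(cfg = cfg, refs = refs, libs = libs, res = res),
           envir = .fixture_env)
  }
  get("fx", envir = .fixture_env)
}
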