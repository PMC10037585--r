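# Shared fixtures generated once per test run: a smoke-scale cohort for
# pipeline tests (seconds) and its manifest.
microDir <- file.path(tempdir(), "tibiaseg-micro-cohort")
if (!file.exists(file.path(microDir, "manifest.csv"))) {
  generateCohort(microCohortSpec(seed = 11L), microDir)
}
microManifest <- readManifest(file.path(microDir, "manifest.csv"))
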