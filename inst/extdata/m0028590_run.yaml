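# Example run configuration for the bundled pedigree preset.
# Any key omitted here falls back to the package default; unknown keys
# are rejected. See ?RunConfig.
seed: 11
outDir: m0028590_run
simulate:
  preset: m0028590
  f2Size: 200
  nChrom: 12
  chromLength: 2500000.0
detect:
  fold: 10.0
  minAbs: 20.0
bsa:
  windowSnps: 20
  high: 0.9
  controlMax: 0.7
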