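{
  "outDir": "cpkin_run",
  "simulate": {
    "nMothers": 13, "nFathers": 10, "nProgeny": 54,
    "genomeLength": 20000, "nPolymorphicSites": 32,
    "contaminationRate": 0.2, "leakageRate": 0, "deNovoMu": 2e-10,
    "generationYears": 25, "depthMean": 12.3, "readLength": 150,
    "insertSize": 350, "baseErrorRate": 0.001, "fracLowMapq": 0.05,
    "fracLowBaseq": 0.02, "seed": 1
  },
  "minDepth": 3, "minMapq": 20, "minBaseq": 20, "homoplasmy": 0.9,
  "mafMin": 0.05, "minCarriers": 3, "maxMismatch": 0,
  "nPolicy": "AS_REFERENCE", "bootstrapReps": 100, "seed": 1
}
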