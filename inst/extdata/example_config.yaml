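# Example pipeline configuration.
#
# The WQI normalization curves/weights and the HAILS coefficients below are
# NON-AUTHORITATIVE placeholders for testing and synthetic work. For a real
# survey, transcribe the curves, weights, class thresholds and CI
# coefficients from your regional standard or study supplement.

radii: [100, 500, 1000, 2000, 3000, 4000]

opgd:
  methods: [equal, quantile, natural, geometric, sd]
  k_min: 3
  k_max: 7

null_model:
  draws: 1000
  seed: 42

gdm:
  splines: 3

hails_ci:
  cultivated: 0.2
  forest: 0.067
  grass: 0.067
  construction: 1.0
  water: 0.067
  wetland: 0.067
  bare: 0.0

wqi:
  thresholds:
    - {lower: 0,  upper: 25,  label: "Very poor"}
    - {lower: 25, upper: 50,  label: "Poor"}
    - {lower: 50, upper: 70,  label: "Medium"}
    - {lower: 70, upper: 90,  label: "Good"}
    - {lower: 90, upper: 100, label: "Excellent"}
  params:
    - {name: DO,  weight: 4, curve: {value: [2, 12],    score: [0, 100]}}
    - {name: TN,  weight: 3, curve: {value: [0.1, 8],   score: [100, 0]}}
    - {name: TP,  weight: 3, curve: {value: [0.005, 1.2], score: [100, 0]}}
    - {name: NH3N, weight: 3, curve: {value: [0.01, 3], score: [100, 0]}}
    - {name: CODMn, weight: 3, curve: {value: [0.5, 18], score: [100, 0]}}
    - {name: EC,  weight: 2, curve: {value: [100, 2000], score: [100, 0]}}
    - {name: TUR, weight: 2, curve: {value: [0, 120],   score: [100, 0]}}
    - {name: TDS, weight: 2, curve: {value: [50, 1500], score: [100, 0]}}
    - {name: NO2N, weight: 2, curve: {value: [0.001, 0.6], score: [100, 0]}}
    - {name: NO3N, weight: 2, curve: {value: [0.05, 12], score: [100, 0]}}
    - {name: Chla, weight: 2, curve: {value: [0.5, 60], score: [100, 0]}}
    - {name: pH,  weight: 1, curve: {value: [4, 7.25, 10.5], score: [0, 100, 0]}}
    - {name: WT,  weight: 1, curve: {value: [0, 16, 32], score: [0, 100, 0]}}
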