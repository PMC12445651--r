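{
  "model_id": "at_biopsy",
  "variant": "without_race",
  "label": "toy set for tests and examples",
  "terms": [
    {
      "covariate": "proteinuria_g_day",
      "transform": "log",
      "center": 0.336472236621213,
      "coefficient": 0.5
    },
    {
      "covariate": "egfr",
      "transform": "identity",
      "center": 76,
      "coefficient": -0.02
    }
  ],
  "baseline_survival": [
    {
      "time_months": 6,
      "s0": 0.999125692770335
    },
    {
      "time_months": 12,
      "s0": 0.996958787582009
    },
    {
      "time_months": 18,
      "s0": 0.993700577396918
    },
    {
      "time_months": 24,
      "s0": 0.989449795116328
    },
    {
      "time_months": 30,
      "s0": 0.984276001505691
    },
    {
      "time_months": 36,
      "s0": 0.978235102477099
    },
    {
      "time_months": 42,
      "s0": 0.971375409694518
    },
    {
      "time_months": 48,
      "s0": 0.963740590485698
    },
    {
      "time_months": 54,
      "s0": 0.955371291367585
    },
    {
      "time_months": 60,
      "s0": 0.946306102717369
    },
    {
      "time_months": 66,
      "s0": 0.936582160748332
    },
    {
      "time_months": 72,
      "s0": 0.926235534437943
    },
    {
      "time_months": 78,
      "s0": 0.915301477622895
    },
    {
      "time_months": 84,
      "s0": 0.903814592838951
    },
    {
      "time_months": 90,
      "s0": 0.891808935435056
    },
    {
      "time_months": 96,
      "s0": 0.879318076223109
    },
    {
      "time_months": 102,
      "s0": 0.866375134794399
    },
    {
      "time_months": 108,
      "s0": 0.853012791821934
    },
    {
      "time_months": 114,
      "s0": 0.839263286213742
    },
    {
      "time_months": 120,
      "s0": 0.825158401353316
    }
  ]
}
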