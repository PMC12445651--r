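{
  "model_id": "post_biopsy",
  "variant": "without_race",
  "label": "SYNTHETIC stand-in coefficients (not the published tool)",
  "terms": [
    {
      "covariate": "proteinuria_12m",
      "transform": "log",
      "center": 0,
      "coefficient": 0.65
    },
    {
      "covariate": "egfr_12m",
      "transform": "identity",
      "center": 80,
      "coefficient": -0.025
    },
    {
      "covariate": "map_12m",
      "transform": "identity",
      "center": 95,
      "coefficient": 0.008
    },
    {
      "covariate": "age_years",
      "transform": "identity",
      "center": 36.6,
      "coefficient": -0.012
    },
    {
      "covariate": "mest_m",
      "transform": "identity",
      "center": 0.38,
      "coefficient": 0.22
    },
    {
      "covariate": "mest_e",
      "transform": "identity",
      "center": 0.17,
      "coefficient": 0.18
    },
    {
      "covariate": "mest_s",
      "transform": "identity",
      "center": 0.77,
      "coefficient": 0.28
    },
    {
      "covariate": "mest_t",
      "transform": "indicator",
      "level": "1",
      "center": 0.25,
      "coefficient": 0.42
    },
    {
      "covariate": "mest_t",
      "transform": "indicator",
      "level": "2",
      "center": 0.05,
      "coefficient": 0.85
    },
    {
      "covariate": "rasb_use",
      "transform": "identity",
      "center": 0.32,
      "coefficient": 0.15
    },
    {
      "covariate": "is_use",
      "transform": "identity",
      "center": 0.09,
      "coefficient": 0.25
    }
  ],
  "baseline_survival": [
    {
      "time_months": 2,
      "s0": 0.999911781694165
    },
    {
      "time_months": 4,
      "s0": 0.999692839649188
    },
    {
      "time_months": 6,
      "s0": 0.999362826461356
    },
    {
      "time_months": 8,
      "s0": 0.998930813220092
    },
    {
      "time_months": 10,
      "s0": 0.998402735624537
    },
    {
      "time_months": 12,
      "s0": 0.997782986909688
    },
    {
      "time_months": 14,
      "s0": 0.997075050164421
    },
    {
      "time_months": 16,
      "s0": 0.996281813247099
    },
    {
      "time_months": 18,
      "s0": 0.995405747682708
    },
    {
      "time_months": 20,
      "s0": 0.994449019611708
    },
    {
      "time_months": 22,
      "s0": 0.993413563087217
    },
    {
      "time_months": 24,
      "s0": 0.99230113087131
    },
    {
      "time_months": 26,
      "s0": 0.991113330984555
    },
    {
      "time_months": 28,
      "s0": 0.989851653812402
    },
    {
      "time_months": 30,
      "s0": 0.988517492714984
    },
    {
      "time_months": 32,
      "s0": 0.987112160027184
    },
    {
      "time_months": 34,
      "s0": 0.985636899701365
    },
    {
      "time_months": 36,
      "s0": 0.984092897449695
    },
    {
      "time_months": 38,
      "s0": 0.982481288987934
    },
    {
      "time_months": 40,
      "s0": 0.980803166813095
    },
    {
      "time_months": 42,
      "s0": 0.979059585831903
    },
    {
      "time_months": 44,
      "s0": 0.977251568076454
    },
    {
      "time_months": 46,
      "s0": 0.975380106686187
    },
    {
      "time_months": 48,
      "s0": 0.973446169293837
    },
    {
      "time_months": 50,
      "s0": 0.971450700922487
    },
    {
      "time_months": 52,
      "s0": 0.969394626478075
    },
    {
      "time_months": 54,
      "s0": 0.967278852904451
    },
    {
      "time_months": 56,
      "s0": 0.965104271054895
    },
    {
      "time_months": 58,
      "s0": 0.962871757323783
    },
    {
      "time_months": 60,
      "s0": 0.960582175074081
    },
    {
      "time_months": 62,
      "s0": 0.958236375890066
    },
    {
      "time_months": 64,
      "s0": 0.955835200679616
    },
    {
      "time_months": 66,
      "s0": 0.953379480646394
    },
    {
      "time_months": 68,
      "s0": 0.950870038148997
    },
    {
      "time_months": 70,
      "s0": 0.948307687461458
    },
    {
      "time_months": 72,
      "s0": 0.945693235447336
    },
    {
      "time_months": 74,
      "s0": 0.94302748215782
    },
    {
      "time_months": 76,
      "s0": 0.940311221362783
    },
    {
      "time_months": 78,
      "s0": 0.937545241022478
    },
    {
      "time_months": 80,
      "s0": 0.934730323706535
    },
    {
      "time_months": 82,
      "s0": 0.931867246966021
    },
    {
      "time_months": 84,
      "s0": 0.92895678366361
    },
    {
      "time_months": 86,
      "s0": 0.92599970226624
    },
    {
      "time_months": 88,
      "s0": 0.922996767104133
    },
    {
      "time_months": 90,
      "s0": 0.919948738599575
    },
    {
      "time_months": 92,
      "s0": 0.916856373468436
    },
    {
      "time_months": 94,
      "s0": 0.913720424897116
    },
    {
      "time_months": 96,
      "s0": 0.910541642697259
    },
    {
      "time_months": 98,
      "s0": 0.907320773440328
    },
    {
      "time_months": 100,
      "s0": 0.904058560573951
    },
    {
      "time_months": 102,
      "s0": 0.900755744521676
    },
    {
      "time_months": 104,
      "s0": 0.897413062767678
    },
    {
      "time_months": 106,
      "s0": 0.894031249927753
    },
    {
      "time_months": 108,
      "s0": 0.890611037807833
    },
    {
      "time_months": 110,
      "s0": 0.88715315545112
    },
    {
      "time_months": 112,
      "s0": 0.883658329174841
    },
    {
      "time_months": 114,
      "s0": 0.880127282597531
    },
    {
      "time_months": 116,
      "s0": 0.876560736657677
    },
    {
      "time_months": 118,
      "s0": 0.872959409624456
    },
    {
      "time_months": 120,
      "s0": 0.869324017101271
    }
  ]
}
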