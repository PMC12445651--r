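{
  "model_id": "at_biopsy",
  "variant": "with_race",
  "label": "SYNTHETIC stand-in coefficients (not the published tool)",
  "terms": [
    {
      "covariate": "proteinuria_g_day",
      "transform": "log",
      "center": 0.182321556793955,
      "coefficient": 0.6
    },
    {
      "covariate": "egfr",
      "transform": "identity",
      "center": 83,
      "coefficient": -0.022
    },
    {
      "covariate": "map_mmHg",
      "transform": "identity",
      "center": 96.7,
      "coefficient": 0.008
    },
    {
      "covariate": "age_years",
      "transform": "identity",
      "center": 35.6,
      "coefficient": -0.012
    },
    {
      "covariate": "mest_m",
      "transform": "identity",
      "center": 0.38,
      "coefficient": 0.25
    },
    {
      "covariate": "mest_e",
      "transform": "identity",
      "center": 0.17,
      "coefficient": 0.2
    },
    {
      "covariate": "mest_s",
      "transform": "identity",
      "center": 0.77,
      "coefficient": 0.3
    },
    {
      "covariate": "mest_t",
      "transform": "indicator",
      "level": "1",
      "center": 0.25,
      "coefficient": 0.45
    },
    {
      "covariate": "mest_t",
      "transform": "indicator",
      "level": "2",
      "center": 0.05,
      "coefficient": 0.9
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
    },
    {
      "covariate": "race",
      "transform": "indicator",
      "level": "japanese",
      "center": 0.205,
      "coefficient": 0.3
    },
    {
      "covariate": "race",
      "transform": "indicator",
      "level": "other",
      "center": 0.008,
      "coefficient": -0.1
    }
  ],
  "baseline_survival": [
    {
      "time_months": 2,
      "s0": 0.999916149863519
    },
    {
      "time_months": 4,
      "s0": 0.999708047250221
    },
    {
      "time_months": 6,
      "s0": 0.999394368164227
    },
    {
      "time_months": 8,
      "s0": 0.998983729795499
    },
    {
      "time_months": 10,
      "s0": 0.998481768137668
    },
    {
      "time_months": 12,
      "s0": 0.997892652162474
    },
    {
      "time_months": 14,
      "s0": 0.997219684915266
    },
    {
      "time_months": 16,
      "s0": 0.996465602904347
    },
    {
      "time_months": 18,
      "s0": 0.995632746194252
    },
    {
      "time_months": 20,
      "s0": 0.994723163906676
    },
    {
      "time_months": 22,
      "s0": 0.993738683927985
    },
    {
      "time_months": 24,
      "s0": 0.992680961225453
    },
    {
      "time_months": 26,
      "s0": 0.991551512618703
    },
    {
      "time_months": 28,
      "s0": 0.990351742572869
    },
    {
      "time_months": 30,
      "s0": 0.989082962814665
    },
    {
      "time_months": 32,
      "s0": 0.987746407565213
    },
    {
      "time_months": 34,
      "s0": 0.986343245580295
    },
    {
      "time_months": 36,
      "s0": 0.984874589812785
    },
    {
      "time_months": 38,
      "s0": 0.983341505269516
    },
    {
      "time_months": 40,
      "s0": 0.981745015473718
    },
    {
      "time_months": 42,
      "s0": 0.980086107834396
    },
    {
      "time_months": 44,
      "s0": 0.978365738147429
    },
    {
      "time_months": 46,
      "s0": 0.976584834398727
    },
    {
      "time_months": 48,
      "s0": 0.974744300000354
    },
    {
      "time_months": 50,
      "s0": 0.9728450165615
    },
    {
      "time_months": 52,
      "s0": 0.970887846274511
    },
    {
      "time_months": 54,
      "s0": 0.968873633979808
    },
    {
      "time_months": 56,
      "s0": 0.966803208960951
    },
    {
      "time_months": 58,
      "s0": 0.964677386511418
    },
    {
      "time_months": 60,
      "s0": 0.962496969307027
    },
    {
      "time_months": 62,
      "s0": 0.960262748611962
    },
    {
      "time_months": 64,
      "s0": 0.957975505341562
    },
    {
      "time_months": 66,
      "s0": 0.955636011001212
    },
    {
      "time_months": 68,
      "s0": 0.953245028517562
    },
    {
      "time_months": 70,
      "s0": 0.950803312975769
    },
    {
      "time_months": 72,
      "s0": 0.948311612274397
    },
    {
      "time_months": 74,
      "s0": 0.945770667707896
    },
    {
      "time_months": 76,
      "s0": 0.943181214485156
    },
    {
      "time_months": 78,
      "s0": 0.940543982191456
    },
    {
      "time_months": 80,
      "s0": 0.937859695200137
    },
    {
      "time_months": 82,
      "s0": 0.935129073039491
    },
    {
      "time_months": 84,
      "s0": 0.932352830719646
    },
    {
      "time_months": 86,
      "s0": 0.929531679023634
    },
    {
      "time_months": 88,
      "s0": 0.926666324766311
    },
    {
      "time_months": 90,
      "s0": 0.923757471024356
    },
    {
      "time_months": 92,
      "s0": 0.920805817340212
    },
    {
      "time_months": 94,
      "s0": 0.917812059902482
    },
    {
      "time_months": 96,
      "s0": 0.914776891705027
    },
    {
      "time_months": 98,
      "s0": 0.911701002686777
    },
    {
      "time_months": 100,
      "s0": 0.908585079854012
    },
    {
      "time_months": 102,
      "s0": 0.905429807386741
    },
    {
      "time_months": 104,
      "s0": 0.902235866730585
    },
    {
      "time_months": 106,
      "s0": 0.899003936675471
    },
    {
      "time_months": 108,
      "s0": 0.895734693422286
    },
    {
      "time_months": 110,
      "s0": 0.892428810638548
    },
    {
      "time_months": 112,
      "s0": 0.889086959504041
    },
    {
      "time_months": 114,
      "s0": 0.885709808747274
    },
    {
      "time_months": 116,
      "s0": 0.882298024673548
    },
    {
      "time_months": 118,
      "s0": 0.878852271185345
    },
    {
      "time_months": 120,
      "s0": 0.875373209795687
    }
  ],
  "race_piecewise": {
    "race": "chinese",
    "cutpoint_months": 36,
    "beta_early": 0.55,
    "beta_late": -0.25
  }
}
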