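{
  "model_id": "post_biopsy",
  "variant": "with_race",
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
      "s0": 0.999919145853908
    },
    {
      "time_months": 4,
      "s0": 0.999718477762248
    },
    {
      "time_months": 6,
      "s0": 0.999416002125064
    },
    {
      "time_months": 8,
      "s0": 0.999020025102244
    },
    {
      "time_months": 10,
      "s0": 0.998535977477506
    },
    {
      "time_months": 12,
      "s0": 0.997967874811991
    },
    {
      "time_months": 14,
      "s0": 0.997318897119823
    },
    {
      "time_months": 16,
      "s0": 0.996591677604297
    },
    {
      "time_months": 18,
      "s0": 0.995788466709416
    },
    {
      "time_months": 20,
      "s0": 0.994911233881339
    },
    {
      "time_months": 22,
      "s0": 0.993961734811268
    },
    {
      "time_months": 24,
      "s0": 0.992941558048382
    },
    {
      "time_months": 26,
      "s0": 0.991852158549635
    },
    {
      "time_months": 28,
      "s0": 0.990694882570269
    },
    {
      "time_months": 30,
      "s0": 0.989470986596502
    },
    {
      "time_months": 32,
      "s0": 0.988181652050398
    },
    {
      "time_months": 34,
      "s0": 0.986827996915277
    },
    {
      "time_months": 36,
      "s0": 0.985411085067444
    },
    {
      "time_months": 38,
      "s0": 0.983931933866167
    },
    {
      "time_months": 40,
      "s0": 0.982391520398476
    },
    {
      "time_months": 42,
      "s0": 0.980790786669427
    },
    {
      "time_months": 44,
      "s0": 0.979130643954685
    },
    {
      "time_months": 46,
      "s0": 0.977411976479696
    },
    {
      "time_months": 48,
      "s0": 0.975635644551757
    },
    {
      "time_months": 50,
      "s0": 0.973802487243226
    },
    {
      "time_months": 52,
      "s0": 0.971913324703286
    },
    {
      "time_months": 54,
      "s0": 0.969968960159808
    },
    {
      "time_months": 56,
      "s0": 0.967970181660782
    },
    {
      "time_months": 58,
      "s0": 0.965917763595408
    },
    {
      "time_months": 60,
      "s0": 0.963812468027575
    },
    {
      "time_months": 62,
      "s0": 0.961655045868724
    },
    {
      "time_months": 64,
      "s0": 0.959446237912415
    },
    {
      "time_months": 66,
      "s0": 0.957186775749271
    },
    {
      "time_months": 68,
      "s0": 0.954877382577946
    },
    {
      "time_months": 70,
      "s0": 0.952518773925337
    },
    {
      "time_months": 72,
      "s0": 0.950111658287261
    },
    {
      "time_months": 74,
      "s0": 0.947656737699169
    },
    {
      "time_months": 76,
      "s0": 0.945154708245096
    },
    {
      "time_months": 78,
      "s0": 0.942606260511908
    },
    {
      "time_months": 80,
      "s0": 0.940012079994955
    },
    {
      "time_months": 82,
      "s0": 0.937372847460422
    },
    {
      "time_months": 84,
      "s0": 0.934689239268997
    },
    {
      "time_months": 86,
      "s0": 0.931961927664892
    },
    {
      "time_months": 88,
      "s0": 0.929191581033755
    },
    {
      "time_months": 90,
      "s0": 0.926378864132588
    },
    {
      "time_months": 92,
      "s0": 0.923524438294433
    },
    {
      "time_months": 94,
      "s0": 0.920628961610244
    },
    {
      "time_months": 96,
      "s0": 0.91769308909013
    },
    {
      "time_months": 98,
      "s0": 0.914717472805872
    },
    {
      "time_months": 100,
      "s0": 0.911702762016463
    },
    {
      "time_months": 102,
      "s0": 0.908649603278179
    },
    {
      "time_months": 104,
      "s0": 0.90555864054059
    },
    {
      "time_months": 106,
      "s0": 0.902430515229735
    },
    {
      "time_months": 108,
      "s0": 0.899265866319586
    },
    {
      "time_months": 110,
      "s0": 0.896065330392821
    },
    {
      "time_months": 112,
      "s0": 0.892829541691802
    },
    {
      "time_months": 114,
      "s0": 0.889559132160607
    },
    {
      "time_months": 116,
      "s0": 0.886254731478859
    },
    {
      "time_months": 118,
      "s0": 0.882916967088047
    },
    {
      "time_months": 120,
      "s0": 0.879546464210952
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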