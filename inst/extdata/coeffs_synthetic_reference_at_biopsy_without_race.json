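{
  "model_id": "at_biopsy",
  "variant": "without_race",
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
    }
  ],
  "baseline_survival": [
    {
      "time_months": 2,
      "s0": 0.999908512842776
    },
    {
      "time_months": 4,
      "s0": 0.999681459386083
    },
    {
      "time_months": 6,
      "s0": 0.999339223281171
    },
    {
      "time_months": 8,
      "s0": 0.998891215608872
    },
    {
      "time_months": 10,
      "s0": 0.998343596742751
    },
    {
      "time_months": 12,
      "s0": 0.99770092819932
    },
    {
      "time_months": 14,
      "s0": 0.996966828314828
    },
    {
      "time_months": 16,
      "s0": 0.996144298774942
    },
    {
      "time_months": 18,
      "s0": 0.995235910096205
    },
    {
      "time_months": 20,
      "s0": 0.994243916648404
    },
    {
      "time_months": 22,
      "s0": 0.99317033263509
    },
    {
      "time_months": 24,
      "s0": 0.992016984743163
    },
    {
      "time_months": 26,
      "s0": 0.9907855500206
    },
    {
      "time_months": 28,
      "s0": 0.989477583963349
    },
    {
      "time_months": 30,
      "s0": 0.988094541866682
    },
    {
      "time_months": 32,
      "s0": 0.986637795397445
    },
    {
      "time_months": 34,
      "s0": 0.98510864568576
    },
    {
      "time_months": 36,
      "s0": 0.983508333824676
    },
    {
      "time_months": 38,
      "s0": 0.981838049401766
    },
    {
      "time_months": 40,
      "s0": 0.980098937511015
    },
    {
      "time_months": 42,
      "s0": 0.97829210457353
    },
    {
      "time_months": 44,
      "s0": 0.976418623212186
    },
    {
      "time_months": 46,
      "s0": 0.974479536365872
    },
    {
      "time_months": 48,
      "s0": 0.972475860786062
    },
    {
      "time_months": 50,
      "s0": 0.970408590026749
    },
    {
      "time_months": 52,
      "s0": 0.968278697015184
    },
    {
      "time_months": 54,
      "s0": 0.966087136272974
    },
    {
      "time_months": 56,
      "s0": 0.96383484584342
    },
    {
      "time_months": 58,
      "s0": 0.961522748970372
    },
    {
      "time_months": 60,
      "s0": 0.959151755565594
    },
    {
      "time_months": 62,
      "s0": 0.956722763495099
    },
    {
      "time_months": 64,
      "s0": 0.954236659709695
    },
    {
      "time_months": 66,
      "s0": 0.951694321240804
    },
    {
      "time_months": 68,
      "s0": 0.949096616079246
    },
    {
      "time_months": 70,
      "s0": 0.946444403951897
    },
    {
      "time_months": 72,
      "s0": 0.943738537008919
    },
    {
      "time_months": 74,
      "s0": 0.940979860432346
    },
    {
      "time_months": 76,
      "s0": 0.938169212975297
    },
    {
      "time_months": 78,
      "s0": 0.935307427439805
    },
    {
      "time_months": 80,
      "s0": 0.93239533110013
    },
    {
      "time_months": 82,
      "s0": 0.929433746077566
    },
    {
      "time_months": 84,
      "s0": 0.92642348967194
    },
    {
      "time_months": 86,
      "s0": 0.92336537465437
    },
    {
      "time_months": 88,
      "s0": 0.920260209525277
    },
    {
      "time_months": 90,
      "s0": 0.917108798741188
    },
    {
      "time_months": 92,
      "s0": 0.913911942913414
    },
    {
      "time_months": 94,
      "s0": 0.910670438981386
    },
    {
      "time_months": 96,
      "s0": 0.907385080363077
    },
    {
      "time_months": 98,
      "s0": 0.904056657084698
    },
    {
      "time_months": 100,
      "s0": 0.900685955891614
    },
    {
      "time_months": 102,
      "s0": 0.897273760342219
    },
    {
      "time_months": 104,
      "s0": 0.893820850886341
    },
    {
      "time_months": 106,
      "s0": 0.890328004929576
    },
    {
      "time_months": 108,
      "s0": 0.886795996884824
    },
    {
      "time_months": 110,
      "s0": 0.883225598212181
    },
    {
      "time_months": 112,
      "s0": 0.879617577448209
    },
    {
      "time_months": 114,
      "s0": 0.875972700225535
    },
    {
      "time_months": 116,
      "s0": 0.872291729283641
    },
    {
      "time_months": 118,
      "s0": 0.868575424471614
    },
    {
      "time_months": 120,
      "s0": 0.864824542743574
    }
  ]
}
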