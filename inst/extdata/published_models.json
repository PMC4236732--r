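{
  "version": "1.0",
  "comment": "Second-round response models for Chlamydomonas reinhardtii bioenergetics; coefficients at full printed precision. 'means' are the fit-sample arithmetic means used to fix the non-varying factors in profile simulations.",
  "models": [
    {
      "response": "CR",
      "n_fit": 40,
      "intercept": 6.67,
      "linear": { "acetate": 9.01, "light": 0.0259, "ammonium": -0.428 },
      "quadratic": [],
      "interaction": [
        { "a": "acetate", "b": "ammonium", "coef": -0.566,
          "center_a": 0.463, "center_b": 7.69 }
      ],
      "means": { "acetate": 0.463, "light": 107, "ammonium": 7.69 }
    },
    {
      "response": "MA_CYT",
      "n_fit": 41,
      "intercept": 5.81,
      "linear": { "acetate": 7.58, "light": 0.0264, "ammonium": -0.283 },
      "quadratic": [],
      "interaction": [],
      "means": { "acetate": 0.488, "light": 107, "ammonium": 7.32 }
    },
    {
      "response": "MA_ALT",
      "n_fit": 42,
      "intercept": 11.1,
      "linear": { "acetate": 3.64, "light": 0.021, "ammonium": -0.318 },
      "quadratic": [
        { "factor": "acetate", "coef": -13.5, "center": 0.488 }
      ],
      "interaction": [
        { "a": "acetate", "b": "ammonium", "coef": -0.383,
          "center_a": 0.488, "center_b": 7.32 }
      ],
      "means": { "acetate": 0.488, "light": 107, "ammonium": 7.32 }
    },
    {
      "response": "PHIPSII800",
      "n_fit": 42,
      "intercept": 0.308,
      "linear": { "light": 0.00103 },
      "quadratic": [],
      "interaction": [],
      "means": { "light": 107 }
    },
    {
      "response": "NPQ800",
      "n_fit": 42,
      "intercept": 0.334,
      "linear": { "acetate": -0.0877, "light": -0.000146, "nitrate": -0.00146 },
      "quadratic": [
        { "factor": "nitrate", "coef": -0.00109, "center": 9.76 }
      ],
      "interaction": [
        { "a": "acetate", "b": "light", "coef": -0.000918,
          "center_a": 0.488, "center_b": 107 }
      ],
      "means": { "acetate": 0.488, "light": 107, "nitrate": 9.76 }
    },
    {
      "response": "P800",
      "n_fit": 42,
      "intercept": 42.3,
      "linear": { "acetate": -3.18, "light": 0.185, "nitrate": 0.879 },
      "quadratic": [
        { "factor": "acetate", "coef": 183, "center": 0.488 },
        { "factor": "nitrate", "coef": -0.608, "center": 9.76 }
      ],
      "interaction": [],
      "means": { "acetate": 0.488, "light": 107, "nitrate": 9.76 }
    }
  ]
}
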