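{
  "comment": "Illustrative (synthetic) logistic NTCP models for grade 2/3 xerostomia and dysphagia. Structure and signs are plausible for head-and-neck toxicity modelling (sqrt of parotid mean dose for xerostomia; constrictor/oral mean dose for dysphagia); the coefficients are NOT a published protocol.",
  "models": [
    {
      "name": "xerostomia_g2",
      "grade": "g2",
      "intercept": -2.2,
      "terms": [
        {"predictor": "parotid_l_mean", "transform": "sqrt", "coefficient": 0.25},
        {"predictor": "parotid_r_mean", "transform": "sqrt", "coefficient": 0.25}
      ]
    },
    {
      "name": "xerostomia_g3",
      "grade": "g3",
      "intercept": -3.7,
      "terms": [
        {"predictor": "parotid_l_mean", "transform": "sqrt", "coefficient": 0.25},
        {"predictor": "parotid_r_mean", "transform": "sqrt", "coefficient": 0.25}
      ]
    },
    {
      "name": "dysphagia_g2",
      "grade": "g2",
      "intercept": -2.8,
      "terms": [
        {"predictor": "constrictor_mean", "transform": "identity", "coefficient": 0.06},
        {"predictor": "baseline", "transform": "identity", "coefficient": 0.3}
      ]
    },
    {
      "name": "dysphagia_g3",
      "grade": "g3",
      "intercept": -4.2,
      "terms": [
        {"predictor": "constrictor_mean", "transform": "identity", "coefficient": 0.06},
        {"predictor": "baseline", "transform": "identity", "coefficient": 0.3}
      ]
    }
  ]
}
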