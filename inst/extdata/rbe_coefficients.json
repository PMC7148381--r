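{
  "version": "1.0",
  "models": {
    "constant_1p1": {
      "parameters": {"rbe": 1.1},
      "citation": "Clinical constant proton RBE of 1.1 (ICRU Report 78)."
    },
    "mcn": {
      "parameters": {
        "p0": 0.99064,
        "p1": 0.35605,
        "p2": 1.1012,
        "p3": 0.0038703
      },
      "units": {
        "p0": "dimensionless",
        "p1": "Gy um/keV",
        "p2": "dimensionless",
        "p3": "Gy^-1/2 um/keV"
      },
      "citation": "McNamara AL, Schuemann J, Paganetti H (2015). A phenomenological relative biological effectiveness (RBE) model for proton therapy based on all published in vitro cell survival data. Phys Med Biol 60:8399-8416. RBEmax = p0 + p1*LETd/(alpha/beta)x; RBEmin = p2 - p3*sqrt((alpha/beta)x)*LETd."
    },
    "ror": {
      "parameters": {
        "r0": 0.99,
        "slope": 0.35,
        "let_scale": 25.0
      },
      "units": {
        "r0": "dimensionless",
        "slope": "Gy um/keV (initial slope of r(L) times (alpha/beta)x)",
        "let_scale": "keV/um"
      },
      "citation": "SYNTHETIC default response: saturating-exponential nonlinear LET response r(L; ab) = r0 + (slope/ab)*let_scale*(1 - exp(-L/let_scale)) averaged dose-weighted over the LET spectrum, with RBEmin fixed at 1, in the spirit of spectrum-based LET-response models (Rorvik et al. 2017, Med Phys 44:2586). The published coefficients are not reproduced here; the defaults were calibrated once so the response stays below the linear (MCN) RBEmax over the organ LET range and the organ-level RBE gap between the two models stays within the reported magnitude (about 0.07 in dose-weighted organ-mean RBE)."
    }
  }
}
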