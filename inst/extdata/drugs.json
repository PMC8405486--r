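{
  "note": "Physicochemical parameters and regional unbound partition coefficients (Kp_uu) for the twelve evaluation drugs. Kp_uu sets are keyed by population; morphine additionally by dose group. Unbound plasma fractions are best-effort literature values. The printed asymmetry-factor table columns of the source are typographically ambiguous and are NOT reproduced here: asymmetry factors are always re-derived from Kp_uu by the steady-state solver.",
  "drugs": [
    {
      "name": "acetaminophen", "mw": 151.16, "charge_class": "neutral",
      "pka": 9.46, "pkb": -4.4, "logp": 0.46, "fu_plasma": 0.8, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 0.51, "lv": 0.51, "cm": 0.51},
        "human": {"ecf": 1, "lv": 1, "cm": 1}
      }
    },
    {
      "name": "atenolol", "mw": 266.34, "charge_class": "base",
      "pka": 14.08, "pkb": 9.67, "logp": 0.16, "fu_plasma": 0.96, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 0.037, "lv": 0.037, "cm": 0.037}
      }
    },
    {
      "name": "indomethacin", "mw": 357.8, "charge_class": "acid",
      "pka": 3.79, "pkb": -2.9, "logp": 4.27, "fu_plasma": 0.01, "fu_csf": 0.47,
      "kpuu": {
        "human": {"ecf": 0.1, "lv": 0.272, "cm": 0.272}
      }
    },
    {
      "name": "methotrexate", "mw": 454.45, "charge_class": "acid",
      "pka": 3.41, "pkb": 2.81, "logp": -1.85, "fu_plasma": 0.54, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 0.018, "lv": 0.0066, "cm": 0.0024}
      }
    },
    {
      "name": "morphine", "mw": 285.34, "charge_class": "base",
      "pka": 10.26, "pkb": 9.12, "logp": 0.87, "fu_plasma": 0.65, "fu_csf": 1,
      "kpuu": {
        "rat_4mg/kg": {"ecf": 0.38, "lv": 0.38, "cm": 0.38},
        "rat_10-40mg/kg": {"ecf": 0.23, "lv": 0.23, "cm": 0.23},
        "human": {"ecf": 0.23, "lv": 0.23, "cm": 0.23}
      }
    },
    {
      "name": "oxycodone", "mw": 315.37, "charge_class": "base",
      "pka": 13.56, "pkb": 8.21, "logp": 0.7, "fu_plasma": 0.55, "fu_csf": 1,
      "kpuu": {
        "human": {"ecf": 1.69, "lv": 2, "cm": 2}
      }
    },
    {
      "name": "paliperidone", "mw": 426.49, "charge_class": "base",
      "pka": 13.74, "pkb": 8.76, "logp": 1.8, "fu_plasma": 0.26, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 0.5, "lv": 0.5, "cm": 0.5}
      }
    },
    {
      "name": "phenytoin", "mw": 252.27, "charge_class": "neutral",
      "pka": 9.47, "pkb": -9, "logp": 2.47, "fu_plasma": 0.1, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 0.26, "lv": 0.26, "cm": 0.26}
      }
    },
    {
      "name": "quinidine", "mw": 324.42, "charge_class": "base",
      "pka": 13.89, "pkb": 9.05, "logp": 3.44, "fu_plasma": 0.13, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 1.5, "lv": 1.5, "cm": 1.5}
      }
    },
    {
      "name": "raclopride", "mw": 347.24, "charge_class": "amphoteric",
      "pka": 5.31, "pkb": 9.32, "logp": 3.38, "fu_plasma": 0.9, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 1.1, "lv": 1.1, "cm": 1.1}
      }
    },
    {
      "name": "remoxipride", "mw": 371.28, "charge_class": "base",
      "pka": 13.06, "pkb": 8.4, "logp": 2.1, "fu_plasma": 0.2, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 0.8, "lv": 0.8, "cm": 0.8}
      }
    },
    {
      "name": "risperidone", "mw": 410.49, "charge_class": "base",
      "pka": null, "pkb": 8.76, "logp": 3.27, "fu_plasma": 0.1, "fu_csf": 1,
      "kpuu": {
        "rat": {"ecf": 0.97, "lv": 0.97, "cm": 0.97}
      }
    }
  ]
}
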