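{
  "note": "Empirical compartmental plasma PK parameter sets used as fixed inputs (mL, mL/min, min, ng/mL). iiv_cv holds percent CVs of the exponential inter-individual variability model; residual error is proportional %CV plus additive SD. Indomethacin (human) uses intramuscular dosing modelled as first-order absorption with 100% bioavailability.",
  "models": [
    {"drug": "acetaminophen", "species": "rat", "cl_cen": 4.70, "q_cen_per1": 11.18, "q_cen_per2": 31.35, "v_cen": 50.71, "v_per1": 27891.70, "v_per2": 162.47,
     "iiv_cv": {"cl_cen": 35.5}, "resid_prop_cv": 26.7, "resid_add_sd": 0, "fu_plasma": 0.8},
    {"drug": "atenolol", "species": "rat", "cl_cen": 6.30, "q_cen_per1": 4.25, "q_cen_per2": 0, "v_cen": 118.70, "v_per1": 203.36, "v_per2": 0,
     "iiv_cv": {"cl_cen": 8.9}, "resid_prop_cv": 14.7, "resid_add_sd": 0, "fu_plasma": 0.96},
    {"drug": "methotrexate", "species": "rat", "cl_cen": 8.31, "q_cen_per1": 23.33, "q_cen_per2": 0.79, "v_cen": 38.16, "v_per1": 139.95, "v_per2": 47.99,
     "iiv_cv": {"cl_cen": 36.5, "q_cen_per2": 52.3, "v_per2": 29.5}, "resid_prop_cv": 17.6, "resid_add_sd": 0, "fu_plasma": 0.54},
    {"drug": "morphine", "species": "rat", "cl_cen": 23.34, "q_cen_per1": 4.97, "q_cen_per2": 31.68, "v_cen": 175.73, "v_per1": 1636.28, "v_per2": 475.86,
     "iiv_cv": {"cl_cen": 46.9, "q_cen_per1": 93.9, "v_cen": 92.5, "v_per2": 49.2}, "resid_prop_cv": 24.2, "resid_add_sd": 0, "fu_plasma": 0.65},
    {"drug": "paliperidone", "species": "rat", "cl_cen": 219.46, "q_cen_per1": 6765.63, "q_cen_per2": 0, "v_cen": 25.00, "v_per1": 32981.00, "v_per2": 0,
     "iiv_cv": {"cl_cen": 44.4, "v_per1": 45.5}, "resid_prop_cv": 20.0, "resid_add_sd": 0, "fu_plasma": 0.26},
    {"drug": "phenytoin", "species": "rat", "cl_cen": 47.72, "q_cen_per1": 415.88, "q_cen_per2": 0, "v_cen": 453.32, "v_per1": 2268.39, "v_per2": 0,
     "iiv_cv": {"cl_cen": 65.8, "v_cen": 122.5, "v_per1": 22.0}, "resid_prop_cv": 16.3, "resid_add_sd": 1571.0, "fu_plasma": 0.1},
    {"drug": "quinidine", "species": "rat", "cl_cen": 178.28, "q_cen_per1": 238.03, "q_cen_per2": 753.99, "v_cen": 183.65, "v_per1": 7335.00, "v_per2": 5062.54,
     "iiv_cv": {"cl_cen": 26.1, "q_cen_per1": 38.4}, "resid_prop_cv": 23.4, "resid_add_sd": 20.8, "fu_plasma": 0.13},
    {"drug": "raclopride", "species": "rat", "cl_cen": 45.40, "q_cen_per1": 68.04, "q_cen_per2": 15.03, "v_cen": 50.44, "v_per1": 468.42, "v_per2": 690.00,
     "iiv_cv": {"cl_cen": 13.6}, "resid_prop_cv": 14.3, "resid_add_sd": 0, "fu_plasma": 0.9},
    {"drug": "remoxipride", "species": "rat", "cl_cen": 47.43, "q_cen_per1": 16.52, "q_cen_per2": 56.76, "v_cen": 82.89, "v_per1": 602.77, "v_per2": 457.52,
     "iiv_cv": {"cl_cen": 31.0, "q_cen_per2": 29.8, "v_cen": 124.4, "v_per1": 36.4, "v_per2": 44.7}, "resid_prop_cv": 21.3, "resid_add_sd": 0, "fu_plasma": 0.2},
    {"drug": "risperidone", "species": "rat", "cl_cen": 773.30, "q_cen_per1": 0, "q_cen_per2": 0, "v_cen": 47936.80, "v_per1": 0, "v_per2": 0,
     "iiv_cv": {"cl_cen": 89.9, "v_cen": 66.9}, "resid_prop_cv": 29.6, "resid_add_sd": 12.9, "fu_plasma": 0.1},
    {"drug": "acetaminophen", "species": "human", "cl_cen": 495.00, "q_cen_per1": 0, "q_cen_per2": 0, "v_cen": 108000.00, "v_per1": 0, "v_per2": 0,
     "iiv_cv": {}, "resid_prop_cv": 23.9, "resid_add_sd": 0, "fu_plasma": 0.8},
    {"drug": "indomethacin", "species": "human", "cl_cen": 14200.00, "q_cen_per1": 54600.00, "q_cen_per2": 0, "v_cen": 1320000.00, "v_per1": 10300000.00, "v_per2": 0,
     "ka": 2850000, "f_bio": 1.0,
     "iiv_cv": {"q_cen_per1": 145.9}, "resid_prop_cv": 22.3, "resid_add_sd": 0, "fu_plasma": 0.01},
    {"drug": "morphine", "species": "human", "cl_cen": 3070.00, "q_cen_per1": 3030.00, "q_cen_per2": 0, "v_cen": 16000.00, "v_per1": 95400.00, "v_per2": 0,
     "iiv_cv": {"cl_cen": 27.1, "v_cen": 59.6}, "resid_prop_cv": 9.6, "resid_add_sd": 0, "fu_plasma": 0.65},
    {"drug": "oxycodone", "species": "human", "cl_cen": 1140.00, "q_cen_per1": 11700.00, "q_cen_per2": 47.40, "v_cen": 93600.00, "v_per1": 178000.00, "v_per2": 19400.00,
     "iiv_cv": {"cl_cen": 31.1, "v_cen": 86.7}, "resid_prop_cv": 19.1, "resid_add_sd": 0, "fu_plasma": 0.55}
  ]
}
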