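{
  "species": "rat",
  "note": "Best-effort literature defaults; where several literature values exist the mean was used. v_bcm and sa_bcm are derived (bcm_fraction * v_brain; spherical-cell geometry) and therefore not listed.",
  "fields": {
    "v_mv": {"value": 0.054, "units": "mL", "source": "brain microvascular blood volume, ~3% of brain volume"},
    "v_ecf": {"value": 0.29, "units": "mL", "source": "brain extracellular fluid, ~16-20% of brain volume"},
    "v_icf": {"value": 1.16, "units": "mL", "source": "brain intracellular fluid, ~60-65% of brain volume"},
    "v_lys": {"value": 0.011, "units": "mL", "source": "lumped lysosomal volume, ~1% of cell volume"},
    "v_lv": {"value": 0.05, "units": "mL", "source": "lateral ventricles CSF"},
    "v_tfv": {"value": 0.05, "units": "mL", "source": "third + fourth ventricles CSF"},
    "v_cm": {"value": 0.017, "units": "mL", "source": "cisterna magna CSF"},
    "v_sas": {"value": 0.18, "units": "mL", "source": "subarachnoid CSF (total rat CSF ~0.25-0.3 mL)"},
    "v_brain": {"value": 1.8, "units": "mL", "source": "adult rat brain volume"},
    "bcm_fraction": {"value": 0.05, "units": "1", "source": "phospholipid volume fraction of brain, 5% of total brain volume"},
    "q_cbf": {"value": 1.2, "units": "mL/min", "source": "cerebral blood flow, ~0.6-1 mL/g/min x 1.8 g brain"},
    "q_ecf": {"value": 0.0002, "units": "mL/min", "source": "brain ECF bulk flow, ~0.2 uL/min"},
    "q_csf": {"value": 0.0022, "units": "mL/min", "source": "CSF production, ~2.2 uL/min"},
    "sa_bbb": {"value": 263, "units": "cm2", "source": "BBB endothelial surface, ~150 cm2/g brain"},
    "sa_bcsfb_lv": {"value": 120, "units": "cm2", "source": "choroid plexus epithelium of the lateral ventricles incl. apical microvilli (total BCSFB comparable to BBB area)"},
    "sa_bcsfb_tfv": {"value": 60, "units": "cm2", "source": "choroid plexus epithelium of the third/fourth ventricles incl. apical microvilli"},
    "sa_lys": {"value": 1122, "units": "cm2", "source": "total lysosomal membrane: ~300 lysosomes/cell, radius ~0.3 um"},
    "pore_radius_nm": {"value": 0.9, "units": "nm", "source": "effective BBB/BCSFB tight-junction pore radius"},
    "paracellular_length_um": {"value": 0.5, "units": "um", "source": "effective paracellular path length (endothelial cell height)"},
    "paracellular_fraction": {"value": 0.0001, "units": "1", "source": "fraction of barrier surface occupied by tight-junction pores"},
    "n_cells": {"value": 3.3e8, "units": "count", "source": "neurons + glia in rat brain"},
    "cell_radius_um": {"value": 9.4, "units": "um", "source": "equivalent spherical radius so total cell volume matches v_icf"},
    "ph_plasma": {"value": 7.4, "units": "pH", "source": "arterial plasma"},
    "ph_ecf": {"value": 7.3, "units": "pH", "source": "brain interstitial fluid"},
    "ph_icf": {"value": 7.0, "units": "pH", "source": "neuronal/glial cytosol"},
    "ph_lys": {"value": 5.0, "units": "pH", "source": "lysosomal lumen"},
    "ph_csf": {"value": 7.3, "units": "pH", "source": "cerebrospinal fluid"}
  }
}
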