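{
  "species": "human",
  "note": "Best-effort literature defaults; where several literature values exist the mean was used. v_bcm and sa_bcm are derived (bcm_fraction * v_brain; spherical-cell geometry) and therefore not listed.",
  "fields": {
    "v_mv": {"value": 30, "units": "mL", "source": "brain microvascular blood volume, ~2% of brain volume (PET/MRI blood-volume studies)"},
    "v_ecf": {"value": 260, "units": "mL", "source": "brain extracellular fluid, ~18-20% of brain volume"},
    "v_icf": {"value": 850, "units": "mL", "source": "brain intracellular fluid, ~60% of brain volume"},
    "v_lys": {"value": 5.8, "units": "mL", "source": "lumped lysosomal volume, ~0.7-1% of cell volume"},
    "v_lv": {"value": 22.5, "units": "mL", "source": "lateral ventricles, MRI volumetry in healthy adults"},
    "v_tfv": {"value": 22.5, "units": "mL", "source": "third + fourth ventricles and aqueduct"},
    "v_cm": {"value": 7.5, "units": "mL", "source": "cisterna magna"},
    "v_sas": {"value": 90, "units": "mL", "source": "cranial + spinal subarachnoid CSF (total CSF ~140-150 mL minus ventricular/cisternal)"},
    "v_brain": {"value": 1400, "units": "mL", "source": "adult brain volume"},
    "bcm_fraction": {"value": 0.05, "units": "1", "source": "phospholipid volume fraction of brain, 5% of total brain volume"},
    "q_cbf": {"value": 610, "units": "mL/min", "source": "cerebral blood flow, ~50 mL/100g/min x 1.2-1.4 kg brain"},
    "q_ecf": {"value": 0.2, "units": "mL/min", "source": "brain ECF bulk flow, 0.15-0.2 mL/min"},
    "q_csf": {"value": 0.35, "units": "mL/min", "source": "CSF production, ~500 mL/day"},
    "sa_bbb": {"value": 150000, "units": "cm2", "source": "BBB endothelial surface, 12-18 m2"},
    "sa_bcsfb_lv": {"value": 75000, "units": "cm2", "source": "choroid plexus epithelium of the lateral ventricles incl. apical microvilli (total BCSFB comparable to BBB area)"},
    "sa_bcsfb_tfv": {"value": 37500, "units": "cm2", "source": "choroid plexus epithelium of the third/fourth ventricles incl. apical microvilli"},
    "sa_lys": {"value": 580000, "units": "cm2", "source": "total lysosomal membrane: ~300 lysosomes/cell, radius ~0.3 um"},
    "pore_radius_nm": {"value": 0.9, "units": "nm", "source": "effective BBB/BCSFB tight-junction pore radius"},
    "paracellular_length_um": {"value": 0.5, "units": "um", "source": "effective paracellular path length (endothelial cell height)"},
    "paracellular_fraction": {"value": 0.0001, "units": "1", "source": "fraction of barrier surface occupied by tight-junction pores"},
    "n_cells": {"value": 1.7e11, "units": "count", "source": "neurons + glia in human brain"},
    "cell_radius_um": {"value": 10.6, "units": "um", "source": "equivalent spherical radius so total cell volume matches v_icf"},
    "ph_plasma": {"value": 7.4, "units": "pH", "source": "arterial plasma"},
    "ph_ecf": {"value": 7.3, "units": "pH", "source": "brain interstitial fluid"},
    "ph_icf": {"value": 7.0, "units": "pH", "source": "neuronal/glial cytosol"},
    "ph_lys": {"value": 5.0, "units": "pH", "source": "lysosomal lumen"},
    "ph_csf": {"value": 7.3, "units": "pH", "source": "cerebrospinal fluid"}
  }
}
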