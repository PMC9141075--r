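{
  "name": "Perinatology care system (case-study fixture)",
  "layout": "current",
  "units": [
    {"id": "N1",  "department": "Neonatology", "beds": 14, "patient_group": "newborn", "specialization_rank": 1},
    {"id": "N2",  "department": "Neonatology", "beds": 4,  "patient_group": "newborn", "specialization_rank": 2},
    {"id": "N3",  "department": "Neonatology", "beds": 11, "patient_group": "newborn", "specialization_rank": 3},
    {"id": "O1n", "department": "Obstetrics",  "beds": 7,  "patient_group": "newborn", "specialization_rank": 4},
    {"id": "O1a", "department": "Obstetrics",  "beds": 25, "patient_group": "adult",   "specialization_rank": 3},
    {"id": "O2",  "department": "Obstetrics",  "beds": 3,  "patient_group": "adult",   "specialization_rank": 2},
    {"id": "O3",  "department": "Obstetrics",  "beds": 6,  "patient_group": "adult",   "specialization_rank": 1}
  ],
  "roster": {
    "comment": "Scheduled nurses per shift type; O1 is a single roster column and is split over O1n/O1a at load time in proportion to beds.",
    "day":     {"N1": 12, "N2": 2, "N3": 4, "O1": 6, "O2": 1, "O3": 3},
    "evening": {"N1": 8,  "N2": 2, "N3": 2, "O1": 5, "O2": 1, "O3": 3},
    "night":   {"N1": 7,  "N2": 2, "N3": 2, "O1": 2, "O2": 1, "O3": 3}
  },
  "ntp_ratio": {
    "comment": "Patients per nurse; the O1 ratio applies to both O1n and O1a.",
    "day":     {"N1": 1, "N2": 2, "N3": 3, "O1": 5,  "O2": 3, "O3": 2},
    "evening": {"N1": 2, "N2": 2, "N3": 6, "O1": 6,  "O2": 3, "O3": 2},
    "night":   {"N1": 2, "N2": 2, "N3": 6, "O1": 16, "O2": 3, "O3": 2}
  },
  "skill_matrix_csv": "skill_matrix_current.csv",
  "registry": [
    {"group": "N1",            "units": ["N1"],                       "nurses": 59},
    {"group": "N2",            "units": ["N2"],                       "nurses": 40},
    {"group": "N3",            "units": ["N3"],                       "nurses": 14},
    {"group": "O1, O2 and O3", "units": ["O1n", "O1a", "O2", "O3"],   "nurses": 53},
    {"group": "O1 and O2",     "units": ["O1n", "O1a", "O2"],         "nurses": 5},
    {"group": "O1",            "units": ["O1n", "O1a"],               "nurses": 5}
  ]
}
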