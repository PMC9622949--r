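[
  {
    "id": "M6",
    "b_edges": ["lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC", "lvlPFC->ldlPFC",
                "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC", "rvlPFC->rdlPFC"],
    "intrinsic_sites": []
  },
  {
    "id": "M29",
    "b_edges": ["lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC", "lvlPFC->ldlPFC",
                "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC", "rvlPFC->rdlPFC",
                "lSPL->lITG", "lvlPFC->lSPL", "ldlPFC->lSPL", "ldlPFC->lvlPFC",
                "rSPL->rITG", "rvlPFC->rSPL", "rdlPFC->rSPL", "rdlPFC->rvlPFC",
                "lvlPFC->dACC", "dACC->lvlPFC", "rvlPFC->dACC", "dACC->rvlPFC"],
    "intrinsic_sites": []
  },
  {
    "id": "M8",
    "b_edges": ["V1->lITG", "lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC",
                "lvlPFC->ldlPFC", "lvlPFC->dACC",
                "V1->rITG", "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC",
                "rvlPFC->rdlPFC", "rvlPFC->dACC"],
    "intrinsic_sites": []
  },
  {
    "id": "M41",
    "b_edges": ["lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC", "lvlPFC->ldlPFC",
                "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC", "rvlPFC->rdlPFC",
                "lSPL->lITG", "lvlPFC->lSPL", "ldlPFC->lSPL", "ldlPFC->lvlPFC",
                "rSPL->rITG", "rvlPFC->rSPL", "rdlPFC->rSPL", "rdlPFC->rvlPFC"],
    "intrinsic_sites": []
  },
  {
    "id": "N22a",
    "b_edges": ["lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC", "lvlPFC->ldlPFC",
                "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC", "rvlPFC->rdlPFC"],
    "intrinsic_sites": ["V1", "SPL", "PFC"]
  },
  {
    "id": "N22b",
    "b_edges": ["lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC", "lvlPFC->ldlPFC",
                "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC", "rvlPFC->rdlPFC"],
    "intrinsic_sites": ["V1", "ITG", "PFC"]
  },
  {
    "id": "N23",
    "b_edges": ["lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC", "lvlPFC->ldlPFC",
                "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC", "rvlPFC->rdlPFC"],
    "intrinsic_sites": ["V1", "SPL", "PFC", "dACC"]
  },
  {
    "id": "N26",
    "b_edges": ["V1->lITG", "lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC",
                "lvlPFC->ldlPFC", "lvlPFC->dACC",
                "V1->rITG", "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC",
                "rvlPFC->rdlPFC", "rvlPFC->dACC"],
    "intrinsic_sites": ["V1", "ITG", "PFC"]
  },
  {
    "id": "N9",
    "b_edges": ["V1->lITG", "lITG->lSPL", "lSPL->lvlPFC", "lSPL->ldlPFC",
                "lvlPFC->ldlPFC", "lvlPFC->dACC",
                "V1->rITG", "rITG->rSPL", "rSPL->rvlPFC", "rSPL->rdlPFC",
                "rvlPFC->rdlPFC", "rvlPFC->dACC"],
    "intrinsic_sites": ["ITG", "PFC", "dACC"]
  }
]
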