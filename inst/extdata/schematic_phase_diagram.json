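{
  "provenance": "Synthetic schematic DOPC/EggSM/Chol diagram for illustration and testing only; region boundaries are simple cholesterol-fraction bands chosen to reproduce the qualitative phase assignments of the study compositions (1:1:0 gel/liquid, 1:1:3 uniform liquid, 2:2:3 and 1:1:1 Lo/Ld). Not an empirical phase diagram; supply a measured diagram for real compositional work.",
  "regions": [
    {
      "phase": "gel_liquid_coexistence",
      "vertices": [
        [1.0, 0.0, 0.0],
        [0.0, 1.0, 0.0],
        [0.0, 0.9, 0.1],
        [0.9, 0.0, 0.1]
      ]
    },
    {
      "phase": "Lo_Ld_coexistence",
      "vertices": [
        [0.9, 0.0, 0.1],
        [0.0, 0.9, 0.1],
        [0.0, 0.5, 0.5],
        [0.5, 0.0, 0.5]
      ]
    },
    {
      "phase": "uniform_liquid",
      "vertices": [
        [0.5, 0.0, 0.5],
        [0.0, 0.5, 0.5],
        [0.0, 0.0, 1.0]
      ]
    }
  ]
}
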