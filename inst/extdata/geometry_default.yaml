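layers:
- name: al_foil
  position_mm: 20.0
  thickness_mm: 0.15
  density_g_cm3: 2.7
- name: rcf_protect
  position_mm: 20.15
  thickness_mm: 0.375
  density_g_cm3: 1.35
- name: rcf1
  position_mm: 50.0
  thickness_mm: 0.125
  density_g_cm3: 1.35
- name: peek_front
  position_mm: 52.0
  thickness_mm: 2.0
  density_g_cm3: 1.32
- name: water
  position_mm: 54.0
  thickness_mm: 30.0
  density_g_cm3: 1.0
- name: peek_back
  position_mm: 84.0
  thickness_mm: 2.0
  density_g_cm3: 1.32
- name: rcf2
  position_mm: 87.0
  thickness_mm: 0.125
  density_g_cm3: 1.35
planes:
- label: RCF1
  position_mm: 50.0
- label: tank_entrance
  position_mm: 54.0
- label: RCF2
  position_mm: 87.0
- label: RCF3
  position_mm: 125.0
magnets:
- field_T: 0.4
  length_mm: 10.0
  position_mm: 30.0
- field_T: 0.4
  length_mm: 30.0
  position_mm: 89.0
tank:
  entrance_mm: 54.0
  length_mm: 30.0
  width_mm: 20.0
  height_mm: 20.0
  sample_width_mm: 5.0
  sample_height_mm: 5.0
stopping_power_material: water
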