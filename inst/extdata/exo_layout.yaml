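actuators:
- id: sh_front
  anchor_segment: torso
  anchor:
  - 0.12
  - 0.05
  - 0.02
  end_segment: upper_arm
  end:
  - 0.045
  - 0.0
  - -0.17
  F_max: 40.0
  joint: shoulder
- id: sh_back
  anchor_segment: torso
  anchor:
  - -0.12
  - 0.05
  - 0.02
  end_segment: upper_arm
  end:
  - -0.045
  - 0.0
  - -0.17
  F_max: 40.0
  joint: shoulder
- id: sh_down
  anchor_segment: torso
  anchor:
  - 0.0
  - 0.05
  - -0.35
  end_segment: upper_arm
  end:
  - 0.0
  - 0.05
  - -0.15
  F_max: 40.0
  joint: shoulder
- id: sh_medial
  anchor_segment: torso
  anchor:
  - 0.0
  - 0.18
  - -0.05
  end_segment: upper_arm
  end:
  - 0.0
  - 0.045
  - -0.17
  F_max: 40.0
  joint: shoulder
- id: sh_rot
  anchor_segment: torso
  anchor:
  - 0.02
  - 0.15
  - -0.1
  end_segment: upper_arm
  end:
  - 0.045
  - 0.0
  - -0.22
  F_max: 40.0
  joint: shoulder
- id: el_flex
  anchor_segment: upper_arm
  anchor:
  - 0.06
  - 0.0
  - -0.22
  end_segment: forearm
  end:
  - 0.055
  - 0.0
  - -0.1
  F_max: 60.0
  joint: elbow
- id: el_ext
  anchor_segment: upper_arm
  anchor:
  - -0.12
  - 0.0
  - -0.22
  end_segment: forearm
  end:
  - -0.055
  - 0.0
  - -0.1
  F_max: 60.0
  joint: elbow
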