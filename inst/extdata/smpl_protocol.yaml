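n_vertices: 6890
landmarks:
- index: 1
  name: Inseam point
  vertex_index: 3149
- index: 2
  name: Left shoulder
  vertex_index: 3011
- index: 3
  name: Right shoulder
  vertex_index: 6470
- index: 4
  name: Left chest
  vertex_index: 1423
- index: 5
  name: Left hip
  vertex_index: 1229
- index: 6
  name: Right hip
  vertex_index: 4949
- index: 7
  name: Left mid finger
  vertex_index: 2445
- index: 8
  name: Right mid finger
  vertex_index: 5906
- index: 9
  name: Left wrist
  vertex_index: 2241
- index: 10
  name: Shoulder top
  vertex_index: 3068
- index: 11
  name: Low left hip
  vertex_index: 3134
- index: 12
  name: Left ankle
  vertex_index: 3334
- index: 13
  name: Lower belly point
  vertex_index: 1769
- index: 14
  name: Forehead point
  vertex_index: 335
- index: 15
  name: Right forearm point
  vertex_index: 5084
- index: 16
  name: Right thigh point
  vertex_index: 4971
- index: 17
  name: Right calf point
  vertex_index: 4589
- index: 18
  name: Right ankle point
  vertex_index: 6723
- index: 19
  name: Mid hip point
  vertex_index: 3145
- index: 20
  name: Right bicep point
  vertex_index: 6281
measurements:
- code: A
  name: Head circumference
  kind: circumference
  landmarks: 14
  plane_orientation: horizontal
- code: B
  name: Neck circumference
  kind: circumference
  landmarks: 10
  plane_orientation: horizontal
- code: C
  name: Shoulder to crotch
  kind: length
  landmarks:
  - 1
  - 10
  plane_orientation: none
- code: D
  name: Chest circumference
  kind: circumference
  landmarks: 4
  plane_orientation: horizontal
- code: E
  name: Waist circumference
  kind: circumference
  landmarks: 13
  plane_orientation: horizontal
- code: F
  name: Hip circumference
  kind: circumference
  landmarks: 19
  plane_orientation: horizontal
- code: G
  name: Wrist circumference
  kind: circumference
  landmarks: 9
  plane_orientation: vertical
- code: H
  name: Bicep circumference
  kind: circumference
  landmarks: 20
  plane_orientation: vertical
- code: I
  name: Forearm circumference
  kind: circumference
  landmarks: 15
  plane_orientation: vertical
- code: J
  name: Arm length
  kind: length
  landmarks:
  - 2
  - 9
  plane_orientation: none
- code: K
  name: Inside leg length
  kind: length
  landmarks:
  - 11
  - 12
  plane_orientation: none
- code: L
  name: Thigh circumference
  kind: circumference
  landmarks: 16
  plane_orientation: horizontal
- code: M
  name: Calf circumference
  kind: circumference
  landmarks: 17
  plane_orientation: horizontal
- code: 'N'
  name: Ankle circumference
  kind: circumference
  landmarks: 18
  plane_orientation: horizontal
- code: O
  name: Shoulder breadth
  kind: length
  landmarks:
  - 2
  - 3
  plane_orientation: none
- code: arm_span
  name: Arm span
  kind: length
  landmarks:
  - 7
  - 8
  plane_orientation: none
- code: inseam_height
  name: Inseam height
  kind: length
  landmarks:
  - 2
  - 19
  plane_orientation: none
- code: hip_width
  name: Hip width
  kind: length
  landmarks:
  - 5
  - 6
  plane_orientation: none
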