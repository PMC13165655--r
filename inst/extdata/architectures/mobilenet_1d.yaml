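name: mobilenet_1d
input_length: 1024
declared_param_count: 10738
layers:
- name: stem
  kind: conv1d
  inputs:
  - input
  kernel: 3
  filters: 8
  stride: 2
- name: stem_relu
  kind: relu
  inputs:
  - stem
- name: s1_dw
  kind: depthwise_conv1d
  inputs:
  - stem_relu
  kernel: 3
  stride: 2
- name: s1_dw_relu
  kind: relu
  inputs:
  - s1_dw
- name: s1_pw
  kind: pointwise_conv1d
  inputs:
  - s1_dw_relu
  kernel: 1
  filters: 16
- name: s1_pw_relu
  kind: relu
  inputs:
  - s1_pw
- name: s2_dw
  kind: depthwise_conv1d
  inputs:
  - s1_pw_relu
  kernel: 3
  stride: 2
- name: s2_dw_relu
  kind: relu
  inputs:
  - s2_dw
- name: s2_pw
  kind: pointwise_conv1d
  inputs:
  - s2_dw_relu
  kernel: 1
  filters: 28
- name: s2_pw_relu
  kind: relu
  inputs:
  - s2_pw
- name: s3_dw
  kind: depthwise_conv1d
  inputs:
  - s2_pw_relu
  kernel: 3
  stride: 2
- name: s3_dw_relu
  kind: relu
  inputs:
  - s3_dw
- name: s3_pw
  kind: pointwise_conv1d
  inputs:
  - s3_dw_relu
  kernel: 1
  filters: 72
- name: s3_pw_relu
  kind: relu
  inputs:
  - s3_pw
- name: s4_dw
  kind: depthwise_conv1d
  inputs:
  - s3_pw_relu
  kernel: 3
  stride: 2
- name: s4_dw_relu
  kind: relu
  inputs:
  - s4_dw
- name: s4_pw
  kind: pointwise_conv1d
  inputs:
  - s4_dw_relu
  kernel: 1
  filters: 100
- name: s4_pw_relu
  kind: relu
  inputs:
  - s4_pw
- name: gap
  kind: gap1d
  inputs:
  - s4_pw_relu
- name: fc
  kind: dense
  inputs:
  - gap
  filters: 2
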