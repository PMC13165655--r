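name: micro_tcn
input_length: 1024
declared_param_count: 41698
layers:
- name: stem
  kind: conv1d
  inputs:
  - input
  kernel: 5
  filters: 16
  stride: 2
- name: stem_relu
  kind: relu
  inputs:
  - stem
- name: b1_conv1
  kind: dilated_causal_conv1d
  inputs:
  - stem_relu
  kernel: 3
  filters: 16
  dilation: 1.0
  padding: causal
- name: b1_relu1
  kind: relu
  inputs:
  - b1_conv1
- name: b1_conv2
  kind: dilated_causal_conv1d
  inputs:
  - b1_relu1
  kernel: 3
  filters: 16
  dilation: 1.0
  padding: causal
- name: b1_add
  kind: add
  inputs:
  - b1_conv2
  - stem_relu
- name: b1_relu2
  kind: relu
  inputs:
  - b1_add
- name: down1
  kind: pointwise_conv1d
  inputs:
  - b1_relu2
  kernel: 1
  filters: 28
  stride: 2
- name: down1_relu
  kind: relu
  inputs:
  - down1
- name: b2_conv1
  kind: dilated_causal_conv1d
  inputs:
  - down1_relu
  kernel: 3
  filters: 28
  dilation: 2.0
  padding: causal
- name: b2_relu1
  kind: relu
  inputs:
  - b2_conv1
- name: b2_conv2
  kind: dilated_causal_conv1d
  inputs:
  - b2_relu1
  kernel: 3
  filters: 28
  dilation: 2.0
  padding: causal
- name: b2_add
  kind: add
  inputs:
  - b2_conv2
  - down1_relu
- name: b2_relu2
  kind: relu
  inputs:
  - b2_add
- name: down2
  kind: pointwise_conv1d
  inputs:
  - b2_relu2
  kernel: 1
  filters: 42
  stride: 2
- name: down2_relu
  kind: relu
  inputs:
  - down2
- name: b3_conv1
  kind: dilated_causal_conv1d
  inputs:
  - down2_relu
  kernel: 3
  filters: 42
  dilation: 4.0
  padding: causal
- name: b3_relu1
  kind: relu
  inputs:
  - b3_conv1
- name: b3_conv2
  kind: dilated_causal_conv1d
  inputs:
  - b3_relu1
  kernel: 3
  filters: 42
  dilation: 4.0
  padding: causal
- name: b3_add
  kind: add
  inputs:
  - b3_conv2
  - down2_relu
- name: b3_relu2
  kind: relu
  inputs:
  - b3_add
- name: down3
  kind: pointwise_conv1d
  inputs:
  - b3_relu2
  kernel: 1
  filters: 58
  stride: 2
- name: down3_relu
  kind: relu
  inputs:
  - down3
- name: b4_conv1
  kind: dilated_causal_conv1d
  inputs:
  - down3_relu
  kernel: 3
  filters: 58
  dilation: 8.0
  padding: causal
- name: b4_relu1
  kind: relu
  inputs:
  - b4_conv1
- name: b4_conv2
  kind: dilated_causal_conv1d
  inputs:
  - b4_relu1
  kernel: 3
  filters: 58
  dilation: 8.0
  padding: causal
- name: b4_add
  kind: add
  inputs:
  - b4_conv2
  - down3_relu
- name: b4_relu2
  kind: relu
  inputs:
  - b4_add
- name: gap
  kind: gap1d
  inputs:
  - b4_relu2
- name: fc
  kind: dense
  inputs:
  - gap
  filters: 2
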