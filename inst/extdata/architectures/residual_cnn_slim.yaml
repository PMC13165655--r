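name: residual_cnn_slim
input_length: 1024
declared_param_count: 140034
layers:
- name: s1_conv1
  kind: conv1d
  inputs:
  - input
  kernel: 5
  filters: 20
- name: s1_relu1
  kind: relu
  inputs:
  - s1_conv1
- name: s1_conv2
  kind: conv1d
  inputs:
  - s1_relu1
  kernel: 5
  filters: 20
- name: s1_proj
  kind: pointwise_conv1d
  inputs:
  - input
  kernel: 1
  filters: 20
- name: s1_add
  kind: add
  inputs:
  - s1_conv2
  - s1_proj
- name: s1_relu2
  kind: relu
  inputs:
  - s1_add
- name: s1_pool
  kind: maxpool1d
  inputs:
  - s1_relu2
  kernel: 4
- name: s2_conv1
  kind: conv1d
  inputs:
  - s1_pool
  kernel: 5
  filters: 40
- name: s2_relu1
  kind: relu
  inputs:
  - s2_conv1
- name: s2_conv2
  kind: conv1d
  inputs:
  - s2_relu1
  kernel: 5
  filters: 40
- name: s2_proj
  kind: pointwise_conv1d
  inputs:
  - s1_pool
  kernel: 1
  filters: 40
- name: s2_add
  kind: add
  inputs:
  - s2_conv2
  - s2_proj
- name: s2_relu2
  kind: relu
  inputs:
  - s2_add
- name: s2_pool
  kind: maxpool1d
  inputs:
  - s2_relu2
  kernel: 4
- name: s3_conv1
  kind: conv1d
  inputs:
  - s2_pool
  kernel: 5
  filters: 64
- name: s3_relu1
  kind: relu
  inputs:
  - s3_conv1
- name: s3_conv2
  kind: conv1d
  inputs:
  - s3_relu1
  kernel: 5
  filters: 64
- name: s3_proj
  kind: pointwise_conv1d
  inputs:
  - s2_pool
  kernel: 1
  filters: 64
- name: s3_add
  kind: add
  inputs:
  - s3_conv2
  - s3_proj
- name: s3_relu2
  kind: relu
  inputs:
  - s3_add
- name: s3_pool
  kind: maxpool1d
  inputs:
  - s3_relu2
  kernel: 4
- name: s4_conv1
  kind: conv1d
  inputs:
  - s3_pool
  kernel: 5
  filters: 100
- name: s4_relu1
  kind: relu
  inputs:
  - s4_conv1
- name: s4_conv2
  kind: conv1d
  inputs:
  - s4_relu1
  kernel: 5
  filters: 100
- name: s4_proj
  kind: pointwise_conv1d
  inputs:
  - s3_pool
  kernel: 1
  filters: 100
- name: s4_add
  kind: add
  inputs:
  - s4_conv2
  - s4_proj
- name: s4_relu2
  kind: relu
  inputs:
  - s4_add
- name: s4_pool
  kind: maxpool1d
  inputs:
  - s4_relu2
  kernel: 4
- name: gap
  kind: gap1d
  inputs:
  - s4_pool
- name: fc
  kind: dense
  inputs:
  - gap
  filters: 2
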