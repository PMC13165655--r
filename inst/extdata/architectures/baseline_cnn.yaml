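name: baseline_cnn
input_length: 1024
declared_param_count: 33826
layers:
- name: conv1
  kind: conv1d
  inputs:
  - input
  kernel: 3
  filters: 8
- name: relu1
  kind: relu
  inputs:
  - conv1
- name: pool1
  kind: maxpool1d
  inputs:
  - relu1
  kernel: 4
- name: conv2
  kind: conv1d
  inputs:
  - pool1
  kernel: 3
  filters: 24
- name: relu2
  kind: relu
  inputs:
  - conv2
- name: pool2
  kind: maxpool1d
  inputs:
  - relu2
  kernel: 4
- name: conv3
  kind: conv1d
  inputs:
  - pool2
  kernel: 3
  filters: 48
- name: relu3
  kind: relu
  inputs:
  - conv3
- name: pool3
  kind: maxpool1d
  inputs:
  - relu3
  kernel: 4
- name: conv4
  kind: conv1d
  inputs:
  - pool3
  kernel: 3
  filters: 80
- name: relu4
  kind: relu
  inputs:
  - conv4
- name: pool4
  kind: maxpool1d
  inputs:
  - relu4
  kernel: 4
- name: flatten
  kind: flatten
  inputs:
  - pool4
- name: fc1
  kind: dense
  inputs:
  - flatten
  filters: 56
- name: fc1_relu
  kind: relu
  inputs:
  - fc1
- name: fc2
  kind: dense
  inputs:
  - fc1_relu
  filters: 2
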