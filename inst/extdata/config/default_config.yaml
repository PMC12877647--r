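scoring:
  scale_max_sum: 3.3
  threshold: 3.25
  pore_threshold: 2.5
charges:
  histidine_positive: false
clash:
  overlap_cutoff: 0.6
  hbond_allowance: 0.4
contact:
  overlap_cutoff: -0.4
relief:
  enabled: true
  max_sweeps: 8
  steps: [30.0, 15.0, 5.0]
score_d:
  w_relieved: 0.5
  min_prob: 0.0
score_e:
  min_prob: 0.10
structure:
  mutate_chain: A
  numbering_offset: 0
vdw_radii:
  "C": 1.70
  "N": 1.55
  "O": 1.52
  "S": 1.80
  "P": 1.80
  "H": 1.20
regions:
  unresolved:
    - "132-398"
    - "433-448"
    - "511-519"
    - "578-582"
    - "598-602"
    - "864-1159"
  domains:
    N-tail: "1-25"
    PAS: "26-135"
    N-linker: "136-397"
    VSD: "398-545"
    pore: "546-670"
    C-linker: "671-747"
    CNBHD: "748-870"
    C-tail: "871-1159"
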