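{
  "nodes": [
    {
      "label": "input_1_1",
      "type": "input",
      "passes": 1,
      "flags": [
        "is_input"
      ],
      "module_addresses": []
    },
    {
      "label": "sub_1_2",
      "type": "sub",
      "passes": 1,
      "flags": [
        "is_branch_start"
      ],
      "module_addresses": []
    },
    {
      "label": "mean_1_3",
      "type": "mean",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "gt_1_4",
      "type": "gt",
      "passes": 1,
      "flags": [
        "is_bool_terminal"
      ],
      "module_addresses": []
    },
    {
      "label": "relu_1_5",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_6",
      "type": "output",
      "passes": 1,
      "flags": [
        "is_output"
      ],
      "module_addresses": []
    }
  ],
  "edges": [
    {
      "from": "input_1_1",
      "to": "sub_1_2",
      "arg": "0"
    },
    {
      "from": "sub_1_2",
      "to": "mean_1_3",
      "arg": "0"
    },
    {
      "from": "mean_1_3",
      "to": "gt_1_4",
      "arg": "0"
    },
    {
      "from": "input_1_1",
      "to": "relu_1_5",
      "arg": "0"
    },
    {
      "from": "relu_1_5",
      "to": "output_1_6",
      "arg": "0"
    }
  ],
  "name": "cond_branch"
}
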