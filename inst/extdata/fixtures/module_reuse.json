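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
      "label": "linear_1_2",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "fc1"
      ]
    },
    {
      "label": "relu_1_3",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "act:1"
      ]
    },
    {
      "label": "linear_2_4",
      "type": "linear",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "fc2"
      ]
    },
    {
      "label": "relu_2_5",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": [
        "act:2"
      ]
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
      "to": "linear_1_2",
      "arg": "0"
    },
    {
      "from": "linear_1_2",
      "to": "relu_1_3",
      "arg": "0"
    },
    {
      "from": "relu_1_3",
      "to": "linear_2_4",
      "arg": "0"
    },
    {
      "from": "linear_2_4",
      "to": "relu_2_5",
      "arg": "0"
    },
    {
      "from": "relu_2_5",
      "to": "output_1_6",
      "arg": "0"
    }
  ],
  "name": "module_reuse"
}
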