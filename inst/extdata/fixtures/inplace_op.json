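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
      "label": "add_1_2",
      "type": "add",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "relu_1_3",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "cos_1_4",
      "type": "cos",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_5",
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
      "to": "add_1_2",
      "arg": "0"
    },
    {
      "from": "add_1_2",
      "to": "relu_1_3",
      "arg": "0"
    },
    {
      "from": "relu_1_3",
      "to": "cos_1_4",
      "arg": "0"
    },
    {
      "from": "cos_1_4",
      "to": "output_1_5",
      "arg": "0"
    }
  ],
  "name": "inplace_op"
}
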