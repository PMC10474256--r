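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
      "label": "cos_1_2",
      "type": "cos",
      "passes": 2,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "relu_1_3",
      "type": "relu",
      "passes": 2,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "mul_1_4",
      "type": "mul",
      "passes": 2,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "tan_1_5",
      "type": "tan",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "cos_2_6",
      "type": "cos",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "relu_2_7",
      "type": "relu",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "mul_2_8",
      "type": "mul",
      "passes": 1,
      "flags": [],
      "module_addresses": []
    },
    {
      "label": "output_1_9",
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
      "to": "cos_1_2:1",
      "arg": "0"
    },
    {
      "from": "cos_1_2:1",
      "to": "relu_1_3:1",
      "arg": "0"
    },
    {
      "from": "relu_1_3:1",
      "to": "mul_1_4:1",
      "arg": "0"
    },
    {
      "from": "mul_1_4:1",
      "to": "cos_1_2:2",
      "arg": "0"
    },
    {
      "from": "cos_1_2:2",
      "to": "relu_1_3:2",
      "arg": "0"
    },
    {
      "from": "relu_1_3:2",
      "to": "mul_1_4:2",
      "arg": "0"
    },
    {
      "from": "mul_1_4:2",
      "to": "tan_1_5",
      "arg": "0"
    },
    {
      "from": "tan_1_5",
      "to": "cos_2_6",
      "arg": "0"
    },
    {
      "from": "cos_2_6",
      "to": "relu_2_7",
      "arg": "0"
    },
    {
      "from": "relu_2_7",
      "to": "mul_2_8",
      "arg": "0"
    },
    {
      "from": "mul_2_8",
      "to": "output_1_9",
      "arg": "0"
    }
  ],
  "name": "fig4b"
}
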